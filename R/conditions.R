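# Classed error conditions used across the package so callers (and the CLI)
# can map failures to exit codes without string matching.

qbd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "qbd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == trunc(x) && x >= 0
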