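#' Canonical byte serialization of ledger records
#'
#' Serializes a transaction envelope, block, or any named-list record into a
#' canonical JSON byte sequence: object keys sorted lexicographically (C
#' locale), no insignificant whitespace, text in UTF-8, integers in decimal
#' notation, logicals as `true`/`false`. Non-integer numerics are rejected —
#' measurements travel on-ledger as decimal strings so that serialization is
#' bit-exact across platforms. Equal inputs always produce byte-identical
#' output, which is what makes block hashes reproducible.
#'
#' @param record A named list (possibly nested); unnamed lists become JSON
#'   arrays. Scalars may be character, integer-valued numeric, or logical.
#' @return A raw vector holding the canonical UTF-8 JSON bytes.
#' @examples
#' canonical_serialize(list(b = 1L, a = "x"))  # keys sorted: a before b
#' @export
canonical_serialize <- function(record) {
  charToRaw(canonical_json(record))
}

# Recursive canonical JSON writer. Kept independent of jsonlite so the byte
# format is fully specified by this file.
canonical_json <- function(x) {
  if (is.null(x)) {
    return("null")
  }
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm) || all(nm == "")) {
      return(paste0("[", paste(vapply(x, canonical_json, character(1)),
                               collapse = ","), "]"))
    }
    if (any(nm == "") || anyDuplicated(nm)) {
      stop("canonical_serialize: all keys must be named and unique",
           call. = FALSE)
    }
    ord <- order_c_locale(nm)
    parts <- vapply(ord, function(i) {
      paste0(json_string(nm[[i]]), ":", canonical_json(x[[i]]))
    }, character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    # vectors of length != 1 must be wrapped in lists explicitly
    return(canonical_json(as.list(x)))
  }
  if (is.character(x)) {
    return(json_string(x))
  }
  if (is.logical(x)) {
    if (is.na(x)) stop("canonical_serialize: NA is not serializable", call. = FALSE)
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) {
    if (is.na(x) || !is.finite(x) || x != trunc(x)) {
      stop("canonical_serialize: only integer-valued numbers are allowed; ",
           "store measurements as decimal strings", call. = FALSE)
    }
    return(format(x, scientific = FALSE, trim = TRUE))
  }
  stop("canonical_serialize: unserializable value of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# Lexicographic key order in the C locale, independent of the session locale.
order_c_locale <- function(nm) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(nm)
}

# Minimal JSON string escaping (control chars, quote, backslash), UTF-8 body.
json_string <- function(s) {
  s <- enc2utf8(as.character(s))
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining C0 control characters, rare in practice
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    for (code in 1:31) {
      ch <- rawToChar(as.raw(code))
      if (grepl(ch, s, fixed = TRUE, useBytes = TRUE)) {
        s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE, useBytes = TRUE)
      }
    }
  }
  paste0("\"", s, "\"")
}

#' SHA-256 hex digest of a raw byte sequence
#'
#' @param bytes Raw vector.
#' @return 64 lowercase hexadecimal characters.
#' @export
sha256_hex <- function(bytes) {
  stopifnot(is.raw(bytes))
  digest::digest(bytes, algo = "sha256", serialize = FALSE)
}
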