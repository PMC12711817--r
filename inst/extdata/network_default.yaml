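# Default network: one single peer (trial ledger), one double peer (both
# ledgers, DC issuer), three endorsers, one orderer/committer, six CAs (one
# per server group), two channels, majority endorsement. Peers are grouped
# onto six servers: four PDCA phase servers plus two blockchain servers.
channels:
  - {name: channel-1, ledger_kind: T-ledger}
  - {name: channel-2, ledger_kind: P-ledger}
peers:
  - peer_id: peer-plan-single
    roles: [single]
    channels: [channel-1]
    hosted_ledgers: [T-ledger]
    server: plan
  - peer_id: peer-do-double
    roles: [double, dc_issuer]
    channels: [channel-1, channel-2]
    hosted_ledgers: [T-ledger, P-ledger]
    server: do
  - peer_id: peer-endorser-1
    roles: [endorser, committer]
    channels: [channel-1, channel-2]
    hosted_ledgers: []
    server: blockchain-1
  - peer_id: peer-endorser-2
    roles: [endorser, committer]
    channels: [channel-1, channel-2]
    hosted_ledgers: []
    server: blockchain-1
  - peer_id: peer-endorser-3
    roles: [endorser, committer]
    channels: [channel-1, channel-2]
    hosted_ledgers: []
    server: blockchain-2
  - peer_id: peer-orderer
    roles: [orderer, committer]
    channels: [channel-1, channel-2]
    hosted_ledgers: []
    server: blockchain-2
cas:
  - {ca_id: ca-plan, server: plan}
  - {ca_id: ca-do, server: do}
  - {ca_id: ca-check, server: check}
  - {ca_id: ca-act, server: act}
  - {ca_id: ca-blockchain-1, server: blockchain-1}
  - {ca_id: ca-blockchain-2, server: blockchain-2}
servers: [plan, do, check, act, blockchain-1, blockchain-2]
policy:
  rule: majority
  k: ~
batch_size: 1
units:
  SDI: peer-plan-single
  DCI: peer-do-double
  TO: peer-do-double
  PrT: peer-do-double
  PoT: peer-do-double
  RA: peer-do-double
  RCA: peer-do-double
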