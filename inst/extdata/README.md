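# Bundled example data

All files here are small plain-text fixtures.

- `synthetic_signature_gosselin_881.txt`, `synthetic_signature_mcquade_42.txt`
  — SYNTHETIC stand-ins for the two published microglial signature gene
  lists the cascade starts from. They reproduce the documented structure of
  those lists (881 and 42 symbols with 9 symbols in common, so their
  case-insensitive union has 914 unique symbols) and include well-known
  microglial marker symbols, but the bulk of the 881-gene list consists of
  generated placeholder symbols (`MGSIG####`). They are NOT the published
  lists.
- `demo_config.yaml` — pipeline configuration used by the worked example:
  a simulation block at desk scale plus a qPCR block.
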