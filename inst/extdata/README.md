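# Packaged fixtures

All sequence fixtures in this directory are **synthetic**: they are
deterministic constructions (see `scripts/make_seed_fixtures.R` in the
source repository), not database entries.  They reproduce the
conserved-residue architecture of the two protein families the tool
searches for, so that profile building, domain validation, reference
numbering and substitution classification are fully exercised without any
external downloads.

- `luxr_seed.synthetic.afa` — aligned seed set for the LuxR family of
  AHL-responsive transcriptional regulators.  Row 1, `TraR_syn`, is
  ungapped and is the numbering reference: all "TraR numbering" positions
  (W57, Y61, D70, P71, W85, G113 in the ligand-binding region; E178,
  L182, G188 in the DNA-binding helix-turn-helix) refer to this row.  The
  members `NesR_syn`, `XagR_syn`, `OryR_syn`, `PsoR_syn` carry the
  plant-associated-bacteria (PAB) solo signature (85M, 61W; `OryR_syn`
  also 57M).
- `luxi_seed.synthetic.afa` — aligned seed set for the LuxI family of
  acyl-homoserine-lactone synthases.  Row 1, `TraI_syn`, is ungapped and
  is the numbering reference.
- `luxi_conserved_sites.synthetic.tsv` — the synthase-core invariant
  positions in TraI numbering used by the "complete consensus" rescue
  rule.  The set lists the widely cited invariant N-terminal residues of
  the family (R25, F29, W35, E44, D49, R70, R104) and, like the seed
  rows, is an approximate stand-in rather than a transcription of any
  single published table.
- `summary.schema.json` — structural schema for `summary.json` written by
  `qs_scan()`.

The `_syn` suffix on every member name marks the sequence as synthetic.
Conclusions about real genomes should rest on profiles built from curated
family alignments; the packaged seeds exist to make the machinery testable
and deterministic.
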