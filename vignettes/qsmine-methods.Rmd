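---
title: "Methods: mining LuxI/LuxR quorum-sensing genes and calling LuxR solos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining LuxI/LuxR quorum-sensing genes and calling LuxR solos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

Many proteobacteria regulate group behaviors by acyl-homoserine-lactone
(AHL) quorum sensing.  The canonical circuit couples a LuxI-family AHL
synthase to a LuxR-family transcriptional regulator, usually encoded next
to each other.  Genomes frequently carry additional *luxR* genes with no
*luxI* in their neighborhood — *LuxR solos* (orphans).  Solos can respond
to endogenous AHLs, eavesdrop on other species, or — in the
plant-associated-bacteria (PAB) subfamily — respond to plant compounds,
and a small number of ligand-binding-domain substitutions (most notably a
regulatory tryptophan replaced by methionine and a tyrosine replaced by
tryptophan) distinguishes the PAB subfamily from AHL-responsive
regulators.

`qsmine` turns the mining procedure behind such surveys into a
reproducible tool: find candidate *luxI*/*luxR* genes in a draft
assembly, validate them by domain architecture, examine the conserved
residues in a fixed reference numbering, and classify every validated
*luxR* as paired or solo.

## Detection: position-specific profiles

Candidate proteins come from a supplied GFF3 annotation or from the
built-in six-frame ORF finder (bacterial genetic code, table 11, starts
ATG/GTG/TTG rendered as Met, default minimum 50 aa).  Each protein is
scored against four profiles built from the packaged seed alignments:

| profile | region modelled |
|---|---|
| `LUXI_SYNTHASE` | full AHL-synthase family domain |
| `LUXI_CONSERVED_SITE` | the most-conserved synthase block (seed columns 21–60) |
| `LUXR_AUTOIND_BIND` | N-terminal autoinducer/ligand-binding domain (columns 1–160) |
| `LUXR_HTH` | C-terminal helix-turn-helix DNA-binding domain |

A profile column stores log-odds scores
$s(a) = \log_2 \frac{p(a)}{q(a)}$ with
$p(a) = \frac{n_a + \alpha\, q(a)}{n_{\text{eff}} + \alpha}$,
where $n_a$ counts residue $a$ among the ungapped rows of the column,
$q$ is the Robinson–Robinson background, and $\alpha$ (default 0.5) is
the pseudocount mass.  Columns with more than 50% gaps are dropped.
Scoring is a local (Smith–Waterman-style) alignment of profile columns
against the protein with affine gap penalties in bits (open 4, extend
0.5; a gap of length $k$ costs $4 + 0.5k$).  Residues outside the
20-letter alphabet (X from ambiguous codons) score a flat −4 bits, so
they can never contribute positively to a hit.

E-values come from a Gumbel null fitted by the method of moments to the
scores of i.i.d. background-distributed sequences (default 300 shuffles
of length 300, seeded):
$\lambda = \pi/(\sigma\sqrt 6)$, $\mu = \bar s - \gamma/\lambda$, and
$E(s) = N \exp(-\lambda (s - \mu))$ for a database of $N$ proteins.
Requiring at least 200 shuffles keeps the moment estimates stable; the
suite checks that the fitted tail tracks the empirical tail of a fresh
null within ±50% at the 99th percentile, and that doubling the null size
moves $\lambda$ by less than 10%.

A gene becomes a candidate when any profile reaches the bit threshold
(default 50).  The two historical detection routes this unifies — a
BLAST-style bit-score cutoff of 50 and HMM domain matches — are not on
identical scales, so the threshold is exposed (`--bits-threshold`)
rather than hard-wired.

## Validation: domain architecture and the rescue rule

* **LuxR**: valid iff both the ligand-binding and the HTH hits reach the
  threshold *and* the ligand-binding envelope starts N-terminal of the
  HTH envelope, matching the family's invariant domain order.  There is
  no rescue path for LuxR: candidates missing either domain are invalid.
* **LuxI**: valid iff both the synthase-family and conserved-site hits
  pass.  When only the conserved-site evidence is missing, the candidate
  is rescued to `VALID_BY_RESIDUE_RESCUE` iff *every* position of the
  packaged synthase rule set matches in TraI numbering ("complete
  consensus").  A gap at a rule position counts as a non-match — the
  rescue is deliberately strict.  The rescue is monotone: restoring the
  conserved-site hit can only upgrade the verdict.

When one protein carries several hits of the same family, only the
best-bits hit per family is kept: calls are per gene, not per domain
copy.

## Reference numbering and substitution classes

Conserved sites are always reported in the numbering of a single
packaged reference per family (`TraR_syn` for LuxR, `TraI_syn` for
LuxI).  Each candidate is globally aligned to the reference
(Needleman–Wunsch, BLOSUM62, gap open 11 / extend 1, ties broken
deterministically preferring match over deletion over insertion), and
every reference position maps to the paired candidate residue or to a
gap.  The LuxR rule set is W57, Y61, D70, P71, W85, G113
(ligand-binding) and E178, L182, G188 (DNA-binding).

Classification of a validated LuxR from its checks:

* `CANONICAL_CONSENSUS` — all nine sites match;
* `PAB_SIGNATURE` — methionine at the regulatory tryptophan site and
  tryptophan at position 61, with no unrecognized ligand-region change;
* `NOVEL_SUBSTITUTION` — any ligand-region substitution absent from the
  packaged list of reported PAB substitutions (57M, 61W, 85M);
* `MIXED` — anything else (including DNA-binding-only substitutions,
  which are always reported but never produce the PAB label).

The regulatory tryptophan of the PAB signature is configurable
(`pab_regulatory_site`, default 85) because the field's descriptions of
the signature variously cite positions 57 and 85 for the same proteins;
the tool defaults to 85 — the position tied to the PsrR-like pattern —
and always reports the position-57 status alongside, so neither reading
is silently discarded.

## Paired or solo: the neighborhood window

For every validated *luxR*, a window of `window_size` bp (default
10 000) is centered on the CDS midpoint, clipped at contig ends.  The
gene is **paired** iff at least one validated *luxI* CDS on the same
contig overlaps the window by ≥ 1 bp, else it is a **solo**; the
distance reported is the gap between the two CDS intervals (0 when they
touch or overlap).  "Centered" is read as midpoint ± half-window since
only the total width is conventionally stated; the window is a flag, not
a constant.  One *luxI* may pair several *luxR* genes — counting is per
*luxR*.  Invariants tested: planting a *luxI* inside a solo's window
always flips it to paired; mirroring a contig preserves all statuses;
pairs + solos always equals the number of validated *luxR*.

## The synthetic-genome generator

`make_assembly()` emulates exactly what the pipeline consumes: contigs of
i.i.d. background bases at a chosen GC content, with family members
(optionally mutated in reference numbering) reverse-translated —
seeded synonymous codon choice by default, so the DNA is not
unrealistically low-entropy — spliced in with a stop appended and an
in-frame guard stop immediately upstream, plus random-protein decoy
inserts that carry real ORFs but must not validate.  Ground truth is
returned and written as GFF3; the same spec and seed give byte-identical
FASTA/GFF3.

Two packaged specs mirror the published summary patterns used as desk
checks: a three-solo/no-*luxI* assembly (solos carrying 85M+61W, 85R and
113T) and a one-pair/two-solo assembly whose pair is adjacent
(convergent, touching CDS intervals).  Both use three 60 kb contigs at
the GC content of the corresponding strain and five decoys — large
enough for realistic ORF noise (~1 000 spurious ORFs per run), small
enough for seconds-scale runs.

What the generator does **not** emulate: operon structure, intergenic
composition, codon-usage bias of a real genome, sequencing error,
assembly fragmentation in the middle of genes.  Passing the planted-gene
recovery experiments therefore demonstrates that the machinery is
correct and well calibrated on clean insertions, not that sensitivity on
real draft genomes equals 1; on real data the profiles (built from
synthetic seeds, not curated family alignments) can differ at the margin
from HMM-based searches, which is why per-gene evidence is always
written to `validation.tsv`.

## Numerical and design choices

* Internal coordinates are 0-based half-open; all serialized output
  (GFF3) is 1-based inclusive.
* The ORF finder reports, per in-frame stop, the longest ORF (earliest
  start after the previous stop); nested sub-ORFs are not emitted.
  Codons containing N translate to X.
* GC% excludes N from the denominator; N50 is the length where the
  cumulative sorted-descending contig lengths first reach half the
  total.
* Profile consensus score equals the sum of per-column maxima, which the
  suite asserts, together with hand-computed column scores and
  single-point-mutant monotonicity.
* All randomness (calibration, simulation) flows from explicit seeds;
  RNG state is restored after internal use so library calls never
  perturb user-level reproducibility.
* Problem sizes in the test suite were chosen as the smallest that still
  exercise every code path convincingly: 20 random genome specs of five
  100 kb contigs (1–4 plants, 10 decoys) for recovery; 200 randomized
  placements for the solo-flip property; 1 000 random offsets for the
  window boundary sweep; 10 000 fresh shuffles for the E-value tail
  check.

## Known limitations

* The packaged seed alignments and conserved-site tables are synthetic
  stand-ins (see `inst/extdata/README.md`); swap in curated family
  alignments for production mining of real genomes.
* The profile scorer is a PSSM with affine gaps, not a full profile HMM
  (no insert-state emissions or local/glocal duality).
* No plasmid detection and no operon modelling; draft-genome
  fragmentation can split a pair across contigs, and a *luxI* on a
  different contig never pairs.
* tRNA/rRNA and non-CDS features are ignored; annotations are trusted
  as given.
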