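# qsmine

Mining acyl-homoserine-lactone (AHL) quorum-sensing genes in bacterial
genome assemblies: detect LuxI-family autoinducer synthases and
LuxR-family transcriptional regulators, validate them by domain
architecture and conserved-residue consensus, and classify every
validated *luxR* as **paired** with a *luxI* or as a **solo** (orphan)
using a 10 kbp gene-neighborhood window.

It is aimed at microbial genomicists surveying draft assemblies for QS
circuits — in particular for LuxR solos, whose ligand-binding-domain
substitution patterns (e.g. the plant-associated-bacteria signature
W85M + Y61W in TraR numbering) hint at non-AHL ligands.

## Method at a glance

* **Detection** — proteins (from GFF3 or a built-in six-frame ORF finder,
  genetic code 11) are scored against four position-specific log-odds
  profiles built from packaged seed alignments: synthase family,
  synthase conserved-site block, LuxR autoinducer-binding domain, LuxR
  helix-turn-helix (HTH).  Column scores are
  `log2(p(a)/q(a))` bits with background-weighted pseudocounts over the
  Robinson–Robinson background `q`; hits are best local alignments with
  affine gap costs, and E-values come from a seeded Gumbel
  (method-of-moments) calibration.  Genes with any hit ≥ 50 bits become
  candidates.
* **Validation** — LuxR: ligand-binding + HTH hits in N→C order.  LuxI:
  synthase + conserved-site hits, with a rescue to
  `VALID_BY_RESIDUE_RESCUE` when the conserved-site hit is missing but
  the candidate shows complete consensus at the packaged synthase-core
  residues (TraI numbering).
* **Residue analysis** — global BLOSUM62 alignment to a numbering
  reference (TraR for LuxR, TraI for LuxI) maps each conserved site to
  the observed residue; validated LuxR proteins are classified
  `CANONICAL_CONSENSUS`, `PAB_SIGNATURE`, `NOVEL_SUBSTITUTION` or
  `MIXED`.
* **Solo calling** — a validated *luxR* is paired iff a validated *luxI*
  CDS overlaps the 10 kbp window centered on its CDS midpoint (same
  contig, ≥ 1 bp overlap); otherwise it is a solo.
* **Simulation** — a deterministic generator plants (optionally mutated)
  family members and decoy ORFs into random contigs with ground-truth
  GFF3, so the whole pipeline is testable offline.

See `vignettes/qsmine-methods.Rmd` for the full model, parameter
meanings and limitations.  The packaged seed sequences are synthetic
stand-ins documented in `inst/extdata/README.md`.

## Worked example

Simulate an assembly patterned on a three-solo genome and scan it:

```r
library(qsmine)
asm <- make_assembly(genome_spec_sd316_like(), out_dir = "sd316_demo")
run <- qs_scan("sd316_demo/assembly.fna", out_dir = "sd316_demo/run")
print(run)
#> qs_run: 980 genes scanned, 3 candidates; 0 luxI, 3 luxR (0 paired, 3 solo)

res <- read.delim("sd316_demo/run/residues.tsv")
subset(res, status != "match")[, c("gene_id", "ref_pos", "expected",
                                   "observed", "classification")]
#>             gene_id ref_pos expected observed     classification
#> 2  contig_1_orf0152      61        Y        W      PAB_SIGNATURE
#> 5  contig_1_orf0152      85        W        M      PAB_SIGNATURE
#> 14 contig_2_orf0107      85        W        R NOVEL_SUBSTITUTION
#> 24 contig_3_orf0210     113        G        T NOVEL_SUBSTITUTION
```

The 980 genes are all ORFs ≥ 50 aa on the three 60 kb contigs; exactly
the three planted *luxR* genes survive profile scoring and domain
validation, none has a *luxI* within its window (3 solos, 0 pairs), and
the residue table recovers the planted substitutions in TraR numbering:
one PAB-signature solo (85M + 61W) and two solos with novel
ligand-region changes (85R, 113T).  The run directory also contains
`candidates.tsv`, `validation.tsv`, `solos.tsv`, `neighborhoods.tsv`,
`qs_genes.gff3` and a machine-readable `summary.json`.

The same pipeline runs from the shell:

```sh
exec/qsmine scan --fasta sd316_demo/assembly.fna --out sd316_demo/run --seed 1
exec/qsmine simulate --spec my_spec.json --out simdir
exec/qsmine calibrate --family LUXR_HTH --shuffles 400 --seed 1
```

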