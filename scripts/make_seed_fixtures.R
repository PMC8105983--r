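#!/usr/bin/env Rscript
# One-time, deterministic construction of the packaged synthetic seed
# alignments under inst/extdata/.  The sequences are NOT database entries:
# they are constructed stand-ins that reproduce the conserved-residue
# architecture of the LuxI (AHL synthase) and LuxR (AHL-responsive
# regulator) families, with the family-defining sites fixed in the
# numbering-reference row (TraR_syn / TraI_syn) and realistic divergence
# plus short deletions elsewhere.  Re-running this script regenerates the
# fixtures byte-identically.

suppressPackageStartupMessages(library(Biostrings))

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# Robinson & Robinson (1991) amino-acid background frequencies
BG <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
        G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
        M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
        S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

make_family <- function(len, sites, members, p_mut = 0.22, extra_subs = list()) {
  anc <- sample(AA, len, replace = TRUE, prob = BG[AA])
  anc[sites$ref_pos] <- sites$expected
  anc[1] <- "M" # all members initiate with Met so ORF round-trips are exact
  rows <- list()
  for (k in seq_along(members)) {
    m <- anc
    if (k > 1) { # reference row stays ungapped and unmutated at sites
      mut <- runif(len) < p_mut & !(seq_len(len) %in% c(1L, sites$ref_pos))
      m[mut] <- vapply(which(mut), function(i) sample(setdiff(AA, m[i]), 1), "")
      # one short deletion away from conserved sites and termini
      ok <- setdiff(11:(len - 14), unlist(lapply(sites$ref_pos, function(p) (p - 6):(p + 2))))
      dstart <- sample(ok, 1); dlen <- sample(2:4, 1)
      m[dstart:(dstart + dlen - 1)] <- "-"
    }
    es <- extra_subs[[members[k]]]
    if (!is.null(es)) m[as.integer(names(es))] <- unname(es)
    rows[[members[k]]] <- paste(m, collapse = "")
  }
  AAStringSet(unlist(rows))
}

set.seed(7021)

# LuxR family: TraR-numbered conserved sites (ligand-binding and HTH regions)
luxr_sites <- data.frame(
  ref_pos  = c(57L, 61L, 70L, 71L, 85L, 113L, 178L, 182L, 188L),
  expected = c("W", "Y", "D", "P", "W", "G", "E", "L", "G"))
luxr_members <- c("TraR_syn", "LuxR_syn", "LasR_syn", "CviR_syn", "SdiA_syn",
                  "ExpR_syn", "NesR_syn", "XagR_syn", "OryR_syn", "PsoR_syn")
# plant-associated-bacteria (PAB) solos carry the Trp->Met / Tyr->Trp signature
pab <- c("85" = "M", "61" = "W")
luxr <- make_family(234, luxr_sites, luxr_members,
                    extra_subs = list(NesR_syn = pab, XagR_syn = pab,
                                      PsoR_syn = pab,
                                      OryR_syn = c(pab, "57" = "M")))

# LuxI family: synthase-core invariant residues in TraI_syn numbering
luxi_sites <- data.frame(
  ref_pos  = c(25L, 29L, 35L, 44L, 49L, 70L, 104L),
  expected = c("R", "F", "W", "E", "D", "R", "R"))
luxi_members <- c("TraI_syn", "LuxI_syn", "LasI_syn", "EsaI_syn",
                  "RhlI_syn", "SinI_syn", "CviI_syn", "PpnI_syn")
luxi <- make_family(211, luxi_sites, luxi_members)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeXStringSet(luxr, "inst/extdata/luxr_seed.synthetic.afa", width = 80)
writeXStringSet(luxi, "inst/extdata/luxi_seed.synthetic.afa", width = 80)
write.table(cbind(luxi_sites, region = "synthase_core"),
            "inst/extdata/luxi_conserved_sites.synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", length(luxr), "LuxR and", length(luxi), "LuxI synthetic seed rows\n")
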