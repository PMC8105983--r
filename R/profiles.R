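#' Packaged seed alignments of synthetic QS family members
#'
#' Returns one of the two aligned seed sets shipped with the package.
#' These are constructed (synthetic) family members — not database entries —
#' that reproduce the conserved-residue architecture of the LuxI autoinducer
#' synthase and LuxR regulator families; the first row of each alignment
#' (`TraI_syn` / `TraR_syn`) is ungapped and serves as the numbering
#' reference.
#'
#' @param family `"LUXI"` or `"LUXR"`.
#' @return an `AAStringSet` of equal-length aligned rows (`-` = gap).
#' @export
seed_alignment <- function(family = c("LUXR", "LUXI")) {
  family <- match.arg(family)
  key <- paste0("seed_", family)
  if (is.null(.qs_cache[[key]])) {
    f <- system.file("extdata",
                     sprintf("%s_seed.synthetic.afa", tolower(family)),
                     package = "qsmine", mustWork = TRUE)
    aln <- Biostrings::readAAStringSet(f)
    stopifnot(length(unique(Biostrings::width(aln))) == 1L, length(aln) >= 4L)
    .qs_cache[[key]] <- aln
  }
  .qs_cache[[key]]
}

# columns of the LuxI seed alignment forming the most-conserved block,
# modelled as the conserved-site sub-profile (two-tier LuxI evidence)
QS_LUXI_SITE_BLOCK <- c(21L, 60L)

seed_for_family <- function(family) {
  switch(family,
    LUXI_SYNTHASE = seed_alignment("LUXI"),
    LUXI_CONSERVED_SITE = {
      aln <- seed_alignment("LUXI")
      Biostrings::subseq(aln, QS_LUXI_SITE_BLOCK[1], QS_LUXI_SITE_BLOCK[2])
    },
    LUXR_AUTOIND_BIND = Biostrings::subseq(seed_alignment("LUXR"), 1L, 160L),
    LUXR_HTH = {
      aln <- seed_alignment("LUXR")
      Biostrings::subseq(aln, 161L, Biostrings::width(aln)[1])
    },
    stop("unknown family: ", family))
}

#' Build a position-specific log-odds profile from a seed alignment
#'
#' Match columns are alignment columns whose gap fraction is at most
#' `gap_fraction_cutoff`.  Column probabilities use background-weighted
#' pseudocounts, `p(a) = (count(a) + pseudocount * bg(a)) / (n_eff +
#' pseudocount)` with `n_eff` the number of ungapped rows in the column, and
#' scores are `log2(p(a)/bg(a))` bits against the packaged
#' Robinson-Robinson background.
#'
#' @param seed an `AAStringSet` of aligned rows (or anything coercible by
#'   `as.character`), equal widths, `-` for gaps.
#' @param family family key stored on the profile (informational).
#' @param pseudocount total background pseudocount mass per column (> 0).
#' @param gap_fraction_cutoff columns gappier than this are dropped.
#' @return an object of class `qs_profile` with elements `family`,
#'   `columns` (L x 20 bit-score matrix), `background`, `n_match_columns`,
#'   `consensus`, and (after [calibrate_evalue()]) `calib`.
#' @export
build_profile <- function(seed, family = "CUSTOM", pseudocount = 0.5,
                          gap_fraction_cutoff = 0.5) {
  stopifnot(pseudocount > 0)
  rows <- as.character(seed)
  if (length(rows) == 0L) stop("empty seed alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("seed alignment rows differ in length")
  mat <- do.call(rbind, strsplit(rows, ""))
  gapfrac <- colMeans(mat == "-")
  keep <- which(gapfrac <= gap_fraction_cutoff)
  if (!length(keep)) stop("all columns exceed the gap fraction cutoff")
  bg <- QS_BACKGROUND
  cols <- matrix(0, nrow = length(keep), ncol = 20,
                 dimnames = list(NULL, QS_AA))
  for (k in seq_along(keep)) {
    obs <- mat[, keep[k]]
    obs <- obs[obs %in% QS_AA]
    cnt <- table(factor(obs, levels = QS_AA))
    p <- (as.numeric(cnt) + pseudocount * bg) / (length(obs) + pseudocount)
    cols[k, ] <- log2(p / bg)
  }
  consensus <- paste(QS_AA[apply(cols, 1, which.max)], collapse = "")
  structure(list(family = family, columns = cols, background = bg,
                 n_match_columns = length(keep), match_columns = keep,
                 consensus = consensus, calib = NULL),
            class = "qs_profile")
}

#' @export
print.qs_profile <- function(x, ...) {
  cat("qs_profile:", x$family, "-", x$n_match_columns, "match columns\n")
  if (!is.null(x$calib))
    cat(sprintf("  Gumbel null: mu = %.2f, lambda = %.3f (%d shuffles)\n",
                x$calib$mu, x$calib$lambda, x$calib$n_shuffles))
  invisible(x)
}

# score for residues outside the 20-letter alphabet (X): never positive
QS_X_SCORE <- -4

#' Score a protein against a profile
#'
#' Best local alignment of the profile's match columns against the protein
#' (Smith-Waterman over the PSSM with affine gap penalties in bits).
#' Returns `NULL` when the best score does not exceed the 0-bit reporting
#' floor.
#'
#' @param profile a `qs_profile`.
#' @param protein amino-acid string (length >= 10).
#' @param gap_open,gap_extend gap penalties in bits (defaults 4 and 0.5; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @param db_size effective database size used for the E-value (default 1;
#'   requires a calibrated profile for E-values, otherwise `evalue` is NA).
#' @return a one-row DomainHit `data.frame` (`family`, `bits`, `evalue`,
#'   `q_start`, `q_end` 0-based half-open protein coords,
#'   `aligned_segment`), or `NULL`.
#' @export
score_protein <- function(profile, protein, gap_open = 4, gap_extend = 0.5,
                          db_size = 1) {
  stopifnot(inherits(profile, "qs_profile"), nchar(protein) >= 10)
  r <- .profile_local_align(profile$columns, protein, gap_open, gap_extend,
                            QS_X_SCORE, TRUE)
  if (r$bits <= 0) return(NULL)
  data.frame(family = profile$family, bits = r$bits,
             evalue = profile_evalue(profile, r$bits, db_size),
             q_start = r$q_start, q_end = r$q_end,
             aligned_segment = substr(protein, r$q_start + 1, r$q_end),
             stringsAsFactors = FALSE)
}

profile_evalue <- function(profile, bits, db_size = 1) {
  if (is.null(profile$calib)) return(NA_real_)
  db_size * exp(-profile$calib$lambda * (bits - profile$calib$mu))
}

#' Calibrate a profile's E-value null distribution
#'
#' Scores `n_shuffles` i.i.d. random proteins drawn from the profile's
#' background frequencies and fits a Gumbel (extreme-value) null by the
#' method of moments: `lambda = pi / (sd * sqrt(6))`, `mu = mean -
#' gamma / lambda`.  E-values are then `db_size * exp(-lambda * (bits -
#' mu))`.  Deterministic for a given seed.
#'
#' @param profile a `qs_profile`.
#' @param n_shuffles number of null sequences (>= 200).
#' @param shuffle_length length of each null sequence (default 300).
#' @param seed RNG seed.
#' @inheritParams score_protein
#' @return the profile with `calib` set to a list `(mu, lambda,
#'   n_shuffles, shuffle_length, seed)`.
#' @export
calibrate_evalue <- function(profile, n_shuffles = 300L, shuffle_length = 300L,
                             seed = 1L, gap_open = 4, gap_extend = 0.5) {
  stopifnot(inherits(profile, "qs_profile"))
  if (n_shuffles < 200L) stop("n_shuffles must be >= 200 for a stable fit")
  scores <- with_seed(seed, {
    prots <- vapply(seq_len(n_shuffles), function(i)
      paste(sample(QS_AA, shuffle_length, replace = TRUE,
                   prob = profile$background), collapse = ""), "")
    .profile_score_many(profile$columns, prots, gap_open, gap_extend,
                        QS_X_SCORE)
  })
  s <- sd(scores)
  if (!is.finite(s) || s <= 0) stop("degenerate null: zero score variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  profile$calib <- list(mu = mu, lambda = lambda,
                        n_shuffles = as.integer(n_shuffles),
                        shuffle_length = as.integer(shuffle_length),
                        seed = as.integer(seed))
  profile
}

#' Build (and cache) the four packaged family profiles
#'
#' Builds calibrated profiles for `LUXI_SYNTHASE`, `LUXI_CONSERVED_SITE`,
#' `LUXR_AUTOIND_BIND` and `LUXR_HTH` from the packaged seed alignments.
#'
#' @param config a [qs_config()] list (pseudocount, gap penalties,
#'   calibration shuffles, seed).
#' @return named list of calibrated `qs_profile` objects.
#' @export
qs_profiles <- function(config = qs_config()) {
  key <- paste0("profiles_", config$pseudocount, "_", config$gap_fraction_cutoff,
                "_", config$calib_shuffles, "_", config$seed,
                "_", config$gap_open, "_", config$gap_extend)
  if (is.null(.qs_cache[[key]])) {
    .qs_cache[[key]] <- setNames(lapply(QS_FAMILIES, function(fam) {
      p <- build_profile(seed_for_family(fam), family = fam,
                         pseudocount = config$pseudocount,
                         gap_fraction_cutoff = config$gap_fraction_cutoff)
      calibrate_evalue(p, n_shuffles = config$calib_shuffles,
                       seed = config$seed, gap_open = config$gap_open,
                       gap_extend = config$gap_extend)
    }), QS_FAMILIES)
  }
  .qs_cache[[key]]
}

family_group <- function(family)
  ifelse(family %in% c("LUXI_SYNTHASE", "LUXI_CONSERVED_SITE"), "LUXI", "LUXR")

#' Scan gene models against all family profiles
#'
#' Scores every gene's protein against each profile and keeps genes with at
#' least one hit at or above `bits_threshold` as candidate QS genes.  For
#' each candidate the best hit per family is retained; `family_call` is the
#' group (LUXI/LUXR) of the strongest above-threshold hit.
#'
#' @param genes GeneModel `data.frame`.
#' @param profiles named list from [qs_profiles()].
#' @param bits_threshold reporting threshold in bits (default 50).
#' @param gap_open,gap_extend gap penalties in bits.
#' @return a list of `qs_candidate` objects (gene, hits, family_call,
#'   validation_status `"UNTESTED"`).
#' @export
scan_proteins <- function(genes, profiles, bits_threshold = 50,
                          gap_open = 4, gap_extend = 0.5) {
  if (nrow(genes) == 0L) return(list())
  db_size <- nrow(genes)
  # cheap first pass without traceback, per profile over all proteins
  bits <- vapply(profiles, function(p)
    .profile_score_many(p$columns, genes$protein, gap_open, gap_extend,
                        QS_X_SCORE), numeric(nrow(genes)))
  bits <- matrix(bits, nrow = nrow(genes),
                 dimnames = list(NULL, names(profiles)))
  keep <- which(apply(bits, 1, max) >= bits_threshold)
  lapply(keep, function(i) {
    hits <- do.call(rbind, lapply(names(profiles), function(fam) {
      if (bits[i, fam] <= 0) return(NULL)
      h <- score_protein(profiles[[fam]], genes$protein[i],
                         gap_open, gap_extend, db_size)
      if (is.null(h)) return(NULL)
      cbind(gene_id = genes$gene_id[i], h)
    }))
    above <- hits[hits$bits >= bits_threshold, ]
    grp <- family_group(above$family)
    best <- tapply(above$bits, grp, max)
    new_candidate(genes[i, ], hits,
                  family_call = names(best)[which.max(best)])
  })
}

new_candidate <- function(gene, hits, family_call = "none") {
  structure(list(gene = gene, hits = hits, family_call = family_call,
                 validation_status = "UNTESTED", reason = NA_character_,
                 residue_checks = NULL, classification = NULL),
            class = "qs_candidate")
}

#' @export
print.qs_candidate <- function(x, ...) {
  cat(sprintf("qs_candidate %s [%s] %s  best bits: %.1f\n",
              x$gene$gene_id, x$family_call, x$validation_status,
              max(x$hits$bits)))
  invisible(x)
}
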