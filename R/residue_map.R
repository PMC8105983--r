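#' Packaged numbering-reference proteins
#'
#' Returns the ungapped first row of the corresponding synthetic seed
#' alignment: `TraR_syn` for LuxR-family numbering and `TraI_syn` for
#' LuxI-family numbering.  All conserved-site positions in the packaged
#' rule sets refer to positions (1-based) in these sequences.
#'
#' @param name `"TraR"` or `"TraI"`.
#' @return a list with `name`, `seq` (amino-acid string).
#' @export
reference_protein <- function(name = c("TraR", "TraI")) {
  name <- match.arg(name)
  aln <- seed_alignment(if (name == "TraR") "LUXR" else "LUXI")
  seq <- gsub("-", "", as.character(aln[[1]]))
  list(name = name, seq = seq)
}

#' Conserved-residue rule sets
#'
#' `luxr_ruleset()` holds the nine invariant positions of AHL-responsive
#' LuxR regulators in TraR numbering: ligand-binding W57, Y61, D70, P71,
#' W85, G113 and DNA-binding E178, L182, G188.  `luxi_ruleset()` reads the
#' packaged synthase-core invariant set (TraI numbering) from
#' `extdata/luxi_conserved_sites.synthetic.tsv`.
#'
#' @return a `data.frame` with columns `ref_pos`, `expected`, `region`.
#' @export
luxr_ruleset <- function() {
  data.frame(
    ref_pos  = c(57L, 61L, 70L, 71L, 85L, 113L, 178L, 182L, 188L),
    expected = c("W", "Y", "D", "P", "W", "G", "E", "L", "G"),
    region   = c(rep("ligand_binding", 6), rep("dna_binding", 3)),
    stringsAsFactors = FALSE)
}

#' @rdname luxr_ruleset
#' @export
luxi_ruleset <- function() {
  f <- system.file("extdata", "luxi_conserved_sites.synthetic.tsv",
                   package = "qsmine", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

# ligand-region substitutions already reported in plant-associated-bacteria
# (PAB) LuxR solos; anything else is a novel substitution
qs_known_patterns <- function() {
  data.frame(ref_pos = c(85L, 61L, 57L), observed = c("M", "W", "M"),
             stringsAsFactors = FALSE)
}

blosum62 <- function() {
  if (is.null(.qs_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .qs_cache$blosum62 <- e$BLOSUM62
  }
  .qs_cache$blosum62
}

#' Globally align a candidate protein to a numbering reference
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scores and affine gaps
#' (open 11, extend 1; a gap of length k costs `open + k * ext`).  Ties are
#' resolved deterministically preferring match over deletion over
#' insertion.
#'
#' @param candidate_protein amino-acid string (>= 50 residues).
#' @param ref a reference from [reference_protein()] (or any list with
#'   `name`/`seq`).
#' @param gap_open,gap_extend gap penalties.
#' @return an object of class `qs_alignment`: list with `ref_name`,
#'   `score`, and `columns`, a two-column integer matrix of aligned 1-based
#'   positions (`ref`, `cand`; 0 = gap).
#' @export
align_to_reference <- function(candidate_protein, ref,
                               gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(candidate_protein) >= 50, nchar(ref$seq) >= 50)
  sm <- blosum62()
  a <- match(strsplit(ref$seq, "")[[1]], rownames(sm))
  b <- match(strsplit(candidate_protein, "")[[1]], rownames(sm))
  if (anyNA(a) || anyNA(b)) {
    # unknown residues (X outside the matrix rows) -> map to matrix's X row
    xi <- match("X", rownames(sm))
    a[is.na(a)] <- xi; b[is.na(b)] <- xi
  }
  al <- .nw_align(a, b, sm, gap_open, gap_extend)
  structure(list(ref_name = ref$name, ref_seq = ref$seq,
                 cand_seq = candidate_protein,
                 score = attr(al, "score"),
                 columns = matrix(as.integer(al), ncol = 2,
                                  dimnames = list(NULL, c("ref", "cand")))),
            class = "qs_alignment")
}

#' Map reference numbering onto a candidate
#'
#' For every 1-based reference position, gives the aligned candidate
#' residue, or `"-"` where the reference position falls in a deletion of
#' the candidate.  Candidate insertions are skipped; the mapping is
#' monotone increasing over non-gap entries.
#'
#' @param alignment a `qs_alignment` from [align_to_reference()].
#' @return a `data.frame` with `ref_pos`, `cand_pos` (NA at gaps),
#'   `observed` (residue or `"-"`).
#' @export
map_reference_numbering <- function(alignment) {
  stopifnot(inherits(alignment, "qs_alignment"))
  cols <- alignment$columns
  cols <- cols[cols[, "ref"] > 0, , drop = FALSE]
  cand <- strsplit(alignment$cand_seq, "")[[1]]
  data.frame(
    ref_pos = cols[, "ref"],
    cand_pos = ifelse(cols[, "cand"] > 0, cols[, "cand"], NA_integer_),
    observed = ifelse(cols[, "cand"] > 0, cand[pmax(cols[, "cand"], 1)], "-"),
    stringsAsFactors = FALSE)
}

#' Check conserved residues against a rule set
#'
#' @param mapping output of [map_reference_numbering()]; must cover all
#'   rule-set positions.
#' @param ruleset a `data.frame` as from [luxr_ruleset()]/[luxi_ruleset()].
#' @return a ResidueCheck `data.frame`: `ref_pos`, `expected`, `region`,
#'   `observed`, `status` in `{match, substitution, gap}`.
#' @export
check_conserved_residues <- function(mapping, ruleset) {
  ix <- match(ruleset$ref_pos, mapping$ref_pos)
  if (anyNA(ix))
    stop("rule-set position(s) beyond the reference length: ",
         paste(ruleset$ref_pos[is.na(ix)], collapse = ", "))
  obs <- mapping$observed[ix]
  data.frame(ref_pos = ruleset$ref_pos, expected = ruleset$expected,
             region = ruleset$region, observed = obs,
             status = ifelse(obs == "-", "gap",
                             ifelse(obs == ruleset$expected,
                                    "match", "substitution")),
             stringsAsFactors = FALSE)
}

#' Classify a LuxR candidate from its conserved-residue checks
#'
#' Labels: `CANONICAL_CONSENSUS` when all nine sites match;
#' `PAB_SIGNATURE` when the regulatory tryptophan site (default TraR
#' position 85, configurable because both 57 and 85 are tracked) shows M
#' and position 61 shows W with no unrecognized ligand-region change — the
#' substitution pattern of plant-associated-bacteria solos such as PsrR and
#' OryR; `NOVEL_SUBSTITUTION` when any ligand-region substitution is absent
#' from the packaged known-pattern list; `MIXED` otherwise.  DNA-binding
#' substitutions are reported but never produce `PAB_SIGNATURE`.
#'
#' @param checks ResidueCheck `data.frame` covering the full LuxR rule set.
#' @param known_patterns `data.frame(ref_pos, observed)` of reported
#'   ligand-region substitutions (default [qs_known_patterns()]).
#' @param pab_regulatory_site TraR position of the regulatory tryptophan
#'   (default 85).
#' @return list with `label` and `evidence` (the checks).
#' @export
classify_luxr <- function(checks, known_patterns = qs_known_patterns(),
                          pab_regulatory_site = 85L) {
  rs <- luxr_ruleset()
  if (!all(rs$ref_pos %in% checks$ref_pos))
    stop("incomplete residue checks for the LuxR rule set")
  obs_at <- function(p) checks$observed[match(p, checks$ref_pos)]
  lig <- checks[checks$region == "ligand_binding", ]
  subs <- lig[lig$status == "substitution", ]
  known <- paste(known_patterns$ref_pos, known_patterns$observed)
  unknown_sub <- subs[!paste(subs$ref_pos, subs$observed) %in% known, ]
  label <-
    if (all(checks$status == "match")) "CANONICAL_CONSENSUS"
    else if (obs_at(pab_regulatory_site) == "M" && obs_at(61L) == "W" &&
             nrow(unknown_sub) == 0L) "PAB_SIGNATURE"
    else if (nrow(unknown_sub) > 0L) "NOVEL_SUBSTITUTION"
    else "MIXED"
  list(label = label, evidence = checks)
}

#' Pairwise identity-distance matrix over proteins
#'
#' Global-alignment percent-identity distances (1 - identical aligned
#' residue pairs / alignment columns) over candidate and packaged
#' canonical LuxR-family proteins; a lightweight stand-in for tree
#' building, suitable for external clustering or phylogeny tools.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return symmetric numeric distance matrix.
#' @export
identity_distance_matrix <- function(proteins) {
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_to_reference(proteins[[j]],
                             list(name = names(proteins)[i],
                                  seq = proteins[[i]]))
    cols <- al$columns
    both <- cols[, 1] > 0 & cols[, 2] > 0
    ri <- strsplit(proteins[[i]], "")[[1]][cols[both, 1]]
    rj <- strsplit(proteins[[j]], "")[[1]][cols[both, 2]]
    d[i, j] <- d[j, i] <- 1 - sum(ri == rj) / nrow(cols)
  }
  d
}
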