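#' Extract the gene neighborhood around an anchor gene
#'
#' Window centered on the anchor CDS midpoint with half-width
#' `window_size/2`, clipped at contig bounds.  A gene is in the window iff
#' its CDS interval overlaps the window by at least 1 bp on the same
#' contig.
#'
#' @param anchor one GeneModel row (the anchor gene).
#' @param all_genes GeneModel `data.frame`.
#' @param contigs named `DNAStringSet` (for clipping at contig ends).
#' @param window_size window width in bp (default 10000).
#' @return list with `anchor_gene_id`, `contig_id`, `window_start`,
#'   `window_end` (0-based half-open) and `genes_in_window`
#'   (`data.frame`: gene_id, start, end, strand).
#' @export
extract_neighborhood <- function(anchor, all_genes, contigs,
                                 window_size = 10000L) {
  if (!anchor$gene_id %in% all_genes$gene_id)
    stop("anchor gene not in the gene set: ", anchor$gene_id)
  clen <- Biostrings::width(contigs[anchor$contig_id])
  mid <- (anchor$start + anchor$end) %/% 2L
  ws <- max(0L, mid - window_size %/% 2L)
  we <- min(clen, mid + window_size %/% 2L)
  same <- all_genes[all_genes$contig_id == anchor$contig_id, , drop = FALSE]
  ov <- IRanges::overlapsAny(
    IRanges::IRanges(start = same$start + 1L, end = same$end),
    IRanges::IRanges(start = ws + 1L, end = we))
  list(anchor_gene_id = anchor$gene_id, contig_id = anchor$contig_id,
       window_start = ws, window_end = we,
       genes_in_window = same[ov, c("gene_id", "start", "end", "strand")])
}

gene_gap_bp <- function(a_start, a_end, b_start, b_end)
  max(0L, max(a_start, b_start) - min(a_end, b_end))

#' Call a validated luxR paired or solo
#'
#' A luxR is `paired` iff at least one validated luxI CDS overlaps its
#' neighborhood window (same contig); otherwise it is a `solo` (orphan).
#' The distance to the nearest pairing luxI is the gap in bp between the
#' two CDS intervals (0 when they overlap or are adjacent).
#'
#' @param luxr a validated (`VALID`) LuxR `qs_candidate`.
#' @param validated_luxi list of LuxI candidates with status `VALID` or
#'   `VALID_BY_RESIDUE_RESCUE`.
#' @param all_genes GeneModel `data.frame` (for the neighborhood table).
#' @param contigs named `DNAStringSet`.
#' @param window_size window width in bp (default 10000).
#' @return a SoloCall list: `luxr_gene_id`, `status`, `nearest_luxi`
#'   (list(gene_id, distance) or NULL), `neighborhood`.
#' @export
call_solo <- function(luxr, validated_luxi, all_genes, contigs,
                      window_size = 10000L) {
  if (!identical(luxr$validation_status, "VALID"))
    stop("call_solo() requires a VALID luxR candidate")
  bad <- vapply(validated_luxi, function(x)
    !x$validation_status %in% c("VALID", "VALID_BY_RESIDUE_RESCUE"), TRUE)
  if (any(bad)) stop("unvalidated luxI candidate(s) passed to call_solo()")
  nb <- extract_neighborhood(luxr$gene, all_genes, contigs, window_size)
  g <- luxr$gene
  nearest <- NULL
  for (li in validated_luxi) {
    lg <- li$gene
    if (lg$contig_id != g$contig_id) next
    # luxI in window iff its CDS overlaps the window interval by >= 1 bp
    if (lg$end <= nb$window_start || lg$start >= nb$window_end) next
    dist <- gene_gap_bp(g$start, g$end, lg$start, lg$end)
    if (is.null(nearest) || dist < nearest$distance)
      nearest <- list(gene_id = lg$gene_id, distance = dist)
  }
  list(luxr_gene_id = g$gene_id,
       status = if (is.null(nearest)) "solo" else "paired",
       nearest_luxi = nearest, neighborhood = nb)
}

#' Summarize solo/paired calls for one assembly
#'
#' @param calls list of SoloCalls from [call_solo()].
#' @param luxi list of validated LuxI candidates (optional; without it the
#'   luxI count falls back to the distinct pairing luxI genes).
#' @return one-row `data.frame`: `n_luxi`, `n_luxr`, `n_pairs`, `n_solos`.
#' @export
summarize_calls <- function(calls, luxi = NULL) {
  status <- vapply(calls, `[[`, "", "status")
  n_luxi <- if (!is.null(luxi)) length(luxi) else
    length(unique(unlist(lapply(calls, function(x) x$nearest_luxi$gene_id))))
  data.frame(n_luxi = n_luxi, n_luxr = length(calls),
             n_pairs = sum(status == "paired"),
             n_solos = sum(status == "solo"))
}
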