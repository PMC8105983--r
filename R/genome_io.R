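#' Read a genome assembly from FASTA
#'
#' Reads contigs from a (possibly multi-record) FASTA file into a named
#' [Biostrings::DNAStringSet].  Sequences are uppercased; contig ids are the
#' first whitespace-delimited token of each header and must be unique.
#' Only DNA is accepted: `A/C/G/T/N` are kept as-is, IUPAC ambiguity codes
#' (`RYSWKMBDHV`) are mapped to `N` with a warning, and any other character
#' (including RNA `U`) is a hard error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`, one element per contig.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate contig id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad))
    stop("non-IUPAC DNA characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(grepl("[RYSWKMBDHV]", seqs))) {
    warning("IUPAC ambiguity codes mapped to N")
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Assembly summary statistics
#'
#' Computes total length, contig count, GC percentage and N50.  GC is
#' calculated over unambiguous bases only (N excluded from the
#' denominator).  N50 is the length at which the cumulative
#' sorted-descending contig lengths first reach half the total.
#'
#' @param contigs a named `DNAStringSet` as from [read_assembly()].
#' @return a one-row `data.frame` with columns `total_length`, `n_contigs`,
#'   `gc_percent`, `n50`.
#' @export
assembly_stats <- function(contigs) {
  if (length(contigs) == 0L) stop("empty contig set")
  len <- Biostrings::width(contigs)
  total <- sum(len)
  freq <- Biostrings::letterFrequency(contigs, c("A", "C", "G", "T"))
  acgt <- sum(freq)
  gc <- if (acgt > 0) 100 * sum(freq[, c("C", "G")]) / acgt else NA_real_
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  data.frame(total_length = total, n_contigs = length(contigs),
             gc_percent = gc, n50 = n50)
}

# codon -> amino-acid lookup for the bacterial genetic code (table 11);
# codons containing ambiguity translate to X.
codon_table <- function(table = "11") {
  key <- paste0("gc_", table)
  if (is.null(.qs_cache[[key]]))
    .qs_cache[[key]] <- Biostrings::getGeneticCode(table)
  .qs_cache[[key]]
}

translate_codons <- function(codons, table = "11") {
  aa <- unname(codon_table(table)[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# translate a CDS nucleotide string (5'->3'); initiator codons of table 11
# (ATG/GTG/TTG) are rendered as M, as gene callers do
translate_cds <- function(dna, table = "11") {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- translate_codons(codons, table)
  if (codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

empty_genes <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             protein = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Find open reading frames on all six frames
#'
#' Scans each contig in both orientations and all three frames under the
#' bacterial genetic code (table 11, starts ATG/GTG/TTG).  An ORF runs from
#' a start codon to the next in-frame stop; only stop-terminated ORFs are
#' reported, and for each stop the longest ORF (earliest start after the
#' previous in-frame stop) is kept.  Initiator codons are translated as M.
#' Coordinates are 0-based half-open on the forward strand and include the
#' stop codon, so the protein length is `(end - start)/3 - 1`.
#'
#' @param contigs named `DNAStringSet` (one or more contigs).
#' @param min_aa minimum protein length in residues (default 50).
#' @param table genetic code id (default `"11"`).
#' @return a GeneModel `data.frame` (`gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein`, `source = "orf_predicted"`).
#' @export
find_orfs <- function(contigs, min_aa = 50L, table = "11") {
  stopifnot(min_aa >= 1L)
  res <- list()
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    fwd <- as.character(contigs[[ci]])
    L <- nchar(fwd)
    if (L < 3 * (min_aa + 1)) next
    for (str in c("+", "-")) {
      s <- if (str == "+") fwd else revcomp_chr(fwd)
      for (f in 0:2) {
        ncod <- (L - f) %/% 3
        if (ncod < min_aa + 1) next
        cs <- seq(f + 1, by = 3, length.out = ncod)
        codons <- substring(s, cs, cs + 2)
        aa <- translate_codons(codons, table)
        aastr <- paste(aa, collapse = "")
        stops <- which(aa == "*")
        starts <- which(codons %in% c("ATG", "GTG", "TTG"))
        if (!length(stops) || !length(starts)) next
        prev <- c(0L, stops[-length(stops)])
        # earliest start strictly after the previous in-frame stop
        first <- findInterval(prev, starts) + 1L
        ok <- first <= length(starts) & starts[pmin(first, length(starts))] < stops
        st <- starts[pmin(first, length(starts))][ok]
        sp <- stops[ok]
        keep <- (sp - st) >= min_aa
        st <- st[keep]; sp <- sp[keep]
        if (!length(st)) next
        prot <- substring(aastr, st, sp - 1L)
        substr(prot, 1L, 1L) <- "M"
        b0 <- f + 3L * (st - 1L)   # strand-local 0-based start
        b1 <- f + 3L * sp          # includes stop codon
        if (str == "-") { tmp <- b0; b0 <- L - b1; b1 <- L - tmp }
        res[[length(res) + 1L]] <- data.frame(
          gene_id = NA_character_, contig_id = cid, start = b0, end = b1,
          strand = str, protein = prot, source = "orf_predicted",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty_genes())
  g <- do.call(rbind, res)
  g <- g[order(match(g$contig_id, names(contigs)), g$start, g$end, g$strand), ]
  g$gene_id <- sprintf("%s_orf%04d", g$contig_id,
                       stats::ave(seq_len(nrow(g)), g$contig_id, FUN = seq_along))
  rownames(g) <- NULL
  g
}

#' Load protein-coding genes from a GFF3 annotation
#'
#' Imports CDS features, joins multi-segment CDS sharing an ID/Parent in
#' annotation order, converts to internal 0-based half-open coordinates and
#' translates each gene (table 11, strand honoured, initiator rendered M,
#' terminal stop removed).
#'
#' @param contigs named `DNAStringSet` the annotation refers to.
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return a GeneModel `data.frame` with `source = "annotated"`.
#' @export
genes_from_gff3 <- function(contigs, path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(empty_genes())
  ids <- as.character(gr$ID)
  if (!is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, "")
    ids <- ifelse(is.na(ids) | ids == "", par, ids)
  }
  ids[is.na(ids) | ids == ""] <- sprintf("cds_%04d", which(is.na(ids) | ids == ""))
  out <- lapply(split(seq_along(gr), factor(ids, levels = unique(ids))), function(ix) {
    seg <- gr[ix]
    cid <- as.character(GenomicRanges::seqnames(seg))[1]
    if (!cid %in% names(contigs))
      stop("CDS '", ids[ix[1]], "' references unknown contig: ", cid)
    clen <- Biostrings::width(contigs[cid])
    s1 <- GenomicRanges::start(seg); e1 <- GenomicRanges::end(seg)
    if (any(s1 < 1) || any(e1 > clen))
      stop("CDS '", ids[ix[1]], "' out of contig range on ", cid)
    strand <- as.character(GenomicRanges::strand(seg))[1]
    if (!strand %in% c("+", "-"))
      stop("CDS '", ids[ix[1]], "' has no strand")
    dna <- paste(substring(as.character(contigs[[cid]]), s1, e1), collapse = "")
    if (strand == "-") dna <- revcomp_chr(dna)
    prot <- translate_cds(dna)
    prot <- sub("\\*$", "", prot)
    if (grepl("\\*", prot))
      stop("internal stop codon in CDS '", ids[ix[1]], "'")
    data.frame(gene_id = ids[ix[1]], contig_id = cid,
               start = min(s1) - 1L, end = max(e1), strand = strand,
               protein = prot, source = "annotated", stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, out)
  g <- g[order(match(g$contig_id, names(contigs)), g$start, g$end), ]
  rownames(g) <- NULL
  g
}

#' Write genes and quorum-sensing calls to GFF3
#'
#' Serializes GeneModels as 1-based inclusive CDS features.  When `calls`
#' (and the candidate set behind them) are supplied, each feature carries
#' `qs_family`, `validation_status` and `solo_status` attributes.
#'
#' @param genes GeneModel `data.frame`.
#' @param path output file.
#' @param qs_family,validation_status,solo_status optional character vectors
#'   aligned with `genes` rows (NA allowed).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, qs_family = NULL,
                       validation_status = NULL, solo_status = NULL) {
  n <- nrow(genes)
  if (n == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$source <- "qsmine"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$gene_source <- genes$source
  if (!is.null(qs_family)) gr$qs_family <- qs_family
  if (!is.null(validation_status)) gr$validation_status <- validation_status
  if (!is.null(solo_status)) gr$solo_status <- solo_status
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
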