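# Independent oracles used across the suite.  These deliberately avoid the
# package's vectorized implementations: plain loops and direct arithmetic.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, prob = NULL)
  paste(sample(AA20, n, TRUE, prob = prob), collapse = "")

random_dna <- function(n, gc = 0.5)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")

# brute-force six-frame ORF scan: explicit per-stop loops, no vectorized
# bookkeeping shared with find_orfs()
brute_orfs <- function(seq, min_aa, table = "11") {
  gc <- Biostrings::getGeneticCode(table)
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 2) next
      codons <- character(ncod)
      for (i in seq_len(ncod))
        codons[i] <- substr(s, f + 3 * i - 2, f + 3 * i)
      aa <- unname(gc[codons]); aa[is.na(aa)] <- "X"
      prev_stop <- 0L
      for (i in seq_len(ncod)) {
        if (aa[i] != "*") next
        # earliest start codon after the previous in-frame stop
        st <- NA_integer_
        for (j in (prev_stop + 1):(i - 1)) {
          if (j < 1 || j >= i) next
          if (codons[j] %in% c("ATG", "GTG", "TTG")) { st <- j; break }
        }
        prev_stop <- i
        if (is.na(st) || (i - st) < min_aa) next
        prot <- paste(c("M", aa[seq(st + 1, length.out = i - st - 1)]),
                      collapse = "")
        b0 <- f + 3L * (st - 1L); b1 <- f + 3L * i
        if (strand == "-") { tmp <- b0; b0 <- L - b1; b1 <- L - tmp }
        out[[length(out) + 1L]] <-
          data.frame(start = b0, end = b1, strand = strand, protein = prot)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      protein = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), ]
}

# a minimal validated candidate at given coordinates, for geometry tests
fake_candidate <- function(gene_id, contig_id, start, end, strand = "+",
                           family_call = "LUXR",
                           status = "VALID") {
  cand <- qsmine:::new_candidate(
    data.frame(gene_id = gene_id, contig_id = contig_id, start = start,
               end = end, strand = strand, protein = strrep("M", 60),
               source = "annotated", stringsAsFactors = FALSE),
    hits = data.frame(), family_call = family_call)
  cand$validation_status <- status
  cand
}

genes_of <- function(cands) do.call(rbind, c(lapply(cands, `[[`, "gene"),
                                             make.row.names = FALSE))

hash_file <- function(path) unname(tools::md5sum(path))

# match recovered candidates against simulator truth by coordinates
match_truth <- function(cands, truth) {
  got <- vapply(cands, function(x)
    paste(x$gene$contig_id, x$gene$start, x$gene$end, x$gene$strand), "")
  want <- paste(truth$contig_id, truth$start, truth$end, truth$strand)
  list(got = got, want = want)
}
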