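#' Scan configuration
#'
#' All tunable parameters of the pipeline in one list, echoed verbatim into
#' `summary.json` for provenance.
#'
#' @param bits_threshold profile-hit acceptance threshold in bits
#'   (default 50).
#' @param window_size neighborhood window in bp (default 10000).
#' @param min_aa minimum ORF length in residues when no annotation is
#'   given (default 50).
#' @param pseudocount profile pseudocount mass (default 0.5).
#' @param gap_fraction_cutoff profile match-column gap cutoff (default 0.5).
#' @param gap_open,gap_extend profile-search gap penalties in bits.
#' @param ref_gap_open,ref_gap_extend reference-alignment (BLOSUM62) gap
#'   penalties.
#' @param calib_shuffles E-value calibration null size (>= 200).
#' @param seed seed for all randomness (calibration, simulation).
#' @param pab_regulatory_site TraR position of the PAB regulatory
#'   tryptophan (default 85; position 57 is reported alongside).
#' @return a `qs_config` list.
#' @export
qs_config <- function(bits_threshold = 50, window_size = 10000L,
                      min_aa = 50L, pseudocount = 0.5,
                      gap_fraction_cutoff = 0.5, gap_open = 4,
                      gap_extend = 0.5, ref_gap_open = 11,
                      ref_gap_extend = 1, calib_shuffles = 300L,
                      seed = 1L, pab_regulatory_site = 85L) {
  cfg <- list(bits_threshold = bits_threshold, window_size = as.integer(window_size),
              min_aa = as.integer(min_aa), pseudocount = pseudocount,
              gap_fraction_cutoff = gap_fraction_cutoff,
              gap_open = gap_open, gap_extend = gap_extend,
              ref_gap_open = ref_gap_open, ref_gap_extend = ref_gap_extend,
              calib_shuffles = as.integer(calib_shuffles),
              seed = as.integer(seed),
              pab_regulatory_site = as.integer(pab_regulatory_site))
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, TRUE)))
  structure(cfg, class = "qs_config")
}

annotate_candidate <- function(cand, config) {
  prot <- cand$gene$protein
  if (cand$family_call == "LUXI") {
    mp <- map_reference_numbering(align_to_reference(
      prot, reference_protein("TraI"),
      gap_open = config$ref_gap_open, gap_extend = config$ref_gap_extend))
    cand$residue_checks <- check_conserved_residues(mp, luxi_ruleset())
    cand$ref_name <- "TraI"
    cand <- validate_luxi(cand, bits_threshold = config$bits_threshold)
  } else if (cand$family_call == "LUXR") {
    cand <- validate_luxr(cand, bits_threshold = config$bits_threshold)
    mp <- map_reference_numbering(align_to_reference(
      prot, reference_protein("TraR"),
      gap_open = config$ref_gap_open, gap_extend = config$ref_gap_extend))
    cand$residue_checks <- check_conserved_residues(mp, luxr_ruleset())
    cand$ref_name <- "TraR"
    if (cand$validation_status == "VALID")
      cand$classification <- classify_luxr(
        cand$residue_checks,
        pab_regulatory_site = config$pab_regulatory_site)
  }
  cand
}

#' Run the full quorum-sensing gene scan
#'
#' Reads (or accepts) an assembly, obtains protein-coding genes from a GFF3
#' annotation or the built-in ORF finder, scores every protein against the
#' four packaged family profiles, validates candidates by domain
#' architecture (with the conserved-residue rescue for LuxI), maps
#' conserved residues in TraR/TraI numbering, classifies validated LuxR
#' proteins, and calls each validated luxR paired or solo by the
#' neighborhood window rule.
#'
#' @param fasta path to an assembly FASTA, or a named `DNAStringSet`.
#' @param gff3 optional GFF3 annotation path; without it ORFs are
#'   predicted.
#' @param config a [qs_config()].
#' @param out_dir optional directory for the report files
#'   (`candidates.tsv`, `validation.tsv`, `residues.tsv`, `solos.tsv`,
#'   `neighborhoods.tsv`, `qs_genes.gff3`, `summary.json`).
#' @return a `qs_run` list: `stats`, `genes`, `candidates`, `calls`,
#'   `summary`, `config`.
#' @export
qs_scan <- function(fasta, gff3 = NULL, config = qs_config(),
                    out_dir = NULL) {
  contigs <- if (is.character(fasta)) read_assembly(fasta) else fasta
  genes <- if (is.null(gff3)) find_orfs(contigs, min_aa = config$min_aa)
           else genes_from_gff3(contigs, gff3)
  stats <- assembly_stats(contigs)
  profiles <- qs_profiles(config)
  cands <- scan_proteins(genes, profiles,
                         bits_threshold = config$bits_threshold,
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
  cands <- lapply(cands, annotate_candidate, config = config)
  names(cands) <- vapply(cands, function(x) x$gene$gene_id, "")
  vstat <- vapply(cands, `[[`, "", "validation_status")
  fam <- vapply(cands, `[[`, "", "family_call")
  luxi <- cands[fam == "LUXI" &
                vstat %in% c("VALID", "VALID_BY_RESIDUE_RESCUE")]
  luxr <- cands[fam == "LUXR" & vstat == "VALID"]
  calls <- lapply(luxr, call_solo, validated_luxi = unname(luxi),
                  all_genes = genes, contigs = contigs,
                  window_size = config$window_size)
  summary <- summarize_calls(unname(calls), luxi = unname(luxi))
  run <- structure(list(stats = stats, genes = genes, candidates = cands,
                        calls = unname(calls), summary = summary,
                        config = config,
                        version = as.character(utils::packageVersion("qsmine"))),
                   class = "qs_run")
  if (!is.null(out_dir)) write_run_reports(run, contigs, out_dir)
  run
}

#' @export
print.qs_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("qs_run: %d genes scanned, %d candidates; ",
                     "%d luxI, %d luxR (%d paired, %d solo)\n"),
              nrow(x$genes), length(x$candidates), s$n_luxi, s$n_luxr,
              s$n_pairs, s$n_solos))
  invisible(x)
}

hits_table <- function(cands) {
  rows <- lapply(cands, function(cand)
    cbind(cand$hits,
          contig_id = cand$gene$contig_id, start = cand$gene$start,
          end = cand$gene$end, strand = cand$gene$strand))
  if (!length(rows))
    return(data.frame(gene_id = character(), family = character(),
                      bits = numeric(), evalue = numeric(),
                      q_start = integer(), q_end = integer(),
                      aligned_segment = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

validation_table <- function(cands) {
  rows <- lapply(cands, function(cand) {
    b <- function(fam) {
      h <- best_hit(cand, fam)
      if (is.null(h)) c(NA_real_, NA_real_) else c(h$bits, h$evalue)
    }
    v <- vapply(QS_FAMILIES, b, numeric(2))
    df <- data.frame(gene_id = cand$gene$gene_id,
                     family_call = cand$family_call)
    for (fam in QS_FAMILIES) {
      df[[paste0(tolower(fam), "_bits")]] <- v[1, fam]
      df[[paste0(tolower(fam), "_evalue")]] <- v[2, fam]
    }
    df$validation_status <- cand$validation_status
    df$reason <- cand$reason
    df
  })
  if (!length(rows)) {
    df <- data.frame(gene_id = character(), family_call = character())
    for (fam in QS_FAMILIES) {
      df[[paste0(tolower(fam), "_bits")]] <- numeric()
      df[[paste0(tolower(fam), "_evalue")]] <- numeric()
    }
    df$validation_status <- character(); df$reason <- character()
    return(df)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

residues_table <- function(cands) {
  rows <- lapply(cands, function(cand) {
    if (is.null(cand$residue_checks)) return(NULL)
    cbind(gene_id = cand$gene$gene_id, ref_name = cand$ref_name,
          cand$residue_checks,
          classification = if (is.null(cand$classification)) NA_character_
                           else cand$classification$label)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(gene_id = character(), ref_name = character(),
                      ref_pos = integer(), expected = character(),
                      region = character(), observed = character(),
                      status = character(), classification = character()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

solos_table <- function(calls) {
  if (!length(calls))
    return(data.frame(luxr_gene_id = character(), contig_id = character(),
                      status = character(), nearest_luxi = character(),
                      nearest_luxi_distance = integer(),
                      window_start = integer(), window_end = integer()))
  do.call(rbind, c(lapply(calls, function(x) data.frame(
    luxr_gene_id = x$luxr_gene_id, contig_id = x$neighborhood$contig_id,
    status = x$status,
    nearest_luxi = if (is.null(x$nearest_luxi)) NA_character_
                   else x$nearest_luxi$gene_id,
    nearest_luxi_distance = if (is.null(x$nearest_luxi)) NA_integer_
                            else x$nearest_luxi$distance,
    window_start = x$neighborhood$window_start,
    window_end = x$neighborhood$window_end)), make.row.names = FALSE))
}

neighborhoods_table <- function(calls, cands) {
  fam <- setNames(vapply(cands, `[[`, "", "family_call"),
                  vapply(cands, function(x) x$gene$gene_id, ""))
  if (!length(calls))
    return(data.frame(anchor_gene_id = character(), contig_id = character(),
                      window_start = integer(), window_end = integer(),
                      gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family_call = character()))
  do.call(rbind, c(lapply(calls, function(x) {
    g <- x$neighborhood$genes_in_window
    data.frame(anchor_gene_id = x$luxr_gene_id,
               contig_id = x$neighborhood$contig_id,
               window_start = x$neighborhood$window_start,
               window_end = x$neighborhood$window_end,
               gene_id = g$gene_id, start = g$start, end = g$end,
               strand = g$strand,
               family_call = ifelse(is.na(fam[g$gene_id]), "",
                                    fam[g$gene_id]))
  }), make.row.names = FALSE))
}

write_tsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

write_run_reports <- function(run, contigs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cands <- run$candidates
  write_tsv(hits_table(cands), file.path(out_dir, "candidates.tsv"))
  write_tsv(validation_table(cands), file.path(out_dir, "validation.tsv"))
  write_tsv(residues_table(cands), file.path(out_dir, "residues.tsv"))
  write_tsv(solos_table(run$calls), file.path(out_dir, "solos.tsv"))
  write_tsv(neighborhoods_table(run$calls, cands),
            file.path(out_dir, "neighborhoods.tsv"))
  st <- solos_table(run$calls)
  cg <- do.call(rbind, c(lapply(cands, function(x) x$gene),
                         make.row.names = FALSE))
  if (is.null(cg)) cg <- empty_genes()
  solo_status <- st$status[match(cg$gene_id, st$luxr_gene_id)]
  write_gff3(cg, file.path(out_dir, "qs_genes.gff3"),
             qs_family = vapply(cands, `[[`, "", "family_call"),
             validation_status = vapply(cands, `[[`, "", "validation_status"),
             solo_status = ifelse(is.na(solo_status), "none", solo_status))
  labels <- lapply(cands, function(x)
    if (is.null(x$classification)) NULL else x$classification$label)
  summary <- list(
    tool = "qsmine", version = run$version,
    assembly = as.list(run$stats),
    counts = c(list(n_genes = nrow(run$genes),
                    n_candidates = length(cands)),
               as.list(run$summary)),
    luxr_classifications = labels[!vapply(labels, is.null, TRUE)],
    config = unclass(run$config))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Structurally validate a run summary against the packaged schema
#'
#' Lightweight structural check (required keys and scalar types) of a
#' `summary.json` against `extdata/summary.schema.json`.
#'
#' @param summary path to a summary.json or the parsed list.
#' @return `TRUE` invisibly; errors describing the first violation.
#' @export
qs_check_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  schema <- jsonlite::read_json(system.file("extdata", "summary.schema.json",
                                            package = "qsmine",
                                            mustWork = TRUE))
  check <- function(obj, sch, where) {
    req <- unlist(sch$required)
    miss <- setdiff(req, names(obj))
    if (length(miss))
      stop("summary missing required key(s) at ", where, ": ",
           paste(miss, collapse = ", "))
    for (k in names(sch$properties)) {
      if (is.null(obj[[k]])) next
      tp <- sch$properties[[k]]$type
      ok <- switch(tp,
        object = is.list(obj[[k]]),
        string = is.character(obj[[k]]),
        number = is.numeric(obj[[k]]),
        integer = is.numeric(obj[[k]]) && obj[[k]] == round(obj[[k]]),
        TRUE)
      if (!ok) stop("summary key '", k, "' at ", where,
                    " is not of type ", tp)
      if (tp == "object" && !is.null(sch$properties[[k]]$properties))
        check(obj[[k]], sch$properties[[k]], paste0(where, "/", k))
    }
  }
  check(summary, schema, "/")
  invisible(TRUE)
}
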