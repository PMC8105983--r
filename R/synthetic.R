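#' Generate a random background contig
#'
#' I.i.d. bases at the stated GC content, deterministic for a given seed.
#'
#' @param length contig length in bp.
#' @param gc_percent target GC percentage (20-80).
#' @param seed RNG seed.
#' @return a `DNAStringSet` of one contig named `contig_1`.
#' @export
generate_background <- function(length, gc_percent, seed) {
  stopifnot(gc_percent >= 20, gc_percent <= 80, length >= 1)
  g <- gc_percent / 200
  seqs <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c(0.5 - g, g, g, 0.5 - g)), collapse = ""))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- "contig_1"
  out
}

# E. coli-style preferred codons for the most_frequent reverse-translation
# policy (fixed table; stop is TAA)
QS_PREFERRED_CODON <- c(
  A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGC", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAT")

synonymous_codons <- function() {
  if (is.null(.qs_cache$syn_codons)) {
    gc <- codon_table("11")
    .qs_cache$syn_codons <- split(names(gc), unname(gc))
  }
  .qs_cache$syn_codons
}

# reverse-translate a protein; caller is responsible for RNG state when
# policy is seeded_random_synonymous
reverse_translate <- function(protein,
                              codon_policy = c("seeded_random_synonymous",
                                               "most_frequent")) {
  codon_policy <- match.arg(codon_policy)
  aa <- strsplit(protein, "")[[1]]
  stopifnot(all(aa %in% QS_AA))
  codons <- if (codon_policy == "most_frequent") {
    QS_PREFERRED_CODON[aa]
  } else {
    syn <- synonymous_codons()
    vapply(aa, function(a) {
      cs <- syn[[a]]
      if (length(cs) == 1L) cs else sample(cs, 1L)
    }, "")
  }
  paste(codons, collapse = "")
}

#' Degapped protein sequence of a packaged seed member
#'
#' @param id member id, e.g. `"TraR_syn"`, `"LuxI_syn"` (the `_syn` suffix
#'   may be omitted).
#' @return amino-acid string.
#' @export
seed_member_protein <- function(id) {
  if (!grepl("_syn$", id)) id <- paste0(id, "_syn")
  for (fam in c("LUXR", "LUXI")) {
    aln <- seed_alignment(fam)
    if (id %in% names(aln))
      return(gsub("-", "", as.character(aln[[id]])))
  }
  stop("unknown seed member: ", id)
}

seed_member_family <- function(id) {
  if (!grepl("_syn$", id)) id <- paste0(id, "_syn")
  if (id %in% names(seed_alignment("LUXR"))) "LUXR"
  else if (id %in% names(seed_alignment("LUXI"))) "LUXI"
  else NA_character_
}

# apply mutations given in reference numbering (TraR/TraI) to a family
# member, mapping positions through the member-to-reference alignment
apply_reference_mutations <- function(protein, family, mutations) {
  if (is.null(mutations) || length(mutations) == 0L) return(protein)
  ref <- reference_protein(if (family == "LUXR") "TraR" else "TraI")
  mp <- map_reference_numbering(align_to_reference(protein, ref))
  aa <- strsplit(protein, "")[[1]]
  for (k in seq_along(mutations)) {
    rp <- as.integer(names(mutations)[k])
    cp <- mp$cand_pos[match(rp, mp$ref_pos)]
    if (is.na(cp)) stop("reference position ", rp,
                        " is deleted in the member; cannot mutate")
    aa[cp] <- mutations[[k]]
  }
  paste(aa, collapse = "")
}

#' Construct a genome specification for the simulator
#'
#' @param contig_lengths integer vector of contig lengths (bp).
#' @param gc_percent background GC percentage.
#' @param plants list of plant specs from [plant_spec()].
#' @param n_decoys number of random ORF-bearing decoy inserts that must not
#'   validate as QS genes.
#' @param seed RNG seed; the same spec and seed give byte-identical output.
#' @return a `qs_genome_spec` list.
#' @export
genome_spec <- function(contig_lengths, gc_percent = 50, plants = list(),
                        n_decoys = 0L, seed = 1L) {
  structure(list(n_contigs = length(contig_lengths),
                 contig_lengths = as.integer(contig_lengths),
                 gc_percent = gc_percent, plants = plants,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "qs_genome_spec")
}

#' @rdname genome_spec
#' @param protein_source a seed member id (see [seed_member_protein()]) or
#'   an explicit amino-acid string.
#' @param mutations named character vector, names = 1-based positions in
#'   reference (TraR/TraI) numbering, values = replacement residues.
#' @param contig_index 1-based contig to plant into.
#' @param insert_pos 0-based insertion offset on the contig.
#' @param strand `"+"` or `"-"`.
#' @param codon_policy `"seeded_random_synonymous"` or `"most_frequent"`.
#' @export
plant_spec <- function(protein_source, mutations = NULL, contig_index = 1L,
                       insert_pos = 1000L, strand = "+",
                       codon_policy = "seeded_random_synonymous") {
  stopifnot(strand %in% c("+", "-"))
  list(protein_source = protein_source, mutations = mutations,
       contig_index = as.integer(contig_index),
       insert_pos = as.integer(insert_pos), strand = strand,
       codon_policy = codon_policy)
}

plant_protein <- function(spec) {
  if (grepl("^[A-Z]{30,}$", spec$protein_source) &&
      !grepl("_syn$", spec$protein_source)) {
    prot <- spec$protein_source
    fam <- NA_character_
  } else {
    prot <- seed_member_protein(spec$protein_source)
    fam <- seed_member_family(spec$protein_source)
  }
  if (!is.null(spec$mutations)) {
    if (is.na(fam)) stop("reference-numbered mutations need a seed member")
    prot <- apply_reference_mutations(prot, fam, spec$mutations)
  }
  prot
}

#' Plant a gene into a contig
#'
#' Reverse-translates the (optionally mutated) protein under the codon
#' policy, appends a TAA stop, splices the construct in at `insert_pos`
#' honouring strand, and writes an in-frame TAA guard stop immediately
#' upstream so that the open reading frame recovered by [find_orfs()]
#' equals the planted protein exactly.  The caller controls RNG state (see
#' [make_assembly()]).
#'
#' @param contig_seq contig sequence as a character string.
#' @param spec a [plant_spec()].
#' @param gene_id id for the truth record.
#' @return list `contig_seq` (modified) and `truth` (one GeneModel row with
#'   the planted protein).
#' @export
plant_gene <- function(contig_seq, spec, gene_id = "plant_1") {
  prot <- plant_protein(spec)
  dna <- paste0(reverse_translate(prot, spec$codon_policy), "TAA")
  nlen <- nchar(dna)
  L <- nchar(contig_seq)
  if (spec$insert_pos + nlen > L)
    stop("plant does not fit: insert_pos ", spec$insert_pos,
         " + ", nlen, " > contig length ", L)
  if (spec$strand == "-") dna <- revcomp_chr(dna)
  substr(contig_seq, spec$insert_pos + 1L, spec$insert_pos + nlen) <- dna
  # in-frame guard stop upstream of the gene (downstream in contig
  # coordinates for minus-strand plants)
  if (spec$strand == "+" && spec$insert_pos >= 3L)
    substr(contig_seq, spec$insert_pos - 2L, spec$insert_pos) <- "TAA"
  if (spec$strand == "-" && spec$insert_pos + nlen + 3L <= L)
    substr(contig_seq, spec$insert_pos + nlen + 1L,
           spec$insert_pos + nlen + 3L) <- "TTA"
  truth <- data.frame(gene_id = gene_id, contig_id = NA_character_,
                      start = spec$insert_pos,
                      end = spec$insert_pos + nlen,
                      strand = spec$strand, protein = prot,
                      source = "planted", stringsAsFactors = FALSE)
  list(contig_seq = contig_seq, truth = truth)
}

#' Build a synthetic assembly with ground truth
#'
#' Generates background contigs at the spec's GC content, splices in every
#' plant (erroring on overlaps), adds `n_decoys` random ORF-bearing decoy
#' inserts at free positions, and optionally writes `assembly.fna`,
#' `truth.gff3` and `spec-echo.json` to `out_dir`.  Byte-reproducible for a
#' given spec and seed.
#'
#' @param spec a [genome_spec()].
#' @param out_dir optional output directory.
#' @return list `contigs` (`DNAStringSet`), `truth` (GeneModel
#'   `data.frame` with a `truth_family` column), `spec`.
#' @export
make_assembly <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "qs_genome_spec"))
  with_seed(spec$seed, {
    seqs <- vapply(spec$contig_lengths, function(L) {
      g <- spec$gc_percent / 200
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.5 - g, g, g, 0.5 - g)), collapse = "")
    }, "")
    names(seqs) <- sprintf("contig_%d", seq_along(seqs))
    occupied <- lapply(seqs, function(x) NULL) # per-contig [start,end) list
    truths <- list()
    claim <- function(ci, s, e) {
      for (iv in occupied[[ci]]) if (s < iv[2] && iv[1] < e)
        stop("insertion region overlaps a previous plant on contig ", ci)
      occupied[[ci]][[length(occupied[[ci]]) + 1L]] <<- c(s, e)
    }
    for (k in seq_along(spec$plants)) {
      ps <- spec$plants[[k]]
      ci <- ps$contig_index
      pl <- plant_gene(seqs[[ci]], ps, gene_id = sprintf("plant_%d", k))
      # the guard stop sits upstream of the gene: left of a "+" plant,
      # right of a "-" plant
      claim(ci, ps$insert_pos - (if (ps$strand == "+") 3L else 0L),
            pl$truth$end + (if (ps$strand == "-") 3L else 0L))
      seqs[[ci]] <- pl$contig_seq
      pl$truth$contig_id <- names(seqs)[ci]
      fam <- if (grepl("^[A-Z]{30,}$", ps$protein_source) &&
                 !grepl("_syn$", ps$protein_source)) NA_character_
             else seed_member_family(ps$protein_source)
      pl$truth$truth_family <- fam
      pl$truth$truth_source <- ps$protein_source
      pl$truth$mutations <- if (is.null(ps$mutations)) "" else
        paste(names(ps$mutations), ps$mutations, sep = ">", collapse = ",")
      truths[[k]] <- pl$truth
    }
    for (k in seq_len(spec$n_decoys)) {
      prot <- paste(c("M", sample(QS_AA, sample(120:250, 1), replace = TRUE,
                                  prob = QS_BACKGROUND)), collapse = "")
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample(spec$n_contigs, 1)
        nlen <- 3L * (nchar(prot) + 1L)
        if (spec$contig_lengths[ci] < nlen + 10L) next
        pos <- sample(3:(spec$contig_lengths[ci] - nlen - 3L), 1)
        free <- !any(vapply(occupied[[ci]], function(iv)
          pos - 3L < iv[2] && iv[1] < pos + nlen + 3L, TRUE))
        if (!free) next
        ds <- plant_spec(prot, contig_index = ci, insert_pos = pos,
                         strand = sample(c("+", "-"), 1))
        ds$protein_source <- prot
        pl <- plant_gene(seqs[[ci]], ds, gene_id = sprintf("decoy_%d", k))
        claim(ci, pos - 3L, pl$truth$end + 3L)
        seqs[[ci]] <- pl$contig_seq
        pl$truth$contig_id <- names(seqs)[ci]
        pl$truth$truth_family <- "DECOY"
        pl$truth$truth_source <- "random"
        pl$truth$mutations <- ""
        truths[[length(truths) + 1L]] <- pl$truth
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place decoy ", k, " after 200 tries")
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    truth <- if (length(truths)) do.call(rbind, truths) else cbind(
      empty_genes(), truth_family = character(), truth_source = character(),
      mutations = character())
    out <- list(contigs = contigs, truth = truth, spec = spec)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(contigs, file.path(out_dir, "assembly.fna"),
                                  width = 80)
      write_gff3(truth, file.path(out_dir, "truth.gff3"),
                 qs_family = truth$truth_family)
      jsonlite::write_json(spec_to_list(spec),
                           file.path(out_dir, "spec-echo.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    out
  })
}

spec_to_list <- function(spec) {
  x <- unclass(spec)
  x$plants <- lapply(x$plants, function(p) {
    p$mutations <- if (is.null(p$mutations)) list() else as.list(p$mutations)
    p
  })
  x
}

#' Read a genome spec from JSON
#'
#' @param path JSON file as written to `spec-echo.json`.
#' @return a `qs_genome_spec`.
#' @export
genome_spec_from_json <- function(path) {
  x <- jsonlite::read_json(path)
  plants <- lapply(x$plants, function(p) {
    mut <- if (length(p$mutations)) {
      setNames(vapply(p$mutations, as.character, ""), names(p$mutations))
    } else NULL
    plant_spec(p$protein_source, mutations = mut,
               contig_index = p$contig_index, insert_pos = p$insert_pos,
               strand = p$strand, codon_policy = p$codon_policy)
  })
  genome_spec(unlist(x$contig_lengths), gc_percent = x$gc_percent,
              plants = plants, n_decoys = x$n_decoys, seed = x$seed)
}

#' Paper-patterned example genome specs
#'
#' `genome_spec_sd316_like()` mirrors the QS content of an assembly with
#' three luxR solos and no luxI (one solo with the PAB-signature
#' substitutions 85M + 61W, one with the novel 85R, one with 113T).
#' `genome_spec_sd129_like()` mirrors an assembly with one adjacent
#' luxI-luxR pair plus two luxR solos.  Both use three 60 kb contigs at the
#' GC content of the corresponding strain and five decoy inserts.
#'
#' @param seed RNG seed for the background and codon choices.
#' @return a `qs_genome_spec`.
#' @export
genome_spec_sd316_like <- function(seed = 316L) {
  genome_spec(rep(60000L, 3), gc_percent = 53.52, seed = seed, n_decoys = 5L,
              plants = list(
                plant_spec("TraR_syn", c("85" = "M", "61" = "W"),
                           contig_index = 1L, insert_pos = 30000L),
                plant_spec("TraR_syn", c("85" = "R"),
                           contig_index = 2L, insert_pos = 20000L),
                plant_spec("TraR_syn", c("113" = "T"),
                           contig_index = 3L, insert_pos = 40000L,
                           strand = "-")))
}

#' Random genome spec with unmutated canonical plants
#'
#' Draws 1-4 (or `n_plants`) unmutated members from both packaged seed
#' families, places them at non-overlapping random positions and strands
#' across the contigs, and adds decoy inserts.  Used for planted-gene
#' recovery experiments: every plant should be recovered and validated,
#' and nothing else should.
#'
#' @param seed RNG seed (drives member choice, placement and background).
#' @param n_contigs,contig_length assembly shape (default 5 x 100 kb).
#' @param n_decoys decoy inserts (default 10).
#' @param n_plants number of plants; default uniform on 1-4.
#' @param gc_percent background GC.
#' @return a `qs_genome_spec`.
#' @export
random_qs_genome_spec <- function(seed, n_contigs = 5L,
                                  contig_length = 100000L, n_decoys = 10L,
                                  n_plants = NULL, gc_percent = 50) {
  members <- c(names(seed_alignment("LUXR")), names(seed_alignment("LUXI")))
  with_seed(seed, {
    if (is.null(n_plants)) n_plants <- sample(1:4, 1)
    claimed <- vector("list", n_contigs)
    plants <- vector("list", n_plants)
    margin <- 800L # generous upper bound on planted gene length + guards
    for (k in seq_len(n_plants)) {
      repeat {
        ci <- sample(n_contigs, 1)
        pos <- sample(seq(3000L, contig_length - 3000L - margin), 1)
        free <- !any(vapply(claimed[[ci]], function(iv)
          pos - margin < iv[2] && iv[1] < pos + margin, TRUE))
        if (free) break
      }
      claimed[[ci]][[length(claimed[[ci]]) + 1L]] <- c(pos, pos + margin)
      plants[[k]] <- plant_spec(sample(members, 1), contig_index = ci,
                                insert_pos = pos,
                                strand = sample(c("+", "-"), 1))
    }
    genome_spec(rep(as.integer(contig_length), n_contigs),
                gc_percent = gc_percent, plants = plants,
                n_decoys = n_decoys, seed = sample.int(1e6, 1))
  })
}

#' @rdname genome_spec_sd316_like
#' @export
genome_spec_sd129_like <- function(seed = 129L) {
  # the luxI-luxR pair is adjacent (convergent, CDS intervals touching)
  luxi_len <- 3L * (nchar(seed_member_protein("LuxI_syn")) + 1L)
  genome_spec(rep(60000L, 3), gc_percent = 53.62, seed = seed, n_decoys = 5L,
              plants = list(
                plant_spec("LuxI_syn", contig_index = 1L,
                           insert_pos = 30000L, strand = "+"),
                plant_spec("TraR_syn", contig_index = 1L,
                           insert_pos = 30000L + luxi_len, strand = "-"),
                plant_spec("TraR_syn", c("113" = "V"),
                           contig_index = 2L, insert_pos = 20000L),
                plant_spec("TraR_syn", contig_index = 3L,
                           insert_pos = 15000L, strand = "-")))
}
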