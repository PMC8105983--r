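traR <- reference_protein("TraR")
traI <- reference_protein("TraI")

test_that("self-alignment gives identity mapping for both references", {
  for (ref in list(traR, traI)) {
    al <- align_to_reference(ref$seq, ref)
    expect_true(all(al$columns[, 1] == al$columns[, 2]))
    mp <- map_reference_numbering(al)
    expect_equal(mp$ref_pos, seq_len(nchar(ref$seq)))
    expect_equal(mp$cand_pos, seq_len(nchar(ref$seq)))
    expect_equal(paste(mp$observed, collapse = ""), ref$seq)
  }
})

test_that("N-terminal extension shifts the mapping by its length", {
  ext <- paste0(strrep("A", 10), traR$seq)
  al <- align_to_reference(ext, traR)
  # one leading insertion of length 10
  expect_equal(al$columns[1:10, 1], rep(0L, 10))
  mp <- map_reference_numbering(al)
  expect_equal(mp$cand_pos, seq_len(nchar(traR$seq)) + 10L)
})

test_that("deletions map to gaps and agree with an independent aligner", {
  aa <- strsplit(traR$seq, "")[[1]]
  del <- paste(aa[-(58:60)], collapse = "")
  al <- align_to_reference(del, traR)
  mp <- map_reference_numbering(al)
  expect_equal(sum(mp$observed == "-"), 3L)
  expect_true(all(mp$observed[c(57, 61)] == aa[c(57, 61)]))
  # monotone over non-gap entries
  expect_true(all(diff(mp$cand_pos[!is.na(mp$cand_pos)]) > 0))

  # independent oracle: Biostrings global aligner, same scoring scheme
  sm <- qsmine:::blosum62()
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(del), Biostrings::AAString(traR$seq),
    type = "global", substitutionMatrix = sm,
    gapOpening = 11, gapExtension = 1)
  expect_equal(al$score, Biostrings::score(pw))
})

test_that("alignment score matches the independent aligner on mutants", {
  set.seed(202)
  for (rep in 1:5) {
    aa <- strsplit(traR$seq, "")[[1]]
    mut <- sample(length(aa), 12)
    aa[mut] <- vapply(aa[mut], function(x) sample(setdiff(AA20, x), 1), "")
    if (rep > 2) aa <- aa[-sample(20:200, 4)] # also drop some residues
    cand <- paste(aa, collapse = "")
    al <- align_to_reference(cand, traR)
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(cand), Biostrings::AAString(traR$seq),
      type = "global", substitutionMatrix = qsmine:::blosum62(),
      gapOpening = 11, gapExtension = 1)
    expect_equal(al$score, Biostrings::score(pw))
  }
})

mutate_ref <- function(ref, subs) {
  aa <- strsplit(ref$seq, "")[[1]]
  aa[as.integer(names(subs))] <- subs
  paste(aa, collapse = "")
}

checks_for <- function(protein) {
  check_conserved_residues(
    map_reference_numbering(align_to_reference(protein, traR)),
    luxr_ruleset())
}

test_that("conserved-residue checks recover planted substitution patterns", {
  # the reference satisfies its own consensus
  ck0 <- checks_for(traR$seq)
  expect_equal(nrow(ck0), 9L)
  expect_true(all(ck0$status == "match"))

  # W85M + Y61W, the PAB-solo pattern
  ck1 <- checks_for(mutate_ref(traR, c("85" = "M", "61" = "W")))
  expect_equal(sum(ck1$status == "substitution"), 2L)
  expect_equal(ck1$observed[ck1$ref_pos == 85], "M")
  expect_equal(ck1$observed[ck1$ref_pos == 61], "W")
  expect_equal(sum(ck1$status == "match"), 7L)

  # W85R and G113V
  ck2 <- checks_for(mutate_ref(traR, c("85" = "R", "113" = "V")))
  expect_equal(ck2$observed[ck2$ref_pos == 85], "R")
  expect_equal(ck2$observed[ck2$ref_pos == 113], "V")
  expect_equal(sum(ck2$status == "substitution"), 2L)

  # statuses always partition the rule set
  for (ck in list(ck0, ck1, ck2)) {
    expect_equal(nrow(ck), nrow(luxr_ruleset()))
    expect_true(all(ck$status %in% c("match", "substitution", "gap")))
  }
  # gap status where a deletion spans a conserved site
  aa <- strsplit(traR$seq, "")[[1]]
  ckg <- checks_for(paste(aa[-(84:86)], collapse = ""))
  expect_equal(ckg$status[ckg$ref_pos == 85], "gap")

  expect_error(
    check_conserved_residues(
      map_reference_numbering(align_to_reference(traR$seq, traR)),
      data.frame(ref_pos = 999L, expected = "W", region = "ligand_binding")),
    "beyond")
})

test_that("classify_luxr assigns the documented labels", {
  expect_equal(classify_luxr(checks_for(traR$seq))$label,
               "CANONICAL_CONSENSUS")
  expect_equal(
    classify_luxr(checks_for(mutate_ref(traR, c("85" = "M", "61" = "W"))))$label,
    "PAB_SIGNATURE")
  expect_equal(classify_luxr(checks_for(mutate_ref(traR, c("85" = "R"))))$label,
               "NOVEL_SUBSTITUTION")
  expect_equal(classify_luxr(checks_for(mutate_ref(traR, c("113" = "V"))))$label,
               "NOVEL_SUBSTITUTION")
  expect_equal(classify_luxr(checks_for(mutate_ref(traR, c("113" = "T"))))$label,
               "NOVEL_SUBSTITUTION")
  # DNA-binding substitutions never produce the PAB label
  dna_sub <- checks_for(mutate_ref(traR, c("182" = "A")))
  expect_equal(classify_luxr(dna_sub)$label, "MIXED")
  # purity: identical checks give identical labels
  ck <- checks_for(mutate_ref(traR, c("85" = "M", "61" = "W")))
  expect_identical(classify_luxr(ck), classify_luxr(ck))
  expect_error(classify_luxr(ck[-1, ]), "incomplete")
})

test_that("identity distances are symmetric, zero on self", {
  prots <- c(TraR = traR$seq, PAB = mutate_ref(traR, c("85" = "M")),
             TraI = traI$seq)
  d <- identity_distance_matrix(prots)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_lt(d["TraR", "PAB"], d["TraR", "TraI"])
})
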