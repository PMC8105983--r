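bg <- qsmine:::QS_BACKGROUND

test_that("build_profile implements the pseudocount column model", {
  # pseudocount -> 0 limit on identical rows: modal log-odds -> log2(1/bg)
  p <- build_profile(c("MKW", "MKW", "MKW", "MKW"), pseudocount = 1e-9)
  expect_equal(p$n_match_columns, 3L)
  expect_equal(unname(p$columns[1, "M"]), log2(1 / bg[["M"]]), tolerance = 1e-6)
  expect_equal(unname(p$columns[2, "K"]), log2(1 / bg[["K"]]), tolerance = 1e-6)
  expect_equal(unname(p$columns[3, "W"]), log2(1 / bg[["W"]]), tolerance = 1e-6)
  expect_equal(p$consensus, "MKW")

  # hand arithmetic: rows MK / MR, pseudocount 0.5, column 2
  p2 <- build_profile(c("MK", "MR"), pseudocount = 0.5)
  pk <- (1 + 0.5 * bg[["K"]]) / (2 + 0.5)
  pr <- (1 + 0.5 * bg[["R"]]) / (2 + 0.5)
  pa <- (0 + 0.5 * bg[["A"]]) / (2 + 0.5)
  expect_equal(unname(p2$columns[2, "K"]), log2(pk / bg[["K"]]))
  expect_equal(unname(p2$columns[2, "R"]), log2(pr / bg[["R"]]))
  expect_equal(unname(p2$columns[2, "A"]), log2(pa / bg[["A"]]))
  # each column's implied probabilities sum to 1
  probs <- bg * 2^p2$columns[1, ]
  expect_equal(sum(probs), 1)

  # a 60%-gap column is excluded from the match columns
  rows <- c("MKW", "M-W", "M-W", "M-W", "MKW")
  p3 <- build_profile(rows, gap_fraction_cutoff = 0.5)
  expect_equal(p3$n_match_columns, 2L)
  expect_error(build_profile(character()), "empty")
  expect_error(build_profile(c("--", "--")), "gap fraction")
})

test_that("score_protein attains the consensus maximum and hand sums", {
  seed <- c("MKWLE", "MKWIE", "MRWLE", "MKWLD")
  p <- build_profile(seed, pseudocount = 0.5)
  hit <- score_protein(p, paste0(p$consensus, "AAAAA"))
  expect_equal(hit$bits, sum(apply(p$columns, 1, max)))
  expect_equal(hit$q_start, 0L)
  expect_equal(hit$q_end, p$n_match_columns)
  expect_equal(hit$aligned_segment, p$consensus)

  # 3-column toy profile, no gaps: bits equal the hand-summed log-odds
  # (columns hold 4xM, 3xK + 1xR, 3xW + 1xF across the four rows)
  p3 <- build_profile(c("MKW", "MKW", "MRW", "MKF"), pseudocount = 0.5)
  hand <- sum(log2((c(4, 3, 3) + 0.5 * bg[c("M", "K", "W")]) / 4.5 /
                   bg[c("M", "K", "W")]))
  expect_equal(score_protein(p3, "MKWGGGGGGG")$bits, unname(hand),
               tolerance = 1e-9)

  # single-point mutants never beat the consensus
  cons <- p$consensus
  set.seed(42)
  for (i in seq_len(nchar(cons))) {
    mut <- cons
    substr(mut, i, i) <- sample(setdiff(AA20, substr(cons, i, i)), 1)
    expect_lte(score_protein(p, paste0(mut, "AAAAA"))$bits,
               sum(apply(p$columns, 1, max)))
  }
})

test_that("hits are invariant to sequence outside the reported envelope", {
  pr <- qs_profiles(qs_config())
  core <- seed_member_protein("TraR")
  set.seed(8)
  h0 <- score_protein(pr$LUXR_AUTOIND_BIND, core)
  flank1 <- paste0(random_protein(30), core)
  h1 <- score_protein(pr$LUXR_AUTOIND_BIND, flank1)
  expect_equal(h1$bits, h0$bits)
  expect_equal(h1$q_start, h0$q_start + 30L)
  expect_equal(h1$aligned_segment, h0$aligned_segment)
})

test_that("calibration is deterministic and E-values behave", {
  p <- build_profile(qsmine:::seed_for_family("LUXI_CONSERVED_SITE"),
                     family = "LUXI_CONSERVED_SITE")
  c1 <- calibrate_evalue(p, n_shuffles = 250, seed = 7)
  c2 <- calibrate_evalue(p, n_shuffles = 250, seed = 7)
  expect_identical(c1$calib, c2$calib)
  expect_gt(c1$calib$lambda, 0)
  expect_error(calibrate_evalue(p, n_shuffles = 100), ">= 200")

  # E-values strictly decreasing in bits
  ev <- qsmine:::profile_evalue(c1, c(10, 20, 30, 60), db_size = 1000)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev > 0))

  # consensus e-value far below the shuffled median
  cons_bits <- score_protein(c1, c1$consensus)$bits
  set.seed(99)
  med_bits <- median(qsmine:::.profile_score_many(
    c1$columns, vapply(1:50, function(i) random_protein(300), ""),
    4, 0.5, qsmine:::QS_X_SCORE))
  expect_lt(qsmine:::profile_evalue(c1, cons_bits),
            qsmine:::profile_evalue(c1, med_bits))
})

test_that("the Gumbel fit tracks the empirical null tail", {
  p <- calibrate_evalue(
    build_profile(qsmine:::seed_for_family("LUXI_CONSERVED_SITE"),
                  family = "LUXI_CONSERVED_SITE"),
    n_shuffles = 500, seed = 11)
  set.seed(2024)
  fresh <- qsmine:::.profile_score_many(
    p$columns,
    vapply(1:10000, function(i) random_protein(300, prob = bg[AA20]), ""),
    4, 0.5, qsmine:::QS_X_SCORE)
  s99 <- unname(quantile(fresh, 0.99))
  emp <- mean(fresh >= s99)
  gumbel <- 1 - exp(-exp(-p$calib$lambda * (s99 - p$calib$mu)))
  expect_gt(gumbel, emp * 0.5)
  expect_lt(gumbel, emp * 1.5)
})

test_that("scan_proteins recovers planted members and rejects noise", {
  cfg <- qs_config()
  pr <- qs_profiles(cfg)
  genes <- data.frame(
    gene_id = c("luxr", "luxi", "junk"),
    contig_id = "c1", start = c(0L, 2000L, 4000L),
    end = c(705L, 2636L, 4903L), strand = "+",
    protein = c(seed_member_protein("TraR"), seed_member_protein("LuxI"),
                {set.seed(31); random_protein(300)}),
    source = "annotated", stringsAsFactors = FALSE)
  cands <- scan_proteins(genes, pr, bits_threshold = cfg$bits_threshold)
  expect_length(cands, 2L)
  calls <- vapply(cands, `[[`, "", "family_call")
  ids <- vapply(cands, function(x) x$gene$gene_id, "")
  expect_equal(sort(paste(ids, calls)), c("luxi LUXI", "luxr LUXR"))
  luxr_hit_fams <- cands[[which(ids == "luxr")]]$hits
  expect_true(all(c("LUXR_AUTOIND_BIND", "LUXR_HTH") %in%
                  luxr_hit_fams$family[luxr_hit_fams$bits >= 50]))
  # degenerate threshold
  expect_length(scan_proteins(genes, pr, bits_threshold = Inf), 0L)
})
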