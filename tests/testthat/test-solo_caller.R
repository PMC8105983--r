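contig50 <- Biostrings::DNAStringSet(c(ctgA = strrep("A", 50000),
                                       ctgB = strrep("A", 50000)))

gene_row <- function(id, ctg, start, end, strand = "+")
  data.frame(gene_id = id, contig_id = ctg, start = start, end = end,
             strand = strand, protein = strrep("M", 60),
             source = "annotated", stringsAsFactors = FALSE)

test_that("extract_neighborhood centers, clips and collects overlaps", {
  anchor <- gene_row("r1", "ctgA", 24000, 24700)
  others <- rbind(anchor,
                  gene_row("near", "ctgA", 20000, 20600),
                  gene_row("far", "ctgA", 40000, 40600),
                  gene_row("other", "ctgB", 24000, 24700))
  nb <- extract_neighborhood(anchor, others, contig50)
  expect_equal(nb$window_end - nb$window_start, 10000L)
  mid <- (24000 + 24700) %/% 2
  expect_equal(c(nb$window_start, nb$window_end), c(mid - 5000L, mid + 5000L))
  expect_setequal(nb$genes_in_window$gene_id, c("r1", "near"))

  # clipped at the contig start
  a2 <- gene_row("r2", "ctgA", 1500, 2500)
  nb2 <- extract_neighborhood(a2, rbind(others, a2), contig50)
  expect_equal(nb2$window_start, 0L)
  expect_equal(nb2$window_end, 2000L %/% 1L + 5000L)

  expect_error(extract_neighborhood(gene_row("x", "ctgA", 0, 9), others,
                                    contig50), "anchor")
})

test_that("in-window membership equals a brute-force overlap scan", {
  set.seed(904)
  for (rep in 1:20) {
    genes <- do.call(rbind, lapply(1:40, function(i) {
      st <- sample(0:49000, 1)
      gene_row(paste0("g", i), "ctgA", st, st + sample(300:900, 1))
    }))
    anchor <- genes[sample(nrow(genes), 1), ]
    nb <- extract_neighborhood(anchor, genes, contig50)
    inwin <- vapply(seq_len(nrow(genes)), function(i)
      genes$start[i] < nb$window_end && genes$end[i] > nb$window_start,
      TRUE)
    expect_setequal(nb$genes_in_window$gene_id, genes$gene_id[inwin])
  }
})

test_that("call_solo pairs by window overlap with exact boundaries", {
  luxr <- fake_candidate("r1", "ctgA", 24000, 24700)
  genes <- genes_of(list(luxr))
  # adjacent divergent luxI: paired at distance 0
  luxi_adj <- fake_candidate("i1", "ctgA", 23300, 24000, "-", "LUXI")
  call <- call_solo(luxr, list(luxi_adj), rbind(genes, genes_of(list(luxi_adj))),
                    contig50)
  expect_equal(call$status, "paired")
  expect_equal(call$nearest_luxi$distance, 0L)

  # luxI on another contig never pairs
  luxi_other <- fake_candidate("i2", "ctgB", 24000, 24700, "+", "LUXI")
  call2 <- call_solo(luxr, list(luxi_other),
                     rbind(genes, genes_of(list(luxi_other))), contig50)
  expect_equal(call2$status, "solo")
  expect_null(call2$nearest_luxi)

  # boundary sweep against a brute-force window-overlap oracle
  mid <- (24000 + 24700) %/% 2
  win <- c(mid - 5000L, mid + 5000L)
  set.seed(55)
  offsets <- sample((win[2] - 700L - 30L):(win[2] + 30L), 200, replace = TRUE)
  for (st in offsets) {
    li <- fake_candidate("iB", "ctgA", st, st + 700L, "+", "LUXI")
    got <- call_solo(luxr, list(li), rbind(genes, genes_of(list(li))),
                     contig50)$status
    want <- if (st < win[2] && st + 700L > win[1]) "paired" else "solo"
    expect_equal(got, want)
  }
  # exact edge: 1 bp overlap pairs, 0 bp overlap does not
  at_edge <- fake_candidate("iE", "ctgA", win[2] - 1L, win[2] + 699L, "+", "LUXI")
  past_edge <- fake_candidate("iF", "ctgA", win[2], win[2] + 700L, "+", "LUXI")
  expect_equal(call_solo(luxr, list(at_edge),
                         rbind(genes, genes_of(list(at_edge))),
                         contig50)$status, "paired")
  expect_equal(call_solo(luxr, list(past_edge),
                         rbind(genes, genes_of(list(past_edge))),
                         contig50)$status, "solo")

  # unvalidated inputs are rejected
  invalid <- fake_candidate("bad", "ctgA", 100, 800, "+", "LUXI", "INVALID")
  expect_error(call_solo(luxr, list(invalid),
                         rbind(genes, genes_of(list(invalid))), contig50),
               "unvalidated")
  unval <- fake_candidate("r2", "ctgA", 24000, 24700, "+", "LUXR", "INVALID")
  expect_error(call_solo(unval, list(), genes_of(list(unval)), contig50),
               "VALID")
})

test_that("planting and removing a luxI flips solo <-> paired (monotone)", {
  set.seed(66)
  for (rep in 1:50) {
    rst <- sample(10000:40000, 1)
    luxr <- fake_candidate("r", "ctgA", rst, rst + 700L)
    base <- genes_of(list(luxr))
    mid <- (2L * rst + 700L) %/% 2L
    inside <- sample(max(0, mid - 5000L + 1L):(mid + 5000L - 701L), 1)
    li <- fake_candidate("i", "ctgA", inside, inside + 700L, "+", "LUXI")
    with_li <- call_solo(luxr, list(li), rbind(base, genes_of(list(li))),
                         contig50)
    without <- call_solo(luxr, list(), base, contig50)
    expect_equal(with_li$status, "paired")
    expect_equal(without$status, "solo")
  }
})

test_that("mirroring a contig preserves solo/paired status", {
  L <- 50000L
  set.seed(12)
  for (rep in 1:20) {
    rst <- sample(5000:44000, 1)
    ist <- sample(5000:44000, 1)
    luxr <- fake_candidate("r", "ctgA", rst, rst + 700L)
    li <- fake_candidate("i", "ctgA", ist, ist + 640L, "+", "LUXI")
    genes <- rbind(genes_of(list(luxr)), genes_of(list(li)))
    s1 <- call_solo(luxr, list(li), genes, contig50)$status
    # mirrored coordinates
    luxr_m <- fake_candidate("r", "ctgA", L - (rst + 700L), L - rst, "-")
    li_m <- fake_candidate("i", "ctgA", L - (ist + 640L), L - ist, "-", "LUXI")
    genes_m <- rbind(genes_of(list(luxr_m)), genes_of(list(li_m)))
    s2 <- call_solo(luxr_m, list(li_m), genes_m, contig50)$status
    expect_equal(s1, s2)
  }
})

test_that("summarize_calls counts pairs and solos consistently", {
  luxr1 <- fake_candidate("r1", "ctgA", 24000, 24700)
  luxi <- fake_candidate("i1", "ctgA", 23300, 24000, "-", "LUXI")
  luxr2 <- fake_candidate("r2", "ctgB", 10000, 10700)
  luxr3 <- fake_candidate("r3", "ctgB", 40000, 40700)
  genes <- genes_of(list(luxr1, luxi, luxr2, luxr3))
  calls <- lapply(list(luxr1, luxr2, luxr3), call_solo,
                  validated_luxi = list(luxi), all_genes = genes,
                  contigs = contig50)
  s <- summarize_calls(calls, luxi = list(luxi))
  expect_equal(unlist(s), c(n_luxi = 1, n_luxr = 3, n_pairs = 1, n_solos = 2))
  expect_equal(s$n_pairs + s$n_solos, s$n_luxr)
  # empty call set
  expect_equal(unlist(summarize_calls(list())),
               c(n_luxi = 0, n_luxr = 0, n_pairs = 0, n_solos = 0))
})
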