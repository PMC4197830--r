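# HighD / LowD scans, QC filter, dedup, matched controls.

mk_scores <- function(score, pos = seq_along(score) * 10L, chrom = "c1") {
  n <- length(score)
  data.frame(chrom = rep(chrom, n), pos = pos,
             ref = rep("A", n), alt = rep("C", n),
             vclass = rep("SNP", n), score = score,
             ddaf = score, pair = rep("A-B", n), stringsAsFactors = FALSE)
}

test_that("qc_filter keeps sites strictly above the quality cutoff", {
  sc <- mk_scores(c(0.9, 0.8, 0.7))
  sc$impq <- c(0.9, 0.8, 0.7)
  out <- qc_filter(sc, 0.8)
  expect_equal(nrow(out), 1)            # strict inequality: 0.8 removed
  expect_equal(out$impq, 0.9)
  sc$impq <- NA_real_
  expect_warning(out2 <- qc_filter(sc, 0.8), "missing")
  expect_equal(nrow(out2), 3)
  out3 <- suppressWarnings(qc_filter(sc, 0.8, strict = TRUE))
  expect_equal(nrow(out3), 0)
  expect_equal(nrow(qc_filter(sc[0, ], 0.8)), 0)
})

test_that("highd_scan reproduces the 12-site worked example exactly", {
  sc <- mk_scores(c(.1, .95, .2, .9, .3, .2, .1, .05, .72, .1, .2, .71))
  cfg <- scan_config(top_percentile = 25, thresh_between = 0.7)
  res <- highd_scan(sc, cfg, level = "between", window_size = 4)
  # top-25% marks sites 2, 4, 9; window maxima: .95 (site 2), none, .72
  # (site 9); both exceed 0.7 -> sites 2 and 9 retained
  expect_equal(res$sites$pos, sc$pos[c(2, 9)])
  expect_equal(res$sites$score, c(0.95, 0.72))
})

test_that("highd_scan degenerate and threshold cases", {
  cfg <- scan_config()
  one <- highd_scan(mk_scores(0.8), cfg, "between", window_size = 10)
  expect_equal(nrow(one$sites), 1)      # single site above threshold
  low <- highd_scan(mk_scores(rep(0.5, 20)), cfg, "between", window_size = 5)
  expect_equal(nrow(low$sites), 0)      # all below threshold
  expect_equal(nrow(highd_scan(mk_scores(numeric(0)), cfg, "between")$sites), 0)
  expect_error(highd_scan(mk_scores(c(.1, .2), pos = c(20L, 10L)), cfg,
                          "between"), "genomic order")
})

test_that("threshold-only mode applies no windowing (exomic-INDEL style)", {
  sc <- mk_scores(c(0.8, 0.75, 0.2, 0.9))
  res <- highd_scan(sc, scan_config(), "between", mode = "threshold")
  expect_equal(nrow(res$sites), 3)
})

test_that("highd_scan retains at most one window argmax per block", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    ws <- sample(c(7, 13, 25), 1)
    sc <- mk_scores(runif(n))
    cfg <- scan_config(top_percentile = 10, thresh_between = 0.2)
    res <- highd_scan(sc, cfg, "between", window_size = ws)
    expect_lte(nrow(res$sites), ceiling(n / ws))
    # every retained site is the maximum marked score of its block
    rp <- rank_pvalues(sc)
    marked <- rp$rank <= ceiling(n * 0.10)
    blk <- (seq_len(n) - 1) %/% ws
    for (j in seq_len(nrow(res$sites))) {
      b <- blk[match(res$sites$pos[j], sc$pos)]
      expect_equal(res$sites$score[j], max(sc$score[marked & blk == b]))
    }
    # invariance to shuffling once re-sorted
    perm <- sample(n)
    sc2 <- sc[perm, ]
    sc2 <- sc2[order(sc2$chrom, sc2$pos), ]
    rownames(sc2) <- NULL
    res2 <- highd_scan(sc2, cfg, "between", window_size = ws)
    expect_equal(res2$sites$pos, res$sites$pos)
  }
})

test_that("lowd_scan applies the printed band and exclusion semantics", {
  pooled <- c(0.39, 0.40, 0.45, 0.50, 0.55, 0.60, 0.61)
  n <- length(pooled)
  daf_m <- matrix(rep(pooled, 3), ncol = 3)
  colnames(daf_m) <- paste0("P", 1:3)
  ft <- structure(list(daf = daf_m,
                       sites = data.frame(chrom = rep("c", n), pos = 1:n,
                                          ref = "A", alt = "C",
                                          vclass = "SNP"),
                       pooled = pooled), class = "frequency_table")
  res <- lowd_scan(ft, scan_config(window_lowd = 1))
  # 0.40, 0.45, 0.55, 0.60 admitted (cvDAF 0 < 0.01); 0.39/0.61 outside the
  # closed band; 0.50 inside the open exclusion interval
  expect_equal(res$sites$pooled_daf, c(0.40, 0.45, 0.55, 0.60))
  expect_equal(unname(res$drop_counts["outside_band"]), 2L)
  expect_equal(unname(res$drop_counts["in_exclusion"]), 1L)
})

test_that("lowd_scan keeps the window minimum iff below the cv threshold", {
  daf_m <- rbind(c(0.48, 0.52, 0.50),    # cv ~0.04
                 c(0.50, 0.50, 0.497),   # cv ~0.0035
                 c(0.50, 0.51, 0.493))   # cv ~0.017 -> not the window min
  colnames(daf_m) <- paste0("P", 1:3)
  ft <- structure(list(daf = daf_m,
                       sites = data.frame(chrom = rep("c", 3), pos = 1:3,
                                          ref = "A", alt = "C",
                                          vclass = "SNP"),
                       pooled = c(0.42, 0.43, 0.44)),
                  class = "frequency_table")
  res <- lowd_scan(ft, scan_config(window_lowd = 100))
  expect_equal(nrow(res$sites), 1)
  expect_equal(res$sites$pos, 2L)
  # raising the threshold above the window minimum only keeps the minimum
  res2 <- lowd_scan(ft, scan_config(window_lowd = 100, cv_thresh = 0.001))
  expect_equal(nrow(res2$sites), 0)
})

test_that("dedup_union keys by site and concatenates pair labels", {
  a <- mk_scores(c(0.8, 0.9), pos = c(10L, 20L)); a$pair <- "A-B"
  b <- mk_scores(c(0.7, 0.85), pos = c(20L, 30L)); b$pair <- "A-C"
  u <- dedup_union(list(a, b))
  expect_equal(nrow(u), 3)
  expect_equal(u$pairs[u$pos == 20], "A-B,A-C")
  expect_equal(u$n_pairs[u$pos == 20], 2L)
  d1 <- mk_scores(runif(3), pos = c(1L, 2L, 3L)); d1$pair <- "A-B"
  d2 <- mk_scores(runif(4), pos = c(11L, 12L, 13L, 14L)); d2$pair <- "A-C"
  expect_equal(nrow(dedup_union(list(d1, d2))), 7)
})

test_that("matched_controls draws from the correct DAF and distance bins", {
  set.seed(3)
  universe <- data.frame(chrom = "c", pos = 1:500,
                         daf = runif(500),
                         gene_dist = sample(c(0, 500, 5e3, 5e4, 5e5), 500,
                                            replace = TRUE))
  targets <- data.frame(chrom = "c", pos = 1001L, daf = 0.80, gene_dist = 0)
  ctrl <- matched_controls(targets, universe, n_per_target = 5, seed = 9)
  expect_equal(nrow(ctrl), 5)
  expect_true(all(abs(ctrl$daf - 0.80) <= 0.05))
  expect_true(all(ctrl$gene_dist == 0))
  # determinism
  ctrl2 <- matched_controls(targets, universe, n_per_target = 5, seed = 9)
  expect_identical(ctrl, ctrl2)
  # impossible target reported unmatched
  t2 <- data.frame(chrom = "c", pos = 1002L, daf = 0.5, gene_dist = 2e6)
  universe2 <- universe[universe$gene_dist < 2e5, ]
  expect_warning(c3 <- matched_controls(t2, universe2, 1, seed = 1),
                 "matched")
  expect_equal(attr(c3, "unmatched"), 1L)
})
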