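# Haplotype extraction, weighted Levenshtein homogeneity, sweep calls and
# the chance-corrected excess.

test_that("extract_haplotypes aggregates carrier strings with frequencies", {
  # 10 identical carriers: no site varies among them -> one haplotype, f = 1
  H <- rbind(c(rep(1L, 10), rep(0L, 2)),
             c(rep(1L, 10), 0L, 0L),            # focal at pos 200
             c(rep(0L, 10), rep(1L, 2)))
  gts <- make_gts(H, pos = c(150L, 200L, 250L))
  hs <- suppressWarnings(extract_haplotypes(gts, 2, window_bp = 2000))
  expect_equal(nrow(hs$haps), 1)
  expect_equal(hs$haps$freq, 1)
  expect_equal(hs$n_carriers, 10)

  # 6 carriers: 4 of "01", 2 of "10" over two carrier-polymorphic sites
  H2 <- rbind(c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L),
              c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L),   # focal: carriers 1-6
              c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 0L))
  gts2 <- make_gts(H2, pos = c(150L, 200L, 250L))
  hs2 <- extract_haplotypes(gts2, 2, window_bp = 2000)
  expect_equal(hs2$haps$string, c("01", "10"))
  expect_equal(hs2$haps$freq, c(4 / 6, 2 / 6))
  expect_equal(hs2$major, "01")

  # degenerate: no flanking polymorphism among carriers
  H3 <- rbind(rep(1L, 4), c(1L, 1L, 0L, 0L))
  gts3 <- make_gts(H3, pos = c(150L, 200L))
  expect_warning(hs3 <- extract_haplotypes(gts3, 2, window_bp = 2000),
                 "degenerate")
  expect_true(hs3$degenerate)
  expect_equal(weighted_levenshtein(hs3), 0)
  expect_error(extract_haplotypes(make_gts(matrix(0L, 1, 4)), 1), "carriers")
})

test_that("major-haplotype ties break lexicographically", {
  # two haplotypes at equal frequency: "01" and "10"
  H <- rbind(c(0L, 0L, 1L, 1L),
             c(1L, 1L, 1L, 1L),
             c(1L, 1L, 0L, 0L))
  hs <- extract_haplotypes(make_gts(H, pos = c(150L, 200L, 250L)), 2)
  expect_equal(hs$major, "01")
})

test_that("weighted Levenshtein reproduces hand-computed cases", {
  mk_hs <- function(strings, counts) {
    haps <- data.frame(string = strings, count = counts,
                       freq = counts / sum(counts), stringsAsFactors = FALSE)
    haps <- haps[order(-haps$count, haps$string), ]
    structure(list(haps = haps, major = haps$string[1],
                   n_carriers = sum(counts), n_sites = nchar(strings[1]),
                   degenerate = FALSE), class = "haplotype_set")
  }
  # 50/50 differing at 1 of 10 sites -> 0.5 * 1/10 (tie: lexicographic major)
  hs <- mk_hs(c("0000000000", "0000000001"), c(5, 5))
  expect_equal(weighted_levenshtein(hs), 0.05)
  # f = (0.6, 0.3, 0.1), distances (0, 2, 5) over 20 sites -> 0.055
  base <- paste(rep("0", 20), collapse = "")
  h2 <- paste(c(rep("0", 18), "1", "1"), collapse = "")
  h3 <- paste(c(rep("1", 5), rep("0", 15)), collapse = "")
  hs2 <- mk_hs(c(base, h2, h3), c(6, 3, 1))
  expect_equal(weighted_levenshtein(hs2), (0.3 * 2 + 0.1 * 5) / 20)
  # renormalized-over-alternatives reading
  expect_equal(weighted_levenshtein(hs2, weighting = "alternatives"),
               (0.75 * 2 + 0.25 * 5) / 20)
  # single haplotype -> 0
  expect_equal(weighted_levenshtein(mk_hs("0101", 7)), 0)
})

test_that("weighted Levenshtein agrees with a DP edit-distance oracle on 200
           random haplotype sets", {
  set.seed(31)
  for (i in 1:200) {
    S <- sample(1:8, 1)
    nh <- sample(1:6, 1)
    strings <- unique(replicate(nh, paste(sample(c("0", "1"), S, TRUE),
                                          collapse = "")))
    counts <- sample(1:20, length(strings), replace = TRUE)
    haps <- data.frame(string = strings, count = counts,
                       freq = counts / sum(counts), stringsAsFactors = FALSE)
    haps <- haps[order(-haps$count, haps$string), ]
    hs <- structure(list(haps = haps, major = haps$string[1],
                         n_carriers = sum(counts), n_sites = S,
                         degenerate = FALSE), class = "haplotype_set")
    want <- sum(haps$freq * vapply(haps$string, lev_oracle, 0, a = haps$string[1])) / S
    expect_equal(weighted_levenshtein(hs), want, tolerance = 1e-12)
  }
})

test_that("the haplotype-set structure is invariant to allele relabeling and
           D to a global symbol swap", {
  # Flipping 0/1 at a column preserves the partition of carriers into
  # distinct haplotypes (counts, frequencies, number of haplotypes); the
  # full edit distance additionally tolerates a simultaneous swap at every
  # column (a symbol permutation). Note per-column flips can alter true
  # Levenshtein distances of the aligned strings, because insertions and
  # deletions may realign shifted patterns; only the substitution distance
  # is per-column invariant.
  set.seed(33)
  H <- matrix(rbinom(9 * 20, 1, 0.4), nrow = 9)
  H[5, ] <- rbinom(20, 1, 0.7)
  pos <- as.integer(seq(120, 280, 20))
  hs0 <- suppressWarnings(extract_haplotypes(make_gts(H, pos = pos), 5))
  H2 <- H
  H2[3, ] <- 1L - H2[3, ]               # relabel alleles at a flanking site
  hs1 <- suppressWarnings(extract_haplotypes(make_gts(H2, pos = pos), 5))
  expect_equal(hs1$haps$count, hs0$haps$count)
  expect_equal(hs1$haps$freq, hs0$haps$freq)
  expect_equal(hs1$n_sites, hs0$n_sites)
  H3 <- H
  flank <- setdiff(seq_len(9), 5)
  H3[flank, ] <- 1L - H3[flank, ]       # global swap at every flanking site
  hs3 <- suppressWarnings(extract_haplotypes(make_gts(H3, pos = pos), 5))
  expect_equal(weighted_levenshtein(hs3), weighted_levenshtein(hs0))
})

test_that("classify_sweep applies threshold and recombination conditioning
           with inclusive boundaries", {
  expect_equal(classify_sweep(0.001, 0.01)$classification, "hard-like")
  expect_equal(classify_sweep(0.183, 0.01)$classification, "not-hard-like")
  expect_equal(classify_sweep(0.026, 0.025)$classification, "hard-like")
  expect_equal(classify_sweep(0.0261, 0.025)$classification, "not-hard-like")
  expect_equal(classify_sweep(0.001, 0.026)$classification, "not-hard-like")
  expect_equal(classify_sweep(0.001, NA)$classification, "unclassifiable")
})

test_that("excess_hard_fraction reproduces the 66/36/30 arithmetic", {
  tg <- rep(c("hard-like", "not-hard-like"), c(33, 17))   # 66%
  ct <- rep(c("hard-like", "not-hard-like"), c(18, 32))   # 36%
  res <- excess_hard_fraction(tg, ct)
  expect_equal(res$obs_pct, 66)
  expect_equal(res$chance_pct, 36)
  expect_equal(res$excess_pct, 30)

  same <- rep(c("hard-like", "not-hard-like"), c(10, 10))
  res2 <- excess_hard_fraction(same, same)
  expect_equal(res2$excess_pct, 0)
  expect_gt(res2$fisher_p, 0.99)
  expect_error(excess_hard_fraction(character(), tg), "empty")
})

test_that("Fisher exact P matches hypergeometric enumeration", {
  tg <- rep(c("hard-like", "not-hard-like"), c(8, 2))
  ct <- rep(c("hard-like", "not-hard-like"), c(2, 8))
  res <- excess_hard_fraction(tg, ct)
  tab <- matrix(c(8, 2, 2, 8), 2)
  expect_equal(res$fisher_p, fisher_oracle(tab), tolerance = 1e-9)
  for (i in 1:20) {
    set.seed(40 + i)
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("simulated hard sweeps are more homogeneous than matched neutral
           sites", {
  m <- demographic_model()
  Dh <- c()
  for (i in 1:8) {
    r <- simulate_sweep(m, sweep_scenario(1.0, duration = 600, pop = "ASN"),
                        1e5, 50, seed = 600 + i)
    hs <- suppressWarnings(
      extract_haplotypes(r$gts, r$selected_index, 2000, r$panel, "ASN",
                         level = "continent"))
    Dh <- c(Dh, weighted_levenshtein(hs))
  }
  Dn <- c()
  for (i in 1:4) {
    r <- simulate_neutral(m, 1e5, 50, seed = 700 + i)
    ftc <- daf(r$gts, r$panel, "continent")
    cand <- which(ftc$daf[, "ASN"] > 0.6 & ftc$daf[, "ASN"] < 1)
    for (s in head(cand, 4)) {
      hs <- suppressWarnings(
        extract_haplotypes(r$gts, s, 2000, r$panel, "ASN",
                           level = "continent"))
      Dn <- c(Dn, weighted_levenshtein(hs))
    }
  }
  expect_gt(length(Dn), 5)
  expect_lt(mean(Dh), mean(Dn))
})
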