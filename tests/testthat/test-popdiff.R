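# DAF, delta-DAF, cvDAF, Weir-Cockerham FST, rank P-values, LD.

test_that("daf counts derived alleles over observed haplotypes per group", {
  # 3 populations x 8 haplotypes with 6, 2, 1 derived at one site
  H <- matrix(c(rep(1L, 6), rep(0L, 2),
                rep(1L, 2), rep(0L, 6),
                rep(1L, 1), rep(0L, 7)), nrow = 1)
  gts <- make_gts(H)
  panel <- make_panel_n(c(P1 = 4, P2 = 4, P3 = 4))
  ft <- daf(gts, panel)
  expect_equal(unname(ft$daf[1, c("P1", "P2", "P3")]), c(0.75, 0.25, 0.125))
  expect_equal(ft$pooled[1], 9 / 24)

  # one pop, 4 haplotypes, derived on 1 -> 0.25; all-ancestral -> 0
  gts2 <- make_gts(matrix(c(1L, 0L, 0L, 0L,
                            0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE))
  ft2 <- daf(gts2, make_panel_n(c(P1 = 2)))
  expect_equal(unname(ft2$daf[, "P1"]), c(0.25, 0))
})

test_that("missing genotypes reduce the denominator; empty groups go NA", {
  H <- matrix(c(1L, NA, 0L, 0L, NA, NA), nrow = 1)
  gts <- make_gts(H)
  panel <- make_panel_n(c(P1 = 2, P2 = 1))
  ft <- daf(gts, panel)
  expect_equal(unname(ft$daf[1, "P1"]), 1 / 3)
  expect_true(is.na(ft$daf[1, "P2"]))
})

test_that("delta_daf is signed with direction = higher-DAF group", {
  # frequencies mirroring the ABCA12 exemplar: 0.96 in ASN vs 0.13 in AFR
  H <- matrix(c(rep(1L, 48), rep(0L, 2),          # ASN 48/50
                rep(1L, 13), rep(0L, 87)), nrow = 1)  # AFR 13/100
  gts <- make_gts(H)
  panel <- make_panel(sprintf("S%02d", 1:75),
                      rep(c("ASN", "AFR"), c(25, 50)),
                      rep(c("ASN", "AFR"), c(25, 50)))
  ft <- daf(gts, panel, level = "continent")
  sc <- delta_daf(ft, c("ASN", "AFR"))
  expect_equal(sc$ddaf, 0.96 - 0.13)
  expect_equal(sc$direction, "ASN")

  H2 <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L,
                 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L), nrow = 2, byrow = TRUE)
  gts2 <- make_gts(H2)
  panel2 <- make_panel_n(c(A = 2, B = 2))
  ft2 <- daf(gts2, panel2)
  sc2 <- delta_daf(ft2, c("A", "B"))
  expect_equal(sc2$ddaf, c(-1, 0))                  # extreme and tie
  expect_equal(sc2$direction, c("B", NA))
  expect_equal(sc2$score, c(1, 0))
})

test_that("cv_daf is the sample-sd / mean of group DAFs", {
  daf_rows <- rbind(rep(0.5, 10), c(0.4, 0.5, 0.6, rep(NA, 7)),
                    c(0.5, 0.5, 0.45, rep(NA, 7)))
  ft <- list(daf = daf_rows,
             sites = data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "C",
                                vclass = "SNP"),
             pooled = c(0.5, 0.5, 0.48))
  class(ft) <- "frequency_table"
  colnames(ft$daf) <- paste0("P", 1:10)
  sc <- cv_daf(ft)
  expect_equal(sc$cvdaf[1], 0)
  expect_equal(sc$cvdaf[2], sd(c(0.4, 0.5, 0.6)) / 0.5)
  expect_equal(sc$cvdaf[2], 0.2)
  expect_equal(sc$cvdaf[3], sd(c(0.5, 0.5, 0.45)) / mean(c(0.5, 0.5, 0.45)),
               tolerance = 1e-12)
  expect_equal(round(sc$cvdaf[3], 4), 0.0597)
})

test_that("cv_daf is scale-free", {
  set.seed(7)
  for (i in 1:20) {
    v <- runif(10, 0.1, 0.9)
    c_ <- runif(1, 0.05, 1)
    ft <- list(daf = rbind(v, v * c_),
               sites = data.frame(chrom = "c", pos = 1:2, ref = "A",
                                  alt = "C", vclass = "SNP"),
               pooled = c(0.5, 0.5))
    colnames(ft$daf) <- paste0("P", 1:10)
    class(ft) <- "frequency_table"
    sc <- cv_daf(ft)
    expect_equal(sc$cvdaf[1], sc$cvdaf[2], tolerance = 1e-10)
  }
})

test_that("Weir-Cockerham FST handles symmetry and fixation", {
  # identical allele counts in both pops -> ~0 (<= 0 by estimator)
  H <- matrix(rep(c(1L, 1L, 0L, 0L), 2), nrow = 1)
  gts <- make_gts(H)
  fst <- weir_cockerham_fst(gts, make_panel_n(c(A = 2, B = 2)), c("A", "B"))
  expect_lte(fst$fst[1], 0)
  # pop1 fixed derived (n=10), pop2 fixed ancestral -> 1
  H2 <- matrix(c(rep(1L, 20), rep(0L, 20)), nrow = 1)
  fst2 <- weir_cockerham_fst(make_gts(H2),
                             make_panel_n(c(A = 10, B = 10)), c("A", "B"))
  expect_equal(fst2$fst[1], 1)
  # monomorphic in both -> missing
  H3 <- matrix(rep(0L, 8), nrow = 1)
  fst3 <- weir_cockerham_fst(make_gts(H3),
                             make_panel_n(c(A = 2, B = 2)), c("A", "B"))
  expect_true(is.na(fst3$fst[1]))
})

test_that("counts 14/20 vs 4/20 match the hand-evaluated W&C formula", {
  expect_equal(fst_from_counts(10, 14, 10, 4),
               wc_oracle(10, 0.7, 2 * 0.7 * 0.3, 10, 0.2, 2 * 0.2 * 0.8),
               tolerance = 1e-14)
})

test_that("FST equals the independently coded W&C oracle on 100 random tables", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    k1 <- sample(0:(2 * n1), 1); k2 <- sample(0:(2 * n2), 1)
    got <- fst_from_counts(n1, k1, n2, k2)
    want <- wc_oracle(n1, k1 / (2 * n1), 2 * (k1 / (2 * n1)) * (1 - k1 / (2 * n1)),
                      n2, k2 / (2 * n2), 2 * (k2 / (2 * n2)) * (1 - k2 / (2 * n2)))
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("genotype-based FST uses observed heterozygosity", {
  set.seed(13)
  H <- matrix(rbinom(1 * 24, 1, 0.5), nrow = 1)
  gts <- make_gts(H)
  panel <- make_panel_n(c(A = 6, B = 6))
  got <- weir_cockerham_fst(gts, panel, c("A", "B"))$fst[1]
  h_obs <- function(cols) mean(H[1, cols[c(TRUE, FALSE)]] != H[1, cols[c(FALSE, TRUE)]])
  p <- function(cols) mean(H[1, cols])
  want <- wc_oracle(6, p(1:12), h_obs(1:12), 6, p(13:24), h_obs(13:24))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rank P-values are rank/N with deterministic tie-breaking", {
  sc <- data.frame(chrom = "c", pos = 1:100, score = runif(100))
  sc$score[17] <- 2   # unique maximum
  rp <- rank_pvalues(sc)
  expect_equal(rp$rank_p[17], 0.01)
  expect_setequal(rp$rank_p, (1:100) / 100)   # bijection onto {1/N..1}

  sc2 <- data.frame(chrom = "c", pos = 1:3, score = c(0.9, 0.9, 0.1))
  rp2 <- rank_pvalues(sc2)
  expect_equal(rp2$rank_p, c(1 / 3, 2 / 3, 1))  # positional tie-break

  sc3 <- data.frame(chrom = "c", pos = 1:5, score = c(3, 1, 5, 2, 4))
  expect_equal(rank_pvalues(sc3, "ascending")$rank[2], 1L)
  expect_error(rank_pvalues(sc3[0, ]), "empty")
})

test_that("ld_r2 matches hand computation from haplotype counts", {
  # perfectly co-inherited pair
  H <- rbind(rep(c(1L, 0L), 5), rep(c(1L, 0L), 5))
  ld <- ld_r2(make_gts(H), 1, 2)
  expect_equal(ld$r2, 1)
  expect_equal(ld$dprime, 1)
  # counts AB=4, Ab=1, aB=1, ab=4 -> r2 = 0.36
  a <- c(rep(1L, 5), rep(0L, 5))
  b <- c(rep(1L, 4), 0L, 1L, rep(0L, 4))
  ld2 <- ld_r2(make_gts(rbind(a, b)), 1, 2)
  expect_equal(ld2$r2, 0.36, tolerance = 1e-12)
  # monomorphic -> undefined
  ld3 <- ld_r2(make_gts(rbind(a, rep(0L, 10))), 1, 2)
  expect_true(is.na(ld3$r2))
})

test_that("independent sites show near-zero r2 in a large panel", {
  set.seed(5)
  H <- rbind(rbinom(4000, 1, 0.5), rbinom(4000, 1, 0.5))
  storage.mode(H) <- "integer"
  expect_lt(ld_r2(make_gts(H), 1, 2)$r2, 0.01)
})
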