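# Per-population derived allele frequency statistics: DAF, pairwise
# delta-DAF, cvDAF, per-site Weir-Cockerham FST, empirical rank P-values and
# pairwise LD.

hap_groups <- function(gts, panel, level = c("population", "continent")) {
  level <- match.arg(level)
  al <- align_panel(gts, panel)
  gts <- al$gts; panel <- al$panel
  lab <- if (level == "population") panel$population else panel$continent
  hap_lab <- rep(lab, each = 2L)
  list(gts = gts, hap_lab = hap_lab, groups = sort(unique(lab)))
}

#' Derived allele frequencies per group
#'
#' Computes, at every site, the derived allele frequency (DAF) within each
#' population or continental group, together with derived/observed allele
#' counts and the pooled DAF over the entire sample. Missing haplotypes are
#' excluded from the denominator; a group with no observed alleles at a site
#' gets a missing DAF.
#'
#' @param gts a [polarized_genotypes()] object.
#' @param panel a `population_panel` (see [read_panel()]).
#' @param level `"population"` or `"continent"` grouping.
#' @return object of class `frequency_table`: `sites` (variant table),
#'   `daf` (sites x groups matrix), `derived` and `observed` count matrices,
#'   `pooled` DAF vector, `level`.
#' @export
daf <- function(gts, panel, level = c("population", "continent")) {
  level <- match.arg(level)
  hg <- hap_groups(gts, panel, level)
  H <- hg$gts$H
  groups <- hg$groups
  der <- obs <- matrix(0, nrow(H), length(groups),
                       dimnames = list(NULL, groups))
  for (g in groups) {
    cols <- hg$hap_lab == g
    sub <- H[, cols, drop = FALSE]
    der[, g] <- rowSums(sub == 1L, na.rm = TRUE)
    obs[, g] <- rowSums(!is.na(sub))
  }
  dafm <- der / obs
  dafm[obs == 0] <- NA_real_
  pooled <- rowSums(der) / rowSums(obs)
  structure(list(sites = hg$gts$variants, daf = dafm, derived = der,
                 observed = obs, pooled = pooled, level = level),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table:", nrow(x$daf), "sites x", ncol(x$daf),
      x$level, "groups\n")
  invisible(x)
}

#' Pairwise derived allele frequency difference (delta-DAF)
#'
#' The differentiation statistic: at each site the signed difference
#' `DAF_A - DAF_B` for a pair of groups. Ranking uses the magnitude; the
#' direction records the group with the higher DAF, interpreted as the group
#' in which the derived allele would have been selected.
#'
#' @param freqs a `frequency_table` from [daf()].
#' @param pair length-2 character vector of group names `(A, B)`.
#' @return data.frame of class `site_score`: site columns, `ddaf` (signed),
#'   `score` (absolute value used for ranking), `direction` (higher-DAF
#'   group; `NA` at ties). Sites with a missing DAF in either group are
#'   dropped; the count is in `attr(, "n_skipped")`.
#' @export
delta_daf <- function(freqs, pair) {
  if (!all(pair %in% colnames(freqs$daf)))
    stop("pair groups not in frequency table: ",
         paste(setdiff(pair, colnames(freqs$daf)), collapse = ", "))
  a <- freqs$daf[, pair[1]]
  b <- freqs$daf[, pair[2]]
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  out <- cbind(freqs$sites[ok, c("chrom", "pos", "ref", "alt", "vclass"),
                           drop = FALSE],
               data.frame(ddaf = d, score = abs(d),
                          direction = ifelse(d > 0, pair[1],
                                             ifelse(d < 0, pair[2], NA)),
                          pair = paste(pair, collapse = "-"),
                          stringsAsFactors = FALSE))
  if (!is.null(freqs$sites$impq)) out$impq <- freqs$sites$impq[ok]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("site_score", "data.frame")
  out
}

#' Coefficient of variation of DAF across groups (cvDAF)
#'
#' `cvDAF = sd(DAF) / mean(DAF)` over the group DAFs at a site, using the
#' sample (n-1) standard deviation. Small values flag unusually uniform
#' frequencies across populations. Sites with fewer than two non-missing
#' group DAFs, or mean DAF zero, are skipped.
#'
#' @param freqs a `frequency_table` from [daf()].
#' @param groups group names to include (default: all).
#' @return data.frame of class `site_score` with `cvdaf` and `score`
#'   (= cvdaf; rank ascending so the smallest cvDAF is the most extreme).
#' @export
cv_daf <- function(freqs, groups = colnames(freqs$daf)) {
  sub <- freqs$daf[, groups, drop = FALSE]
  n_ok <- rowSums(!is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  s <- apply(sub, 1L, sd, na.rm = TRUE)
  ok <- n_ok >= 2L & !is.na(mu) & mu > 0
  out <- cbind(freqs$sites[ok, c("chrom", "pos", "ref", "alt", "vclass"),
                           drop = FALSE],
               data.frame(cvdaf = s[ok] / mu[ok], stringsAsFactors = FALSE))
  out$score <- out$cvdaf
  out$pooled_daf <- freqs$pooled[ok]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("site_score", "data.frame")
  out
}

#' Weir & Cockerham's per-site FST for two groups
#'
#' The Weir & Cockerham (1984) variance-component estimator
#' `theta = a / (a + b + c)` for a biallelic site and two populations, with
#' observed heterozygosity taken from the diploid genotypes. Sites
#' monomorphic across both groups are reported missing; slightly negative
#' estimates are retained.
#'
#' @param gts a [polarized_genotypes()] object (phased; haplotype pairs
#'   define diploid genotypes).
#' @param panel a `population_panel`.
#' @param pair length-2 character vector of group names.
#' @param level `"population"` or `"continent"`.
#' @return data.frame: site columns plus `fst` (NA where undefined).
#' @export
weir_cockerham_fst <- function(gts, panel, pair,
                               level = c("population", "continent")) {
  level <- match.arg(level)
  hg <- hap_groups(gts, panel, level)
  if (!all(pair %in% hg$groups))
    stop("pair groups not in panel: ",
         paste(setdiff(pair, hg$groups), collapse = ", "))
  H <- hg$gts$H
  ind_lab <- hg$hap_lab[seq(1, length(hg$hap_lab), by = 2L)]
  fst <- rep(NA_real_, nrow(H))
  stat <- lapply(pair, function(g) {
    cols <- which(hg$hap_lab == g)
    h1 <- H[, cols[seq(1, length(cols), 2L)], drop = FALSE]
    h2 <- H[, cols[seq(2, length(cols), 2L)], drop = FALSE]
    ok <- !is.na(h1) & !is.na(h2)
    n <- rowSums(ok)                              # diploids observed
    p <- rowSums((h1 + h2) * ok, na.rm = TRUE) / (2 * n)
    het <- rowSums((h1 != h2) & ok, na.rm = TRUE) / n
    list(n = n, p = p, h = het)
  })
  n1 <- stat[[1]]$n; n2 <- stat[[2]]$n
  p1 <- stat[[1]]$p; p2 <- stat[[2]]$p
  h1 <- stat[[1]]$h; h2 <- stat[[2]]$h
  comp <- wc_fst_components(n1, p1, h1, n2, p2, h2)
  denom <- comp$a + comp$b + comp$c
  def <- n1 > 0 & n2 > 0 & is.finite(denom) & denom != 0
  fst[def] <- (comp$a / denom)[def]
  out <- cbind(hg$gts$variants[, c("chrom", "pos", "ref", "alt"),
                               drop = FALSE],
               data.frame(fst = fst))
  rownames(out) <- NULL
  out
}

# Weir & Cockerham (1984) two-population variance components, vectorized.
wc_fst_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' FST from allele counts (two populations, one site)
#'
#' Convenience wrapper around the Weir & Cockerham components for count
#' data: `n` diploids per group with `k` derived alleles, heterozygosity at
#' its Hardy-Weinberg expectation `2p(1-p)` unless supplied.
#'
#' @param n1,k1,n2,k2 diploid sample sizes and derived-allele counts.
#' @param h1,h2 observed heterozygote frequencies (default HWE).
#' @return FST estimate (NA when the denominator vanishes).
#' @export
fst_from_counts <- function(n1, k1, n2, k2, h1 = NULL, h2 = NULL) {
  p1 <- k1 / (2 * n1); p2 <- k2 / (2 * n2)
  if (is.null(h1)) h1 <- 2 * p1 * (1 - p1)
  if (is.null(h2)) h2 <- 2 * p2 * (1 - p2)
  comp <- wc_fst_components(n1, p1, h1, n2, p2, h2)
  denom <- comp$a + comp$b + comp$c
  ifelse(denom == 0, NA_real_, comp$a / denom)
}

#' Empirical rank P-values
#'
#' Ranks scores genome-wide and assigns `P = rank / N`, rank 1 being the
#' most extreme score (largest under `"descending"`, smallest under
#' `"ascending"`). Ties are broken by genomic order for determinism.
#'
#' @param scores a `site_score` data.frame with a `score` column (and
#'   `chrom`, `pos` for tie-breaking).
#' @param order `"descending"` (delta-DAF: large = extreme) or
#'   `"ascending"` (cvDAF: small = extreme).
#' @return the input with `rank` and `rank_p` columns added, original row
#'   order preserved.
#' @export
rank_pvalues <- function(scores, order = c("descending", "ascending")) {
  order <- match.arg(order)
  if (!nrow(scores)) stop("empty score set")
  if (any(!is.finite(scores$score))) stop("non-finite scores")
  key <- if (order == "descending") -scores$score else scores$score
  o <- order(key, scores$chrom, scores$pos)
  rk <- integer(nrow(scores))
  rk[o] <- seq_len(nrow(scores))
  scores$rank <- rk
  scores$rank_p <- rk / nrow(scores)
  scores
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Haplotype-count based `r^2` and `D'` between two sites within a group.
#'
#' @param gts a [polarized_genotypes()] object.
#' @param siteA,siteB site row indices.
#' @param panel optional `population_panel`; with `group`, restricts
#'   haplotypes to one population/continent.
#' @param group optional group label.
#' @param level `"population"` or `"continent"`.
#' @return list `r2`, `dprime`, `D` (all `NA` if either site is monomorphic
#'   within the group).
#' @export
ld_r2 <- function(gts, siteA, siteB, panel = NULL, group = NULL,
                  level = c("population", "continent")) {
  level <- match.arg(level)
  H <- gts$H
  if (!is.null(panel) && !is.null(group)) {
    hg <- hap_groups(gts, panel, level)
    H <- hg$gts$H[, hg$hap_lab == group, drop = FALSE]
  }
  a <- H[siteA, ]; b <- H[siteB, ]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    return(list(r2 = NA_real_, dprime = NA_real_, D = NA_real_))
  pab <- mean(a == 1L & b == 1L)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(r2 = r2, dprime = if (dmax == 0) NA_real_ else abs(D) / dmax, D = D)
}
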