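# Independent oracles and fixture builders shared across the suite.

# -- dynamic-programming Levenshtein distance (independent of utils::adist) --
lev_oracle <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in 1:na) {
    cur <- c(i, numeric(nb))
    for (j in 1:nb)
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (A[i] != B[j]))
    prev <- cur
  }
  prev[nb + 1]
}

# -- scalar Weir & Cockerham (1984) two-population estimator, coded from the
#    published variance components --
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# -- Fisher exact P (two-sided) for a 2x2 table by hypergeometric
#    enumeration --
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  obs <- choose(m, tab[1, 1]) * choose(n, tab[2, 1]) / choose(m + n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# -- empirical quantile, hand interpolation (R type 7) --
quantile_oracle <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# -- fixture builders ---------------------------------------------------------

# polarized genotypes straight from a 0/1 site-by-haplotype matrix
make_gts <- function(H, pos = NULL, chrom = "chr1", impq = NA_real_) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  samples <- sprintf("S%02d", seq_len(ncol(H) / 2))
  variants <- data.frame(chrom = rep(chrom, n), pos = pos,
                         ref = rep("A", n), alt = rep("C", n),
                         vclass = rep("SNP", n), ancestral = rep("A", n),
                         impq = rep_len(impq, n), stringsAsFactors = FALSE)
  polarized_genotypes(variants, H, samples)
}

make_panel_n <- function(pops) {
  # pops: named integer vector population -> n samples; continent = CONT1
  sample <- sprintf("S%02d", seq_len(sum(pops)))
  make_panel(sample, rep(names(pops), pops),
             rep("CONT1", sum(pops)))
}

write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# small, fast single-population model for neutral-theory checks
tiny_model <- function(...) {
  args <- list(N_anc = 1000, npop = 1, lambda = 10, mu = 2.5e-8,
               rec = 1e-8, burnin_factor = 8)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(demographic_model, args)
}
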