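# Enrichment and validation statistics: gene-set overlap against control
# draws, genic enrichment of candidate sites, genotype and allele-frequency
# concordance between callsets, and LD-proxy expansion.

#' Gene-set overlap enrichment against random control sets
#'
#' The observed fraction of target genes present in a reference list (e.g.
#' genes previously reported under positive selection) is compared with the
#' fractions obtained from `n_control` random gene sets of the same size
#' drawn from the universe, using a one-sided one-sample t-test of the
#' control fractions against the observed value (alternative: controls are
#' smaller).
#'
#' @param target character vector of target gene ids (subset of universe).
#' @param reference character vector of reference gene ids.
#' @param universe character vector from which controls are drawn.
#' @param n_control number of control sets (default 100).
#' @param seed integer seed.
#' @return list: `obs_pct`, `control_mean_pct`, `control_sd_pct`,
#'   `p_value` (one-sided; `NA` with `degenerate = TRUE` when the control
#'   fractions have zero variance), `n_target`.
#' @export
gene_overlap_enrichment <- function(target, reference, universe,
                                    n_control = 100, seed = 1) {
  target <- unique(target)
  universe <- unique(universe)
  if (length(universe) < length(target))
    stop("universe smaller than target set")
  if (!length(intersect(reference, universe)))
    warning("reference and universe share no genes")
  obs <- 100 * mean(target %in% reference)
  set.seed(seed)
  ctrl <- replicate(n_control,
                    100 * mean(sample(universe, length(target)) %in% reference))
  degenerate <- sd(ctrl) == 0
  p <- if (degenerate) NA_real_
  else t.test(ctrl, mu = obs, alternative = "less")$p.value
  list(obs_pct = obs, control_mean_pct = mean(ctrl),
       control_sd_pct = sd(ctrl), p_value = p, degenerate = degenerate,
       n_target = length(target))
}

#' Genic enrichment of candidate sites
#'
#' 2x2 contingency of genic/non-genic status in target versus control
#' sites: odds ratio (cross-product; Haldane-corrected when a cell is zero)
#' and Fisher exact P-value.
#'
#' @param target_genic,control_genic logical vectors (or 0/1) flagging
#'   genic sites.
#' @return list: `odds_ratio`, `fisher_p`, `table`, `haldane` (TRUE when
#'   the 0.5 correction was applied).
#' @export
genic_enrichment <- function(target_genic, control_genic) {
  tab <- matrix(c(sum(target_genic), sum(!target_genic),
                  sum(control_genic), sum(!control_genic)),
                nrow = 2, dimnames = list(c("genic", "nongenic"),
                                          c("target", "control")))
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, fisher_p = fisher.test(tab)$p.value, table = tab,
       haldane = haldane)
}

#' Annotate sites as genic and with distance to the nearest gene start
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`
#'   (optional; gene start = `start` on `+`/missing, `end` on `-`), 1-based
#'   inclusive coordinates (convert BED input with [read_genes_bed()]).
#' @return `sites` with `genic` (inside any gene interval, exons + introns,
#'   no flanking) and `gene_dist` (bp to the nearest gene start; 0 when on
#'   it).
#' @export
annotate_genes <- function(sites, genes) {
  if (is.null(genes$strand)) genes$strand <- "+"
  starts <- ifelse(genes$strand == "-", genes$end, genes$start)
  sites$genic <- FALSE
  sites$gene_dist <- NA_real_
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    for (i in si) {
      p <- sites$pos[i]
      sites$genic[i] <- any(p >= genes$start[gi] & p <= genes$end[gi])
      sites$gene_dist[i] <- min(abs(p - starts[gi]))
    }
  }
  sites
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (chrom, start, end, optional name, score, strand).
#' @return data.frame `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_genes_bed <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = b[[2]] + 1L, end = b[[3]],
             name = if (ncol(b) >= 4) b[[4]] else NA_character_,
             strand = if (ncol(b) >= 6) b[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Genotype concordance between two callsets
#'
#' Sites are matched by `(chrom, pos, ref, alt)` and samples by id; at each
#' shared site the fraction of identical unordered diploid genotypes
#' (allele dosages, so `0|1` and `1|0` agree) across shared samples is
#' reported, with median and mean summaries by variant class.
#'
#' @param gtsA,gtsB [polarized_genotypes()] objects.
#' @return list: `per_site` data.frame (`chrom`, `pos`, `vclass`,
#'   `concordance`), `summary` (per vclass median/mean), `n_samples`.
#' @export
genotype_concordance <- function(gtsA, gtsB) {
  shared_s <- intersect(gtsA$samples, gtsB$samples)
  if (!length(shared_s)) stop("no shared samples")
  keyA <- with(gtsA$variants, paste(chrom, pos, ref, alt))
  keyB <- with(gtsB$variants, paste(chrom, pos, ref, alt))
  shared_k <- intersect(keyA, keyB)
  if (!length(shared_k)) stop("no shared sites")
  ia <- match(shared_k, keyA)
  ib <- match(shared_k, keyB)
  dosage <- function(gts, rows, samples) {
    cols1 <- 2L * match(samples, gts$samples) - 1L
    gts$H[rows, cols1, drop = FALSE] + gts$H[rows, cols1 + 1L, drop = FALSE]
  }
  dA <- dosage(gtsA, ia, shared_s)
  dB <- dosage(gtsB, ib, shared_s)
  conc <- rowMeans(dA == dB, na.rm = TRUE)
  per_site <- data.frame(chrom = gtsA$variants$chrom[ia],
                         pos = gtsA$variants$pos[ia],
                         vclass = gtsA$variants$vclass[ia],
                         concordance = conc, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per_site$concordance, per_site$vclass),
                                function(x) data.frame(n = length(x),
                                                       median = median(x),
                                                       mean = mean(x))))
  list(per_site = per_site, summary = summ, n_samples = length(shared_s))
}

#' Allele-frequency concordance between two frequency tables
#'
#' Spearman rank correlation of the matched group DAFs of two callsets over
#' shared sites.
#'
#' @param freqsA,freqsB `frequency_table` objects from [daf()].
#' @return data.frame per shared group: `group`, `n_sites`, `rho`,
#'   `p_value` (`NA` with fewer than 3 shared sites).
#' @export
af_concordance <- function(freqsA, freqsB) {
  keyA <- with(freqsA$sites, paste(chrom, pos, ref, alt))
  keyB <- with(freqsB$sites, paste(chrom, pos, ref, alt))
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA)
  ib <- match(shared, keyB)
  groups <- intersect(colnames(freqsA$daf), colnames(freqsB$daf))
  do.call(rbind, lapply(groups, function(g) {
    a <- freqsA$daf[ia, g]
    b <- freqsB$daf[ib, g]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3)
      return(data.frame(group = g, n_sites = sum(ok), rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman"))
    data.frame(group = g, n_sites = sum(ok), rho = unname(ct$estimate),
               p_value = ct$p.value)
  }))
}

#' Expand a site set with LD proxies
#'
#' Adds, for each target site, all sites within `window_bp` whose `r^2`
#' with the target exceeds `r2_min` within the chosen group.
#'
#' @param gts a [polarized_genotypes()] object.
#' @param target_idx row indices of target sites.
#' @param r2_min LD threshold (strict `>`, default 0.8).
#' @param window_bp search window around each target (default 100 kb).
#' @param panel,group,level optional group restriction.
#' @return data.frame: `target_idx`, `proxy_idx`, `r2` (targets themselves
#'   are not listed).
#' @export
ld_proxy_expand <- function(gts, target_idx, r2_min = 0.8, window_bp = 1e5,
                            panel = NULL, group = NULL,
                            level = c("population", "continent")) {
  level <- match.arg(level)
  pos <- gts$variants$pos
  chrom <- gts$variants$chrom
  rows <- list()
  for (t in target_idx) {
    cand <- which(chrom == chrom[t] & abs(pos - pos[t]) <= window_bp &
                  seq_along(pos) != t)
    for (c in cand) {
      r2 <- ld_r2(gts, t, c, panel, group, level)$r2
      if (!is.na(r2) && r2 > r2_min)
        rows[[length(rows) + 1L]] <- data.frame(target_idx = t,
                                                proxy_idx = c, r2 = r2)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_idx = integer(), proxy_idx = integer(), r2 = numeric())
  rownames(out) <- NULL
  out
}
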