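# Power / sensitivity benchmark: thresholds at a 5% false-discovery rate
# derived from neutral simulations, and true-positive rates per statistic
# and sweep scenario.

#' Empirical neutral threshold
#'
#' The empirical quantile (linear interpolation, R type 7) of a neutral
#' score distribution; with `q = 0.95` the resulting threshold corresponds
#' to a 5% false discovery rate.
#'
#' @param neutral_scores numeric vector of neutral scores (pooled per-site
#'   scores, or per-replicate maxima, depending on the calibration chosen).
#' @param q quantile (default 0.95).
#' @param min_scores minimum number of scores required (default 100).
#' @return the threshold.
#' @export
neutral_threshold <- function(neutral_scores, q = 0.95, min_scores = 100) {
  neutral_scores <- neutral_scores[is.finite(neutral_scores)]
  if (length(neutral_scores) < min_scores)
    stop("need at least ", min_scores, " neutral scores, got ",
         length(neutral_scores))
  unname(quantile(neutral_scores, q, type = 7))
}

#' Sensitivity per sweep scenario
#'
#' The fraction of sweep replicates whose selected-variant score strictly
#' exceeds the neutral threshold, per scenario class and overall, with an
#' exact (Clopper-Pearson) binomial confidence interval.
#'
#' @param scores numeric vector: one selected-variant score per replicate.
#' @param threshold neutral threshold from [neutral_threshold()].
#' @param scenario factor/vector grouping replicates into scenario classes.
#' @param conf confidence level (default 0.95).
#' @return data.frame: `scenario` (classes plus `"overall"`), `n`,
#'   `detected`, `sensitivity`, `ci_lo`, `ci_hi`.
#' @export
sensitivity <- function(scores, threshold, scenario = rep("all", length(scores)),
                        conf = 0.95) {
  ok <- is.finite(scores)
  if (any(!ok)) warning(sum(!ok), " replicate score(s) missing; dropped")
  scores <- scores[ok]
  scenario <- as.character(scenario)[ok]
  one <- function(s, label) {
    n <- length(s)
    k <- sum(s > threshold)
    ci <- binom.test(k, n, conf.level = conf)$conf.int
    data.frame(scenario = label, n = n, detected = k, sensitivity = k / n,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }
  cls <- sort(unique(scenario))
  out <- do.call(rbind, lapply(cls, function(cl)
    one(scores[scenario == cl], cl)))
  rbind(out, one(scores, "overall"))
}

continent_pairs <- list(c("AFR", "EUR"), c("AFR", "ASN"), c("EUR", "ASN"))

# per-site scores for the frequency-based statistics: the maximum over the
# three continental pairs of |delta-DAF| and (optionally) of per-site FST
site_scores_freq <- function(rep, stats = c("ddaf", "fst")) {
  ft <- daf(rep$gts, rep$panel, level = "continent")
  out <- list()
  if ("ddaf" %in% stats) {
    d <- do.call(cbind, lapply(continent_pairs, function(p)
      abs(ft$daf[, p[1]] - ft$daf[, p[2]])))
    out$ddaf <- apply(d, 1L, max, na.rm = TRUE)
  }
  if ("fst" %in% stats) {
    f <- do.call(cbind, lapply(continent_pairs, function(p)
      weir_cockerham_fst(rep$gts, rep$panel, p, level = "continent")$fst))
    out$fst <- suppressWarnings(apply(f, 1L, max, na.rm = TRUE))
    out$fst[!is.finite(out$fst)] <- NA_real_
  }
  out
}

# haplotype-statistic scores at chosen sites of a replicate, on a subsample
# of individuals per group (the study design restricts haplotype statistics
# to 30 random individuals per group)
site_scores_hap <- function(rep, sites, stats = c("ihs", "xpehh"),
                            subsample = 30, seed = 1) {
  gts <- rep$gts
  panel <- rep$panel
  if (!is.null(subsample)) {
    sub <- subsample_individuals(gts, panel, subsample, seed = seed)
    gts <- sub$gts
    panel <- sub$panel
  }
  groups <- sort(unique(panel$continent))
  out <- list()
  if ("ihs" %in% stats)
    out$ihs <- vapply(sites, function(s) {
      v <- suppressWarnings(lapply(groups, function(g)
        ihs(gts, s, rep$map, panel, g, level = "continent")))
      v <- v[!vapply(v, is.null, TRUE)]
      if (!length(v)) return(NA_real_)
      max(vapply(v, function(x) -x$raw, 0))   # positive = long derived haps
    }, 0)
  if ("xpehh" %in% stats)
    out$xpehh <- vapply(sites, function(s) {
      prs <- continent_pairs
      v <- suppressWarnings(lapply(prs, function(p)
        xpehh(gts, s, rep$map, panel, p[1], p[2], level = "continent")))
      v <- v[!vapply(v, is.null, TRUE)]
      if (!length(v)) return(NA_real_)
      max(vapply(v, function(x) abs(x$raw), 0))
    }, 0)
  out
}

#' Subsample individuals per group
#' @param gts a [polarized_genotypes()] object.
#' @param panel a `population_panel`.
#' @param n individuals retained per continent (all if fewer).
#' @param seed integer seed.
#' @return list `gts`, `panel` restricted to the subsample.
#' @export
subsample_individuals <- function(gts, panel, n, seed = 1) {
  set.seed(seed)
  al <- align_panel(gts, panel)
  keep <- unlist(lapply(split(al$panel$sample, al$panel$continent),
                        function(s) if (length(s) <= n) s else sample(s, n)))
  keep_idx <- al$gts$samples %in% keep
  gts2 <- polarized_genotypes(al$gts$variants,
                              al$gts$H[, rep(keep_idx, each = 2L), drop = FALSE],
                              al$gts$samples[keep_idx], al$gts$phased)
  list(gts = gts2, panel = al$panel[al$panel$sample %in% keep, , drop = FALSE])
}

#' Neutral score distributions from simulation
#'
#' Simulates neutral replicates and collects, per statistic, the pooled
#' per-site scores and the per-replicate maxima; either distribution can
#' feed [neutral_threshold()] (see Details of [power_table()]).
#'
#' @param model a [demographic_model()].
#' @param n_replicates neutral replicates.
#' @param stats subset of `c("ddaf", "fst", "ihs", "xpehh")`.
#' @param region_bp,n_per_pop simulation size.
#' @param seed base seed.
#' @param hap_sites_per_rep sites per replicate at which the (expensive)
#'   haplotype statistics are evaluated (sampled among sites with pooled
#'   DAF in `[0.05, 0.95]`).
#' @param subsample individuals per group for haplotype statistics.
#' @return list per statistic: `per_site` (pooled vector), `per_rep_max`.
#' @export
neutral_benchmark <- function(model, n_replicates, stats = "ddaf",
                              region_bp = 1e5, n_per_pop = 50, seed = 1,
                              hap_sites_per_rep = 10, subsample = 30) {
  acc <- lapply(stats, function(s) list(per_site = list(), per_rep_max = c()))
  names(acc) <- stats
  freq_stats <- intersect(stats, c("ddaf", "fst"))
  hap_stats <- intersect(stats, c("ihs", "xpehh"))
  for (r in seq_len(n_replicates)) {
    rep <- simulate_neutral(model, region_bp, n_per_pop,
                            seed = replicate_seed(seed, r))
    if (!nrow(rep$gts$variants)) next
    if (length(freq_stats)) {
      sc <- site_scores_freq(rep, freq_stats)
      for (s in freq_stats) {
        acc[[s]]$per_site[[r]] <- sc[[s]]
        acc[[s]]$per_rep_max <- c(acc[[s]]$per_rep_max,
                                  suppressWarnings(max(sc[[s]], na.rm = TRUE)))
      }
    }
    if (length(hap_stats)) {
      pooled <- rowMeans(rep$gts$H, na.rm = TRUE)
      cand <- which(pooled >= 0.05 & pooled <= 0.95)
      set.seed(replicate_seed(seed, r) + 7)
      sites <- if (length(cand) > hap_sites_per_rep)
        sort(sample(cand, hap_sites_per_rep)) else cand
      hc <- site_scores_hap(rep, sites, hap_stats, subsample,
                            seed = replicate_seed(seed, r) + 13)
      for (s in hap_stats) {
        acc[[s]]$per_site[[r]] <- hc[[s]]
        m <- suppressWarnings(max(hc[[s]], na.rm = TRUE))
        acc[[s]]$per_rep_max <- c(acc[[s]]$per_rep_max,
                                  if (is.finite(m)) m else NA_real_)
      }
    }
  }
  lapply(acc, function(a) list(per_site = unlist(a$per_site),
                               per_rep_max = a$per_rep_max))
}

#' Sweep replicates scored at the selected variant
#'
#' Simulates sweep replicates over final-allele-frequency classes and
#' scores the selected variant with the requested statistics; optionally
#' also computes the 2-kb weighted Levenshtein distance of the
#' derived-allele haplotypes in the selected population (used by the
#' hard/soft-sweep analyses).
#'
#' Sweep durations rotate over `durations` and the selected population over
#' `pops`, emulating a grid of scenarios; each replicate's realized final
#' frequency is recorded.
#'
#' @param model a [demographic_model()].
#' @param targets final-allele-frequency classes.
#' @param n_per_class replicates per class.
#' @param stats statistics evaluated at the selected variant.
#' @param levenshtein also compute the weighted Levenshtein distance.
#' @param window_bp Levenshtein window (default 2000).
#' @param durations sweep durations cycled across replicates (generations).
#' @param pops selected populations cycled across replicates.
#' @param region_bp,n_per_pop,seed simulation size and base seed.
#' @param subsample individuals per group for haplotype statistics.
#' @return data.frame, one row per replicate: `target`, `duration`, `pop`,
#'   `realized`, one score column per statistic, and `lev_D`,
#'   `lev_carriers`, `lev_nhap` when requested.
#' @export
sweep_benchmark <- function(model, targets = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            n_per_class = 10, stats = "ddaf",
                            levenshtein = TRUE, window_bp = 2000,
                            durations = seq(200, 1200, by = 200),
                            pops = c("AFR", "EUR", "ASN"),
                            region_bp = 1e5, n_per_pop = 50, seed = 1,
                            subsample = 30) {
  rows <- list()
  k <- 0L
  for (tg in targets) for (i in seq_len(n_per_class)) {
    k <- k + 1L
    dur <- durations[(k - 1L) %% length(durations) + 1L]
    pop <- pops[(k - 1L) %% length(pops) + 1L]
    sc <- sweep_scenario(tg, duration = dur, pop = pop)
    rep <- simulate_sweep(model, sc, region_bp, n_per_pop,
                          seed = replicate_seed(seed, 10000 + k))
    row <- data.frame(target = tg, duration = dur, pop = pop,
                      realized = rep$pop_freq[pop],
                      attempts = rep$attempts, stringsAsFactors = FALSE)
    freq_stats <- intersect(stats, c("ddaf", "fst"))
    if (length(freq_stats)) {
      ssc <- site_scores_freq(rep, freq_stats)
      for (s in freq_stats) row[[s]] <- ssc[[s]][rep$selected_index]
    }
    hap_stats <- intersect(stats, c("ihs", "xpehh"))
    if (length(hap_stats)) {
      hc <- site_scores_hap(rep, rep$selected_index, hap_stats, subsample,
                            seed = replicate_seed(seed, 20000 + k))
      for (s in hap_stats) row[[s]] <- hc[[s]]
    }
    if (levenshtein) {
      sample_carriers <- sum(
        hap_cols_for_group(rep$gts, rep$panel, pop,
                           "continent")$H[rep$selected_index, ] == 1L,
        na.rm = TRUE)
      if (sample_carriers >= 1L) {
        hs <- extract_haplotypes(rep$gts, rep$selected_index, window_bp,
                                 rep$panel, pop, level = "continent")
        row$lev_D <- weighted_levenshtein(hs)
        row$lev_carriers <- hs$n_carriers
        row$lev_nhap <- nrow(hs$haps)
      } else {
        row$lev_D <- NA_real_
        row$lev_carriers <- 0L
        row$lev_nhap <- NA_integer_
      }
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full power table for the four statistics
#'
#' The complete harness: neutral replicates define, per statistic, the
#' threshold at `1 - fdr` (default the 95th percentile, a 5% false
#' discovery rate); sweep replicates grouped by final-allele-frequency
#' class (plus `"overall"`) are then scored at the selected variant and the
#' proportion exceeding the threshold is the sensitivity.
#'
#' Two calibrations of the neutral score distribution are available:
#' `threshold_mode = "per_site"` (default) pools the per-site scores of all
#' neutral replicates, matching a genome-wide empirical outlier threshold;
#' `"replicate_max"` uses each neutral replicate's maximum score, a
#' per-region family-wise calibration that is far more conservative for
#' partial sweeps. See the package vignette for the trade-off.
#'
#' @inheritParams sweep_benchmark
#' @param n_neutral neutral replicates.
#' @param fdr false discovery rate (default 0.05).
#' @param threshold_mode `"per_site"` or `"replicate_max"`.
#' @return list of class `power_table`: `table` (statistic x scenario
#'   sensitivities with exact binomial CIs), `thresholds`, `counts`,
#'   `threshold_mode`, `sweeps` (per-replicate scores).
#' @export
power_table <- function(model, stats = c("ddaf", "fst"),
                        targets = c(0.2, 0.4, 0.6, 0.8, 1.0),
                        n_neutral = 100, n_per_class = 10,
                        region_bp = 1e5, n_per_pop = 50, seed = 1,
                        fdr = 0.05, threshold_mode = c("per_site", "replicate_max"),
                        durations = seq(200, 1200, by = 200),
                        pops = c("AFR", "EUR", "ASN"), subsample = 30) {
  threshold_mode <- match.arg(threshold_mode)
  nb <- neutral_benchmark(model, n_neutral, stats, region_bp, n_per_pop,
                          seed = seed, subsample = subsample)
  thresholds <- vapply(stats, function(s) {
    pool <- if (threshold_mode == "per_site") nb[[s]]$per_site
            else nb[[s]]$per_rep_max
    neutral_threshold(pool, q = 1 - fdr, min_scores = min(100, length(pool)))
  }, 0)
  sw <- sweep_benchmark(model, targets, n_per_class, stats,
                        levenshtein = FALSE, durations = durations,
                        pops = pops, region_bp = region_bp,
                        n_per_pop = n_per_pop, seed = seed,
                        subsample = subsample)
  tab <- do.call(rbind, lapply(stats, function(s) {
    st <- sensitivity(sw[[s]], thresholds[[s]],
                      scenario = format(sw$target, nsmall = 1))
    st$statistic <- s
    st
  }))
  structure(list(table = tab[, c("statistic", setdiff(names(tab), "statistic"))],
                 thresholds = thresholds,
                 counts = c(neutral = n_neutral, per_class = n_per_class),
                 threshold_mode = threshold_mode, sweeps = sw),
            class = "power_table")
}

#' @export
print.power_table <- function(x, ...) {
  cat("power_table (", x$counts["neutral"], "neutral,",
      x$counts["per_class"], "sweeps/class, thresholds:",
      paste(names(x$thresholds), signif(x$thresholds, 3), collapse = ", "),
      ";", x$threshold_mode, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
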