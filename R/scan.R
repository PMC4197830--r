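# HighD / LowD genome scans: QC filtering, top-percentile marking,
# non-overlapping variant-count windows, per-window peak-picking, and
# matched-control sampling.

#' Scan configuration
#'
#' Defaults follow the reference analysis: 5,000-variant windows and a
#' delta-DAF threshold of 0.7 for between-continent comparisons, 0.25 within
#' continents; 100-variant windows and cvDAF < 0.01 for the LowD scan, which
#' is restricted to sites with pooled DAF in `[0.40, 0.60]` excluding the
#' open interval `(0.45, 0.55)`; imputation-quality cutoff 0.8.
#'
#' @param window_highd,window_lowd window sizes in variant counts.
#' @param top_percentile percentage of most extreme sites marked before
#'   peak-picking.
#' @param thresh_between,thresh_within delta-DAF retention thresholds
#'   (strict `>`).
#' @param cv_thresh cvDAF retention threshold (strict `<`).
#' @param daf_band closed pooled-DAF band for the LowD scan.
#' @param daf_exclusion open pooled-DAF interval excluded inside the band.
#' @param min_impq imputation-quality cutoff (strict `>` keeps a site).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(window_highd = 5000, window_lowd = 100,
                        top_percentile = 1,
                        thresh_between = 0.7, thresh_within = 0.25,
                        cv_thresh = 0.01,
                        daf_band = c(0.40, 0.60),
                        daf_exclusion = c(0.45, 0.55),
                        min_impq = 0.8) {
  stopifnot(top_percentile > 0, top_percentile <= 100,
            thresh_between >= 0, thresh_between <= 1,
            thresh_within >= 0, thresh_within <= 1,
            daf_band[1] <= daf_exclusion[1],
            daf_exclusion[2] <= daf_band[2])
  structure(list(window_highd = window_highd, window_lowd = window_lowd,
                 top_percentile = top_percentile,
                 thresh_between = thresh_between,
                 thresh_within = thresh_within,
                 cv_thresh = cv_thresh, daf_band = daf_band,
                 daf_exclusion = daf_exclusion, min_impq = min_impq),
            class = "scan_config")
}

#' Imputation-quality filter
#'
#' Removes sites whose imputation quality is at or below `min_impq`
#' (retention requires `impq > min_impq`). Sites with a missing quality are
#' kept and counted in lenient mode (default) or dropped in strict mode.
#'
#' @param scores a `site_score` data.frame with an `impq` column (sites
#'   without one pass through unchanged).
#' @param min_impq quality cutoff.
#' @param strict drop sites with missing quality when `TRUE`.
#' @return filtered data.frame; `attr(, "drop_counts")` records removals.
#' @export
qc_filter <- function(scores, min_impq = 0.8, strict = FALSE) {
  if (is.null(scores$impq) || !nrow(scores)) {
    attr(scores, "drop_counts") <- c(low_impq = 0L, missing_impq = 0L)
    return(scores)
  }
  miss <- is.na(scores$impq)
  low <- !miss & scores$impq <= min_impq
  keep <- !low & (!strict | !miss)
  if (any(miss) && !strict)
    warning(sum(miss), " site(s) with missing imputation quality kept")
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(low_impq = sum(low),
                                missing_impq = if (strict) sum(miss) else 0L)
  out
}

window_index <- function(chrom, window_size) {
  idx <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  paste0(chrom, ":", (idx - 1L) %/% window_size + 1L)
}

#' HighD scan: windowed peak-picking of extreme delta-DAF sites
#'
#' The scan proceeds in four steps: (i) mark the `top_percentile` of sites
#' by |delta-DAF| rank; (ii) partition all scanned sites, per chromosome and
#' in genomic order, into consecutive non-overlapping blocks of
#' `window_size` variants (the last block may be short); (iii) in each block
#' take the maximum-|delta-DAF| marked site; (iv) retain it if its
#' |delta-DAF| strictly exceeds the threshold for the comparison level.
#' With `mode = "threshold"` (exomic-INDEL style) steps i-iii are skipped
#' and the threshold alone is applied.
#'
#' @param scores a ranked `site_score` data.frame ([delta_daf()] then
#'   [rank_pvalues()]), in genomic order.
#' @param cfg a [scan_config()].
#' @param level `"between"` or `"within"` continents, selecting the
#'   threshold.
#' @param window_size block size in variants (default from `cfg`).
#' @param mode `"window"` (default) or `"threshold"`.
#' @return list of class `scan_result`: `sites` (retained rows with
#'   `window`), `level`, `threshold`, `n_input`, `drop_counts`.
#' @export
highd_scan <- function(scores, cfg = scan_config(),
                       level = c("between", "within"),
                       window_size = cfg$window_highd,
                       mode = c("window", "threshold")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  thresh <- if (level == "between") cfg$thresh_between else cfg$thresh_within
  if (!nrow(scores)) {
    return(structure(list(sites = scores, level = level, threshold = thresh,
                          n_input = 0L, drop_counts = c()),
                     class = "scan_result"))
  }
  if (!identical(order(scores$chrom, scores$pos), seq_len(nrow(scores))))
    stop("scores must be in genomic order (chrom, pos)")
  if (mode == "threshold") {
    keep <- scores$score > thresh
    out <- scores[keep, , drop = FALSE]
    out$window <- NA_character_
    rownames(out) <- NULL
    return(structure(list(sites = out, level = level, threshold = thresh,
                          n_input = nrow(scores),
                          drop_counts = c(below_threshold = sum(!keep))),
                     class = "scan_result"))
  }
  if (is.null(scores$rank)) scores <- rank_pvalues(scores)
  # top percentile by rank; ceiling so at least one site is always marked
  marked <- scores$rank <= ceiling(nrow(scores) * cfg$top_percentile / 100)
  win <- window_index(scores$chrom, window_size)
  scores$window <- win
  cand <- scores[marked, , drop = FALSE]
  picked <- do.call(rbind, lapply(split(cand, cand$window), function(w) {
    w[order(-w$score, w$pos), , drop = FALSE][1L, , drop = FALSE]
  }))
  if (is.null(picked)) picked <- scores[0, , drop = FALSE]
  retained <- picked[picked$score > thresh, , drop = FALSE]
  retained <- retained[order(retained$chrom, retained$pos), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(sites = retained, level = level, threshold = thresh,
                 n_input = nrow(scores),
                 drop_counts = c(unmarked = sum(!marked),
                                 below_threshold = nrow(picked) - nrow(retained))),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result (", x$level, "): ", nrow(x$sites), " site(s) retained of ",
      x$n_input, " scanned (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' LowD scan: windowed minimum-cvDAF sites
#'
#' Restricts to sites with pooled DAF inside the closed band
#' `[0.40, 0.60]` but outside the open exclusion interval `(0.45, 0.55)`
#' (rare sites trivially show low differentiation; sites at frequency 0.5
#' everywhere are likely miscalled paralogs). Surviving sites are split into
#' consecutive windows of `window_lowd` variants per chromosome; the
#' minimum-cvDAF site of each window is retained if its cvDAF is strictly
#' below `cv_thresh`.
#'
#' @param freqs a `frequency_table` from [daf()] at population level.
#' @param cfg a [scan_config()].
#' @return list of class `scan_result`; `drop_counts` reports band and
#'   exclusion removals.
#' @export
lowd_scan <- function(freqs, cfg = scan_config()) {
  sc <- cv_daf(freqs)
  in_band <- sc$pooled_daf >= cfg$daf_band[1] & sc$pooled_daf <= cfg$daf_band[2]
  in_excl <- sc$pooled_daf > cfg$daf_exclusion[1] &
    sc$pooled_daf < cfg$daf_exclusion[2]
  keep <- in_band & !in_excl
  surv <- sc[keep, , drop = FALSE]
  if (nrow(surv)) {
    surv$window <- window_index(surv$chrom, cfg$window_lowd)
    picked <- do.call(rbind, lapply(split(surv, surv$window), function(w) {
      w[order(w$cvdaf, w$pos), , drop = FALSE][1L, , drop = FALSE]
    }))
    retained <- picked[picked$cvdaf < cfg$cv_thresh, , drop = FALSE]
    retained <- retained[order(retained$chrom, retained$pos), , drop = FALSE]
  } else retained <- surv
  rownames(retained) <- NULL
  structure(list(sites = retained, level = "lowd",
                 threshold = cfg$cv_thresh, n_input = nrow(sc),
                 drop_counts = c(outside_band = sum(!in_band),
                                 in_exclusion = sum(in_band & in_excl))),
            class = "scan_result")
}

#' Union of scan results with per-site pair labels
#'
#' Unique sites are keyed by `(chrom, pos, ref, alt)`; every contributing
#' comparison pair is retained as a comma-separated label.
#'
#' @param results list of `scan_result` objects (or data.frames with a
#'   `pair` column).
#' @return data.frame of unique sites with `pairs` and `n_pairs` columns.
#' @export
dedup_union <- function(results) {
  dfs <- lapply(results, function(r) if (inherits(r, "scan_result")) r$sites else r)
  all <- do.call(rbind, lapply(dfs, function(d)
    d[, intersect(c("chrom", "pos", "ref", "alt", "score", "pair"),
                  names(d)), drop = FALSE]))
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      pairs = character(), n_pairs = integer()))
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = "\r")
  split_idx <- split(seq_len(nrow(all)), key)
  rows <- lapply(split_idx, function(i) {
    first <- all[i[1], , drop = FALSE]
    first$pairs <- paste(unique(all$pair[i]), collapse = ",")
    first$n_pairs <- length(unique(all$pair[i]))
    first$score <- max(all$score[i])
    first
  })
  out <- do.call(rbind, rows)
  out$pair <- NULL
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

dist_bin <- function(d) {
  cut(d, breaks = c(-Inf, 0, 1e3, 1e4, 1e5, Inf),
      labels = c("0", "(0,1kb]", "(1,10kb]", "(10,100kb]", ">100kb"))
}

#' Matched random control sites
#'
#' For each target site, draws control sites from a universe matched on (i)
#' derived allele frequency in the target's assigned population (within
#' `daf_tol`, relaxed stepwise to `daf_tol_max` when candidates run short)
#' and (ii) distance to the nearest gene start, binned as
#' 0, (0,1kb], (1,10kb], (10,100kb], >100kb. Sampling is without
#' replacement and reproducible under `seed`.
#'
#' @param targets data.frame with columns `chrom`, `pos`, `daf`,
#'   `gene_dist`.
#' @param universe data.frame with the same columns (targets are excluded
#'   from their own candidate pools by position).
#' @param n_per_target controls drawn per target.
#' @param daf_tol,daf_tol_max initial and maximal DAF matching tolerance.
#' @param seed integer seed.
#' @return data.frame of controls with a `target_idx` column; targets with
#'   no candidates even after relaxation are listed in
#'   `attr(, "unmatched")`.
#' @export
matched_controls <- function(targets, universe, n_per_target = 1,
                             daf_tol = 0.02, daf_tol_max = 0.05, seed = 1) {
  set.seed(seed)
  ub <- dist_bin(universe$gene_dist)
  tb <- dist_bin(targets$gene_dist)
  out <- list()
  unmatched <- integer()
  for (i in seq_len(nrow(targets))) {
    tol <- daf_tol
    cand <- integer()
    repeat {
      cand <- which(ub == tb[i] &
                    abs(universe$daf - targets$daf[i]) <= tol &
                    !(universe$chrom == targets$chrom[i] &
                      universe$pos == targets$pos[i]))
      if (length(cand) >= n_per_target || tol >= daf_tol_max) break
      tol <- min(tol + 0.01, daf_tol_max)
    }
    if (length(cand) < n_per_target) {
      unmatched <- c(unmatched, i)
      next
    }
    pick <- cand[sample.int(length(cand), n_per_target)]
    ctrl <- universe[pick, , drop = FALSE]
    ctrl$target_idx <- i
    out[[length(out) + 1L]] <- ctrl
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(universe[0, , drop = FALSE], data.frame(target_idx = integer()))
  rownames(res) <- NULL
  if (length(unmatched))
    warning(length(unmatched), " target(s) could not be matched")
  attr(res, "unmatched") <- unmatched
  res
}
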