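# Hard-vs-soft sweep classification from the homogeneity of derived-allele
# haplotypes: 2-kb window extraction, frequency-weighted Levenshtein
# distance, threshold + recombination conditioning, and the chance-corrected
# excess of hard-like sites.

#' Extract derived-allele haplotypes around a focal site
#'
#' Collects the haplotypes carrying the derived allele at the focal site,
#' written as strings with one symbol per polymorphic flanking site inside
#' `focal position +/- window_bp / 2` (the focal site itself, constant among
#' carriers, is excluded). Identical strings are aggregated into distinct
#' haplotypes with counts and relative frequencies; the major haplotype is
#' the most frequent one, ties broken by lexicographically smallest string.
#'
#' @param gts a [polarized_genotypes()] object.
#' @param focal site row index.
#' @param window_bp total window width in bp (default 2000).
#' @param panel,group,level optional restriction to one group's haplotypes;
#'   flanking sites are those polymorphic within that group.
#' @return object of class `haplotype_set`: `haps` (data.frame string,
#'   count, freq), `major` (string), `n_carriers`, `n_sites`, `span`
#'   (bp interval), `degenerate` (no polymorphic flanking site).
#' @export
extract_haplotypes <- function(gts, focal, window_bp = 2000, panel = NULL,
                               group = NULL,
                               level = c("population", "continent")) {
  level <- match.arg(level)
  H <- gts$H
  if (!is.null(panel) && !is.null(group)) {
    hc <- hap_cols_for_group(gts, panel, group, level)
    H <- hc$H
    gts <- hc$gts
  }
  carriers <- which(H[focal, ] == 1L)
  if (!length(carriers)) stop("no derived-allele carriers at the focal site")
  pos <- gts$variants$pos
  lo <- pos[focal] - window_bp / 2
  hi <- pos[focal] + window_bp / 2
  in_win <- which(gts$variants$chrom == gts$variants$chrom[focal] &
                  pos >= lo & pos <= hi & seq_along(pos) != focal)
  # flanking sites polymorphic among the carrier haplotypes themselves:
  # sites at which all carriers agree are uninformative about their mutual
  # divergence and are not part of the haplotype strings
  poly <- in_win[vapply(in_win, function(i) {
    x <- H[i, carriers]
    any(x == 1L, na.rm = TRUE) && any(x == 0L, na.rm = TRUE)
  }, TRUE)]
  degenerate <- !length(poly)
  strings <- if (degenerate) rep("", length(carriers)) else {
    sub <- H[poly, carriers, drop = FALSE]
    sub[is.na(sub)] <- 9L
    apply(sub, 2L, paste, collapse = "")
  }
  tab <- table(strings)
  haps <- data.frame(string = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  haps$freq <- haps$count / sum(haps$count)
  haps <- haps[order(-haps$count, haps$string), , drop = FALSE]
  rownames(haps) <- NULL
  if (degenerate)
    warning("no polymorphic flanking sites in window; degenerate haplotype set")
  structure(list(haps = haps, major = haps$string[1],
                 n_carriers = length(carriers), n_sites = length(poly),
                 span = c(lo, hi), focal = focal, degenerate = degenerate),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haps), "distinct haplotype(s) over",
      x$n_sites, "site(s),", x$n_carriers, "carrier(s)\n")
  invisible(x)
}

#' Frequency-weighted Levenshtein homogeneity statistic
#'
#' `D = sum_h f_h * Lev(major, h) / S`, the mean edit distance of a random
#' carrier haplotype from the major haplotype, normalized by the major
#' haplotype's string length S (one symbol per site). The major haplotype
#' itself contributes zero, so `D = 0` iff a single distinct haplotype
#' exists; values near zero indicate the single-predominant-haplotype
#' signature of a hard (classic) sweep.
#'
#' With `weighting = "alternatives"` the weights are renormalized over the
#' non-major haplotypes only (an alternative reading of frequency-weighted
#' averaging); the default weights over all carriers.
#'
#' @param hs a `haplotype_set` from [extract_haplotypes()].
#' @param weighting `"carriers"` (default) or `"alternatives"`.
#' @return `D` in `[0, 1]` (0 for a degenerate single-site-free window).
#' @export
weighted_levenshtein <- function(hs, weighting = c("carriers", "alternatives")) {
  weighting <- match.arg(weighting)
  if (hs$degenerate || nrow(hs$haps) == 1L) return(0)
  S <- nchar(hs$major)
  d <- as.numeric(adist(hs$major, hs$haps$string))
  w <- hs$haps$freq
  if (weighting == "alternatives") {
    alt <- hs$haps$string != hs$major
    w <- w * alt / sum(w[alt])
  }
  sum(w * d) / S
}

#' Classify a site as hard-sweep-like
#'
#' A site is `hard-like` when its weighted Levenshtein distance does not
#' exceed `ref_threshold` (the mean distance in a reference set of accepted
#' classic sweeps) and the local recombination rate lies inside
#' `recomb_range` (the range observed at those reference sites), both
#' boundaries inclusive. A missing recombination rate makes the site
#' `unclassifiable`.
#'
#' @param D weighted Levenshtein distance.
#' @param recomb_rate local rate in cM/Mb (e.g. [local_rate()] over the
#'   window).
#' @param ref_threshold default 0.026.
#' @param recomb_range default `c(0, 0.025)` cM/Mb.
#' @return list of class `sweep_call`: `D`, `recomb_rate`, `classification`
#'   in `{"hard-like", "not-hard-like", "unclassifiable"}`.
#' @export
classify_sweep <- function(D, recomb_rate, ref_threshold = 0.026,
                           recomb_range = c(0, 0.025)) {
  cls <- if (is.na(recomb_rate)) "unclassifiable"
  else if (D <= ref_threshold && recomb_rate >= recomb_range[1] &&
           recomb_rate <= recomb_range[2]) "hard-like"
  else "not-hard-like"
  structure(list(D = D, recomb_rate = recomb_rate,
                 classification = cls,
                 ref_threshold = ref_threshold,
                 recomb_range = recomb_range),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  cat("sweep_call:", x$classification, "(D =", signif(x$D, 3),
      ", rate =", signif(x$recomb_rate, 3), "cM/Mb)\n")
  invisible(x)
}

#' Chance-corrected excess of hard-like sites
#'
#' Compares the fraction of hard-like classifications among target sites
#' with the fraction among matched control sites classified under identical
#' thresholds: the difference estimates the true fraction of targets with
#' hard-sweep haplotype characteristics beyond what arises by chance. A
#' Fisher exact test on the 2x2 table assesses the contrast.
#'
#' @param calls_targets,calls_controls lists of `sweep_call` objects (or
#'   character vectors of classifications). Unclassifiable calls are
#'   excluded.
#' @return list: `obs_pct`, `chance_pct`, `excess_pct` (percentages),
#'   `fisher_p`, `table` (2x2 counts).
#' @export
excess_hard_fraction <- function(calls_targets, calls_controls) {
  cls <- function(x) {
    v <- vapply(x, function(c) if (is.character(c)) c else c$classification, "")
    v[v != "unclassifiable"]
  }
  tg <- cls(calls_targets)
  ct <- cls(calls_controls)
  if (!length(tg) || !length(ct)) stop("empty call set")
  tab <- matrix(c(sum(tg == "hard-like"), sum(tg != "hard-like"),
                  sum(ct == "hard-like"), sum(ct != "hard-like")),
                nrow = 2, dimnames = list(c("hard", "not"),
                                          c("target", "control")))
  obs <- 100 * tab[1, 1] / sum(tab[, 1])
  cha <- 100 * tab[1, 2] / sum(tab[, 2])
  list(obs_pct = obs, chance_pct = cha, excess_pct = obs - cha,
       fisher_p = fisher.test(tab)$p.value, table = tab)
}
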