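# Extended-haplotype statistics: EHH decay curves, integrated EHH (iHH),
# iHS with frequency-bin standardization, and cross-population XP-EHH.

hap_cols_for_group <- function(gts, panel, group, level) {
  hg <- hap_groups(gts, panel, level)
  list(H = hg$gts$H[, hg$hap_lab == group, drop = FALSE], gts = hg$gts)
}

# homozygosity of a partition: sum C(n_h, 2) / C(n, 2)
hh_of_groups <- function(gid) {
  n <- length(gid)
  if (n < 2) return(NA_real_)
  tab <- tabulate(gid)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity around a focal site
#'
#' EHH at offset x is the probability that two randomly drawn carrier
#' haplotypes are identical over all sites between the focal site and x:
#' `EHH(x) = sum_h C(n_h, 2) / C(n_core, 2)` over distinct extended
#' haplotypes h. EHH(0) = 1 and the curve is non-increasing outward on each
#' side.
#'
#' @param gts a [polarized_genotypes()] object (one chromosome).
#' @param focal site row index.
#' @param core `"derived"`, `"ancestral"`, or `"all"` (all haplotypes, used
#'   by XP-EHH).
#' @param map a `recomb_map` for genetic distances.
#' @param panel,group,level optional restriction to one group's haplotypes.
#' @param max_extend_bp maximum extension from the focal site (default 1 Mb).
#' @return object of class `ehh_curve`: data.frame `curve` with `side`,
#'   `pos`, `bp_offset`, `cm_offset`, `ehh`; plus `n_core`, `focal`, `core`.
#'   `NULL` (with a warning) when fewer than two core haplotypes exist.
#' @export
ehh <- function(gts, focal, core = c("derived", "ancestral", "all"),
                map = NULL, panel = NULL, group = NULL,
                level = c("population", "continent"), max_extend_bp = 1e6) {
  core <- match.arg(core)
  level <- match.arg(level)
  H <- gts$H
  if (!is.null(panel) && !is.null(group)) {
    hc <- hap_cols_for_group(gts, panel, group, level)
    H <- hc$H
    gts <- hc$gts
  }
  a <- H[focal, ]
  carriers <- switch(core,
                     derived = which(a == 1L),
                     ancestral = which(a == 0L),
                     all = which(!is.na(a)))
  if (length(carriers) < 2L) {
    warning("fewer than 2 core haplotypes; EHH undefined")
    return(NULL)
  }
  pos <- gts$variants$pos
  chrom <- gts$variants$chrom
  on_chrom <- chrom == chrom[focal] &
    abs(pos - pos[focal]) <= max_extend_bp
  sub <- which(on_chrom)
  Hc <- H[sub, carriers, drop = FALSE]
  Hc[is.na(Hc)] <- 2L      # missing treated as its own allele symbol
  p <- pos[sub]
  f_idx <- match(focal, sub)

  walk <- function(idx_seq) {
    gid <- rep(1L, ncol(Hc))
    out_pos <- numeric(length(idx_seq))
    out_ehh <- numeric(length(idx_seq))
    for (k in seq_along(idx_seq)) {
      i <- idx_seq[k]
      gid <- as.integer(interaction(gid, Hc[i, ], drop = TRUE))
      out_pos[k] <- p[i]
      out_ehh[k] <- hh_of_groups(gid)
    }
    list(pos = out_pos, ehh = out_ehh)
  }
  right <- walk(seq_len(length(sub))[-seq_len(f_idx)])
  left <- walk(rev(seq_len(f_idx - 1L)))

  mk <- function(side, w) {
    if (!length(w$pos)) return(NULL)
    data.frame(side = side, pos = w$pos,
               bp_offset = abs(w$pos - pos[focal]),
               cm_offset = if (is.null(map)) NA_real_ else
                 abs(map_cm(map, w$pos) - map_cm(map, pos[focal])),
               ehh = w$ehh)
  }
  curve <- rbind(
    data.frame(side = "focal", pos = pos[focal], bp_offset = 0,
               cm_offset = 0, ehh = 1),
    mk("right", right), mk("left", left))
  rownames(curve) <- NULL
  structure(list(curve = curve, n_core = length(carriers), focal = focal,
                 core = core), class = "ehh_curve")
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve over genetic distance (cM), summed
#' over the two sides. Integration proceeds outward and stops after the
#' first point at which EHH falls below `cutoff` (that trapezoid is
#' included); if the curve never reaches the cutoff before the window edge
#' the integral is truncated there and flagged.
#'
#' @param curve an `ehh_curve` from [ehh()] (with cM offsets).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return list `ihh` (cM-weighted area), `truncated` (logical per side).
#' @export
ihh <- function(curve, cutoff = 0.05) {
  cv <- curve$curve
  if (all(is.na(cv$cm_offset)))
    stop("EHH curve has no genetic-map distances; supply a map to ehh()")
  side_area <- function(side) {
    s <- cv[cv$side == side, , drop = FALSE]
    s <- s[order(s$cm_offset), , drop = FALSE]
    x <- c(0, s$cm_offset)
    y <- c(1, s$ehh)
    area <- 0
    trunc <- TRUE
    for (i in seq_len(length(x) - 1L)) {
      area <- area + (x[i + 1] - x[i]) * (y[i + 1] + y[i]) / 2
      if (y[i + 1] < cutoff) { trunc <- FALSE; break }
    }
    list(area = area, trunc = trunc)
  }
  r <- side_area("right")
  l <- side_area("left")
  list(ihh = r$area + l$area, truncated = c(left = l$trunc, right = r$trunc))
}

#' Raw iHS at one site
#'
#' `ln(iHH_ancestral / iHH_derived)` within one population: negative values
#' indicate unusually long derived-allele haplotypes, the classic signature
#' of an incomplete sweep. Standardize with [standardize_scores()].
#'
#' @inheritParams ehh
#' @param site focal site row index.
#' @param cutoff EHH integration cutoff.
#' @return list `raw`, `daf` (derived frequency among the group's
#'   haplotypes), `truncated`; `NULL` if either allele has fewer than two
#'   carriers or a degenerate integral.
#' @export
ihs <- function(gts, site, map, panel = NULL, group = NULL,
                level = c("population", "continent"),
                max_extend_bp = 1e6, cutoff = 0.05) {
  level <- match.arg(level)
  ca <- ehh(gts, site, "ancestral", map, panel, group, level, max_extend_bp)
  cd <- ehh(gts, site, "derived", map, panel, group, level, max_extend_bp)
  if (is.null(ca) || is.null(cd)) return(NULL)
  ia <- ihh(ca, cutoff)
  id <- ihh(cd, cutoff)
  if (ia$ihh <= 0 || id$ihh <= 0) return(NULL)
  freq <- cd$n_core / (ca$n_core + cd$n_core)
  list(raw = log(ia$ihh / id$ihh), daf = freq,
       truncated = any(ia$truncated, id$truncated))
}

#' Raw XP-EHH between two groups at one site
#'
#' `ln(iHH_A / iHH_B)` where each iHH integrates the all-haplotype EHH of
#' one group from the shared focal site. Positive values indicate longer
#' haplotypes (more recent selection) in group A. Antisymmetric in the two
#' groups.
#'
#' @inheritParams ihs
#' @param groupA,groupB group labels in the panel.
#' @return list `raw`, `daf` (pooled derived frequency over both groups),
#'   `truncated`; `NULL` on degenerate integrals.
#' @export
xpehh <- function(gts, site, map, panel, groupA, groupB,
                  level = c("population", "continent"),
                  max_extend_bp = 1e6, cutoff = 0.05) {
  level <- match.arg(level)
  cA <- ehh(gts, site, "all", map, panel, groupA, level, max_extend_bp)
  cB <- ehh(gts, site, "all", map, panel, groupB, level, max_extend_bp)
  if (is.null(cA) || is.null(cB)) return(NULL)
  iA <- ihh(cA, cutoff)
  iB <- ihh(cB, cutoff)
  if (iA$ihh <= 0 || iB$ihh <= 0) return(NULL)
  hgA <- hap_cols_for_group(gts, panel, groupA, level)$H[site, ]
  hgB <- hap_cols_for_group(gts, panel, groupB, level)$H[site, ]
  pooled <- mean(c(hgA, hgB), na.rm = TRUE)
  list(raw = log(iA$ihh / iB$ihh), daf = pooled,
       truncated = any(iA$truncated, iB$truncated))
}

#' Standardize raw haplotype scores within frequency bins
#'
#' Scores are grouped into derived-allele-frequency classes of width
#' `bin_width`; bins with fewer than `min_per_bin` scores are merged with
#' their nearest neighbour; each score is then z-standardized within its
#' bin, so that standardized scores are comparable across frequencies
#' (within each bin, mean 0 and sd 1).
#'
#' @param raw numeric vector of raw ln-ratio scores.
#' @param freq derived allele frequencies, same length.
#' @param bin_width frequency class width (default 0.05).
#' @param min_per_bin minimum scores per class before merging (default 20).
#' @return data.frame `raw`, `freq`, `bin` (final class id), `std`.
#' @export
standardize_scores <- function(raw, freq, bin_width = 0.05,
                               min_per_bin = 20) {
  stopifnot(length(raw) == length(freq))
  ok <- is.finite(raw) & is.finite(freq)
  bin <- pmin(floor(freq / bin_width), floor(1 / bin_width) - 1e-9)
  bin[!ok] <- NA
  # merge thin bins into their nearest populated neighbour
  repeat {
    tab <- table(bin[ok])
    thin <- names(tab)[tab < min_per_bin]
    if (!length(thin) || length(tab) <= 1L) break
    b <- as.numeric(thin[1])
    others <- as.numeric(setdiff(names(tab), thin[1]))
    nearest <- others[which.min(abs(others - b))]
    bin[!is.na(bin) & bin == b] <- nearest
  }
  std <- rep(NA_real_, length(raw))
  for (b in unique(bin[ok])) {
    i <- which(!is.na(bin) & bin == b)
    mu <- mean(raw[i])
    s <- sd(raw[i])
    std[i] <- if (is.na(s) || s == 0) 0 else (raw[i] - mu) / s
  }
  data.frame(raw = raw, freq = freq, bin = bin, std = std)
}
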