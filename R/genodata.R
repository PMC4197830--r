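# Data model and I/O: phased VCF ingestion, ancestral/derived polarization,
# sample panels and recombination maps.

#' Construct a polarized genotype set
#'
#' The central data container: an ordered table of variant records together
#' with a site-by-haplotype 0/1 matrix in which 1 denotes the derived allele
#' (the allele differing from the inferred ancestral state).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `vclass` (one of `"SNP"`, `"INDEL"`, `"SV"`), `ancestral`,
#'   and optionally `impq` (imputation quality in `[0, 1]`).
#' @param H integer matrix, sites x haplotypes, entries 0 (ancestral),
#'   1 (derived) or `NA` (missing); column names `"<sample>_1"`, `"<sample>_2"`.
#' @param samples character vector of sample identifiers; haplotype columns
#'   `2*i - 1` and `2*i` belong to sample `i`.
#' @param phased logical, whether haplotypes are phased.
#' @param drop_counts named list of per-filter drop counters accumulated
#'   during polarization.
#' @return An object of class `polarized_genotypes`. Sites are sorted by
#'   `(chrom, pos, alt)`.
#' @export
polarized_genotypes <- function(variants, H, samples, phased = TRUE,
                                drop_counts = list()) {
  stopifnot(is.data.frame(variants), nrow(variants) == nrow(H))
  if (!is.matrix(H)) H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (ncol(H) != 2L * length(samples))
    stop("haplotype count must be twice the sample count")
  if (any(variants$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
  if (is.null(variants$impq)) variants$impq <- NA_real_
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  H <- H[ord, , drop = FALSE]
  rownames(variants) <- NULL
  colnames(H) <- paste0(rep(samples, each = 2L), "_", 1:2)
  mono <- rowSums(H == 1L, na.rm = TRUE) == 0L |
    rowSums(H == 0L, na.rm = TRUE) == 0L
  structure(list(variants = variants, H = H, samples = samples,
                 phased = phased, monomorphic = mono,
                 drop_counts = drop_counts),
            class = "polarized_genotypes")
}

#' @export
print.polarized_genotypes <- function(x, ...) {
  cat("polarized_genotypes:", nrow(x$variants), "sites x",
      ncol(x$H), "haplotypes (", length(x$samples), "samples,",
      if (x$phased) "phased" else "unphased", ")\n")
  cat("  classes:", paste(names(table(x$variants$vclass)),
                          table(x$variants$vclass), collapse = ", "), "\n")
  if (any(x$monomorphic)) cat("  monomorphic rows:", sum(x$monomorphic), "\n")
  invisible(x)
}

#' @export
dim.polarized_genotypes <- function(x) dim(x$H)

#' Subset sites of a polarized genotype set
#' @param gts a `polarized_genotypes` object.
#' @param i logical or integer index over sites.
#' @return a `polarized_genotypes` object with the selected sites.
#' @export
subset_sites <- function(gts, i) {
  polarized_genotypes(gts$variants[i, , drop = FALSE],
                      gts$H[i, , drop = FALSE],
                      gts$samples, gts$phased, gts$drop_counts)
}

variant_class <- function(ref, alt) {
  ifelse(grepl("^<.+>$", alt), "SV",
         ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"))
}

parse_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Read a phased VCF
#'
#' Parses a (possibly gzipped) VCF 4.x file via `vcfR`, extracting genotypes,
#' the ancestral-allele INFO annotation and an optional imputation-quality
#' INFO key. Multiallelic records are skipped by default or split into one
#' biallelic record per alternate allele.
#'
#' @param path VCF file path (plain or gzip).
#' @param region optional `"chrom:start-end"` string restricting sites.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @param aa_key INFO key holding the ancestral allele (default `"AA"`).
#' @param impq_key INFO key holding imputation quality (default `"RSQ"`).
#' @param require_phased error on the first unphased genotype when `TRUE`.
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, vclass,
#'   ancestral, impq), `A` (sites x haplotypes matrix of 0/1 alternate-allele
#'   indicators, `NA` for missing), `samples`, and `phased`.
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "split"),
                     aa_key = "AA", impq_key = "RSQ", require_phased = TRUE) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  info <- fix[, "INFO"]

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- chrom == rg$chrom & pos >= rg$start & pos <= rg$end
  }

  gtcol <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))

  rows <- list()
  hap_list <- list()
  for (i in which(keep)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && multiallelic == "skip") next
    g <- gtcol[i, ]
    sep <- if (any(grepl("/", g, fixed = TRUE))) {
      if (require_phased)
        stop("unphased genotype at ", chrom[i], ":", pos[i],
             " but phased data required")
      "/"
    } else "|"
    parts <- strsplit(g, sep, fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) parts[bad] <- list(c(NA_character_, NA_character_))
    al <- suppressWarnings(as.integer(unlist(parts)))
    aa <- parse_info_field(info[i], aa_key)
    if (!is.na(aa)) aa <- toupper(sub("\\|.*$", "", aa))
    iq <- suppressWarnings(as.numeric(parse_info_field(info[i], impq_key)))
    for (j in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[j],
        vclass = variant_class(ref[i], alts[j]),
        ancestral = if (is.na(aa)) NA_character_ else aa,
        impq = iq, stringsAsFactors = FALSE)
      hap_list[[length(hap_list) + 1L]] <- as.integer(al == j)
    }
  }
  if (!length(rows))
    return(list(variants = data.frame(), A = matrix(integer(), 0, 0),
                samples = samples, phased = TRUE))
  variants <- do.call(rbind, rows)
  A <- do.call(rbind, hap_list)
  colnames(A) <- paste0(rep(samples, each = 2L), "_", 1:2)
  list(variants = variants, A = A, samples = samples,
       phased = !any(grepl("/", gtcol, fixed = TRUE)))
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region: ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Polarize raw variants to ancestral/derived coding
#'
#' Recodes alternate-allele indicators to derived-allele indicators using the
#' ancestral-allele annotation. Sites whose ancestral allele is missing or
#' matches neither allele are dropped and counted. Symbolic structural
#' variants without an annotation are assumed derived relative to an
#' ancestral reference allele (logged as an assumption).
#'
#' @param raw result of [read_vcf()].
#' @return a [polarized_genotypes()] object; `drop_counts` records the number
#'   of sites removed as unpolarizable.
#' @export
polarize <- function(raw) {
  v <- raw$variants
  if (!nrow(v)) stop("no polarizable sites")
  anc <- v$ancestral
  sv_assumed <- v$vclass == "SV" & is.na(anc)
  if (any(sv_assumed)) {
    anc[sv_assumed] <- v$ref[sv_assumed]
    message(sum(sv_assumed),
            " symbolic SV site(s) assumed ancestral = REF (no AA annotation)")
  }
  usable <- !is.na(anc) & (anc == v$ref | anc == v$alt)
  n_missing <- sum(is.na(anc))
  n_mismatch <- sum(!is.na(anc) & !(anc == v$ref | anc == v$alt))
  if (!any(usable)) stop("no polarizable sites")
  v <- v[usable, , drop = FALSE]
  anc <- anc[usable]
  A <- raw$A[usable, , drop = FALSE]
  flip <- anc == v$alt      # alt allele is ancestral: derived = ref
  H <- A
  H[flip, ] <- 1L - H[flip, , drop = FALSE]
  v$ancestral <- anc
  polarized_genotypes(v, H, raw$samples, phased = raw$phased,
                      drop_counts = list(aa_missing = n_missing,
                                         aa_mismatch = n_mismatch))
}

#' Write a polarized genotype set to VCF
#'
#' Emits a minimal phased VCF 4.2 with `AA` (and, when present, `RSQ`) INFO
#' annotations, suitable for round-tripping through [read_vcf()] and
#' [polarize()].
#'
#' @param gts a `polarized_genotypes` object.
#' @param path output path (plain text).
#' @export
write_vcf <- function(gts, path) {
  v <- gts$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gts$samples), collapse = "\t")), con)
  ns <- length(gts$samples)
  # derived indicator -> alt-allele indicator
  flip <- v$ancestral == v$alt
  A <- gts$H
  A[flip, ] <- 1L - A[flip, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    info <- paste0("AA=", v$ancestral[i])
    if (!is.na(v$impq[i])) info <- paste0(info, ";RSQ=", v$impq[i])
    a <- A[i, ]
    g <- paste(ifelse(is.na(a[seq(1, 2 * ns, 2)]), ".", a[seq(1, 2 * ns, 2)]),
               ifelse(is.na(a[seq(2, 2 * ns, 2)]), ".", a[seq(2, 2 * ns, 2)]),
               sep = "|")
    writeLines(paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                       "PASS", info, "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample panel
#'
#' @param path TSV with header columns `sample`, `population`, `continent`.
#' @return data.frame of class `population_panel` with one row per sample.
#' @export
read_panel <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "population", "continent") %in% names(p)))
    stop("panel must have columns sample, population, continent")
  key <- paste(p$sample, p$population, p$continent)
  p <- p[!duplicated(key), , drop = FALSE]
  if (anyDuplicated(p$sample))
    stop("conflicting duplicate panel assignment for sample(s): ",
         paste(unique(p$sample[duplicated(p$sample)]), collapse = ", "))
  rownames(p) <- NULL
  class(p) <- c("population_panel", "data.frame")
  p
}

#' Build a panel in memory
#' @param sample,population,continent equal-length character vectors.
#' @return data.frame of class `population_panel`.
#' @export
make_panel <- function(sample, population, continent) {
  p <- data.frame(sample = sample, population = population,
                  continent = continent, stringsAsFactors = FALSE)
  class(p) <- c("population_panel", "data.frame")
  p
}

#' Align a panel with a genotype set
#'
#' Restricts both to the shared samples; panel samples absent from the
#' genotypes are dropped with a warning.
#'
#' @param gts a `polarized_genotypes` object.
#' @param panel a `population_panel`.
#' @return list `gts`, `panel` restricted to shared samples.
#' @export
align_panel <- function(gts, panel) {
  shared <- intersect(gts$samples, panel$sample)
  if (!length(shared)) stop("no samples shared between genotypes and panel")
  if (length(shared) < nrow(panel))
    warning(nrow(panel) - length(shared),
            " panel sample(s) absent from the genotypes; ignored")
  panel <- panel[match(shared, panel$sample), , drop = FALSE]
  if (length(shared) < length(gts$samples)) {
    keep_h <- rep(gts$samples %in% shared, each = 2L)
    gts <- polarized_genotypes(gts$variants, gts$H[, keep_h, drop = FALSE],
                               gts$samples[gts$samples %in% shared],
                               gts$phased, gts$drop_counts)
  }
  list(gts = gts, panel = panel)
}

#' Read a recombination map
#'
#' HapMap-style text map: columns position (bp), rate (cM/Mb) for the
#' interval starting at that position, and cumulative genetic position (cM).
#' Queries are answered by piecewise-linear interpolation of the cumulative
#' map, held constant beyond its ends.
#'
#' @param path whitespace- or tab-separated text file (gzip transparent),
#'   with or without a header line.
#' @return object of class `recomb_map` supporting [map_cm()] and
#'   [local_rate()].
#' @export
read_recomb_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "[ \t]+")[[1]][1])))
  m <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  recomb_map(pos = as.numeric(m[[1]]), rate = as.numeric(m[[2]]),
             cm = as.numeric(m[[3]]), source = path)
}

#' Construct a recombination map from vectors
#' @param pos bp positions (ascending).
#' @param rate cM/Mb over the interval starting at each position.
#' @param cm cumulative cM at each position; defaults to the integral of
#'   `rate`.
#' @param source optional provenance label.
#' @return object of class `recomb_map`.
#' @export
recomb_map <- function(pos, rate, cm = NULL, source = NULL) {
  if (is.unsorted(pos, strictly = TRUE))
    stop("map positions must be strictly increasing")
  if (is.null(cm))
    cm <- cumsum(c(0, diff(pos) * rate[-length(rate)] / 1e6))
  bad <- which(diff(cm) < 0)
  if (length(bad))
    stop("non-monotone cumulative cM at map line ", bad[1] + 1L)
  structure(list(pos = pos, rate = rate, cm = cm, source = source),
            class = "recomb_map")
}

#' Genetic position (cM) at base-pair coordinates
#' @param map a `recomb_map`.
#' @param bp numeric vector of positions.
#' @return cM positions, linearly interpolated (constant beyond map ends).
#' @export
map_cm <- function(map, bp) {
  approx(map$pos, map$cm, xout = bp, rule = 2)$y
}

#' Mean local recombination rate over an interval
#' @param map a `recomb_map`.
#' @param start,end interval in bp.
#' @return rate in cM/Mb averaged over `[start, end]`.
#' @export
local_rate <- function(map, start, end) {
  if (end <= start) return(NA_real_)
  (map_cm(map, end) - map_cm(map, start)) / ((end - start) / 1e6)
}

#' Uniform recombination map over a region
#' @param length_bp region length.
#' @param rate_cm_mb uniform rate in cM/Mb.
#' @return a `recomb_map`.
#' @export
uniform_map <- function(length_bp, rate_cm_mb) {
  recomb_map(pos = c(1, length_bp), rate = c(rate_cm_mb, rate_cm_mb),
             source = "uniform")
}
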