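# End-to-end orchestration: a config-driven pipeline over the package's
# stages (simulate/ingest -> frequencies -> scans -> haplotype statistics ->
# sweep classification), with seeds, stage outputs and a JSON run manifest.

#' Run the full differentiation-scan pipeline
#'
#' Stages, in order: (1) obtain genotypes, either by simulating a replicate
#' (optionally with a planted sweep) or by reading a VCF + panel (+ map);
#' (2) continent-level frequency table; (3) between-continent HighD scans
#' for all pairs, deduplicated; (4) LowD scan at population level;
#' (5) sweep classification (weighted Levenshtein + recombination
#' conditioning) of every retained HighD site in its assigned group;
#' (6) optional gene-overlap enrichment when gene annotations are supplied.
#' Every stage's row counts, the full configuration and the seed are echoed
#' into the manifest, so a rerun with the same config is reproducible.
#'
#' @param config nested list (or path to a YAML file):
#'   \describe{
#'     \item{input}{either `list(simulate = list(region_bp, n_per_pop,
#'       sweep = list(target_af, duration, pop, ...)))` or `list(vcf =,
#'       panel =, map = )` paths.}
#'     \item{model}{[demographic_model()] arguments (simulation input).}
#'     \item{scan}{[scan_config()] arguments.}
#'     \item{classify}{`ref_threshold`, `recomb_range`, `window_bp`.}
#'     \item{enrich}{optional: `genes_bed`, `reference_genes` (path, one id
#'       per line).}
#'     \item{seed}{integer.}
#'     \item{out_dir}{output directory for TSV stage outputs and
#'       `manifest.json`; omit to skip writing.}
#'   }
#' @return list of class `pipeline_run`: `manifest`, `highd`, `lowd`,
#'   `calls`, `enrichment`, `replicate`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "popdiffscan",
                   version = as.character(utils::packageVersion("popdiffscan")),
                   seed = seed, config = config, stages = list())

  # ---- stage 1: genotypes ----
  replicate <- NULL
  if (!is.null(config$input$simulate)) {
    sim <- config$input$simulate
    model <- do.call(demographic_model,
                     if (is.null(config$model)) list() else config$model)
    region_bp <- if (is.null(sim$region_bp)) 1e5 else sim$region_bp
    n_per_pop <- if (is.null(sim$n_per_pop)) 50 else sim$n_per_pop
    if (!is.null(sim$sweep)) {
      scen <- do.call(sweep_scenario, sim$sweep)
      replicate <- simulate_sweep(model, scen, region_bp, n_per_pop, seed)
    } else {
      replicate <- simulate_neutral(model, region_bp, n_per_pop, seed)
    }
    gts <- replicate$gts
    panel <- replicate$panel
    map <- replicate$map
  } else if (!is.null(config$input$vcf)) {
    gts <- polarize(read_vcf(config$input$vcf))
    panel <- read_panel(config$input$panel)
    map <- if (!is.null(config$input$map)) read_recomb_map(config$input$map)
           else NULL
  } else stop("config$input must provide either simulate or vcf")
  manifest$stages$genotypes <- list(n_sites = nrow(gts$variants),
                                    n_samples = length(gts$samples))

  # ---- stage 2: frequencies ----
  ft_cont <- daf(gts, panel, level = "continent")
  ft_pop <- daf(gts, panel, level = "population")
  manifest$stages$frequencies <- list(continents = colnames(ft_cont$daf),
                                      populations = colnames(ft_pop$daf))

  # ---- stage 3: HighD scans (between continents) ----
  cfg <- do.call(scan_config,
                 if (is.null(config$scan)) list() else config$scan)
  conts <- colnames(ft_cont$daf)
  pairs <- if (length(conts) >= 2) utils::combn(conts, 2, simplify = FALSE)
           else list()
  scans <- lapply(pairs, function(p) {
    sc <- rank_pvalues(delta_daf(ft_cont, p))
    sc <- qc_filter(sc, cfg$min_impq)
    highd_scan(sc, cfg, level = "between")
  })
  highd <- dedup_union(scans)
  manifest$stages$highd <- list(n_pairs = length(pairs),
                                n_retained = nrow(highd))

  # ---- stage 4: LowD scan (across populations) ----
  lowd <- lowd_scan(ft_pop, cfg)
  manifest$stages$lowd <- list(n_retained = nrow(lowd$sites))

  # ---- stage 5: sweep classification of HighD sites ----
  ccfg <- config$classify
  window_bp <- if (is.null(ccfg$window_bp)) 2000 else ccfg$window_bp
  ref_threshold <- if (is.null(ccfg$ref_threshold)) 0.026 else ccfg$ref_threshold
  recomb_range <- if (is.null(ccfg$recomb_range)) c(0, 0.025)
                  else ccfg$recomb_range
  calls <- NULL
  if (nrow(highd)) {
    key <- with(gts$variants, paste(chrom, pos, ref, alt))
    calls <- do.call(rbind, lapply(seq_len(nrow(highd)), function(i) {
      idx <- match(paste(highd$chrom[i], highd$pos[i], highd$ref[i],
                         highd$alt[i]), key)
      dafs <- ft_cont$daf[idx, ]
      grp <- names(which.max(dafs))     # assigned group: highest DAF
      hs <- extract_haplotypes(gts, idx, window_bp, panel, grp,
                               level = "continent")
      D <- weighted_levenshtein(hs)
      rate <- if (is.null(map)) NA_real_ else
        local_rate(map, max(1, gts$variants$pos[idx] - window_bp / 2),
                   gts$variants$pos[idx] + window_bp / 2)
      call <- classify_sweep(D, rate, ref_threshold, recomb_range)
      data.frame(chrom = highd$chrom[i], pos = highd$pos[i], group = grp,
                 D = D, recomb_rate = rate,
                 classification = call$classification,
                 stringsAsFactors = FALSE)
    }))
    manifest$stages$classify <-
      list(n_classified = nrow(calls),
           n_hard_like = sum(calls$classification == "hard-like"))
  } else {
    manifest$stages$classify <- list(n_classified = 0L, skipped = FALSE)
  }

  # ---- stage 6: enrichment (only with annotations) ----
  enrichment <- NULL
  if (!is.null(config$enrich$genes_bed) &&
      !is.null(config$enrich$reference_genes) && nrow(highd)) {
    genes <- read_genes_bed(config$enrich$genes_bed)
    refg <- readLines(config$enrich$reference_genes)
    ann <- annotate_genes(highd, genes)
    host <- unique(unlist(lapply(which(ann$genic), function(i)
      genes$name[genes$chrom == ann$chrom[i] & genes$start <= ann$pos[i] &
                 genes$end >= ann$pos[i]])))
    universe <- unique(genes$name)
    if (length(host))
      enrichment <- gene_overlap_enrichment(host, refg, universe, seed = seed)
    manifest$stages$enrich <- list(n_host_genes = length(host))
  } else {
    manifest$stages$enrich <- list(skipped = TRUE)
  }

  out <- structure(list(manifest = manifest, highd = highd,
                        lowd = lowd$sites, calls = calls,
                        enrichment = enrichment, replicate = replicate),
                   class = "pipeline_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) if (!is.null(df) && nrow(df))
      write.table(df, file.path(config$out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    wr(highd, "highd_sites.tsv")
    wr(lowd$sites, "lowd_sites.tsv")
    wr(calls, "sweep_calls.tsv")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$manifest$stages
  cat("pipeline_run:", s$genotypes$n_sites, "sites;",
      s$highd$n_retained, "HighD;", s$lowd$n_retained, "LowD;",
      if (!is.null(x$calls)) paste(s$classify$n_hard_like, "hard-like")
      else "no classification", "\n")
  invisible(x)
}
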