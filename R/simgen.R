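# Synthetic-data generator: forward-time Wright-Fisher simulation of a
# three-population out-of-Africa demography with recombination, migration and
# optional selective sweeps of controlled final allele frequency.

#' Three-population demographic model
#'
#' A configurable out-of-Africa skeleton: an ancestral population that grows
#' at `T_af`, an out-of-Africa bottleneck population B splitting at `T_b`,
#' and a European/East-Asian split at `T_eu_as` followed by exponential
#' growth, with symmetric pairwise migration. Default parameter values follow
#' the published three-population calibration of low-coverage phase-I
#' sequence data (Gravel et al. 2011); they are a documented approximation,
#' not a parameter-exact replication of any external model file.
#'
#' All parameters are in natural (unrescaled) units: diploid effective sizes,
#' generations, per-generation rates. `lambda` is the population-size
#' rescaling factor applied before simulation; it divides sizes and times and
#' multiplies mutation, recombination, migration and growth rates, which
#' preserves theta = 4*N*mu, rho = 4*N*r and times in units of 2N
#' generations.
#'
#' @param N_anc,N_af,N_b,N_eu0,N_as0 diploid effective sizes: ancestral,
#'   modern African, out-of-Africa bottleneck, and initial European /
#'   East-Asian sizes at their split.
#' @param g_eu,g_as per-generation exponential growth rates after `T_eu_as`.
#' @param T_af,T_b,T_eu_as event times in generations before present
#'   (African growth, out-of-Africa split, European/East-Asian split).
#' @param m_af_b,m_af_eu,m_af_as,m_eu_as symmetric per-generation migration
#'   fractions.
#' @param mu,rec mutation and recombination rates per bp per generation.
#' @param lambda rescaling factor (>= 1).
#' @param burnin_factor burn-in length in units of the rescaled ancestral
#'   population size.
#' @param npop 3 for the full model, 1 for a single constant-size
#'   population of size `N_anc` (used for neutral-theory checks).
#' @param m_scale multiplier applied to all migration rates (sensitivity
#'   analyses).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(N_anc = 7310, N_af = 14474, N_b = 1861,
                              N_eu0 = 1032, N_as0 = 554,
                              g_eu = 0.0038, g_as = 0.0048,
                              T_af = 5920, T_b = 2040, T_eu_as = 920,
                              m_af_b = 15e-5, m_af_eu = 2.5e-5,
                              m_af_as = 0.78e-5, m_eu_as = 3.11e-5,
                              mu = 2.36e-8, rec = 1.25e-8,
                              lambda = 10, burnin_factor = 8,
                              npop = 3, m_scale = 1) {
  m <- list(N_anc = N_anc, N_af = N_af, N_b = N_b, N_eu0 = N_eu0,
            N_as0 = N_as0, g_eu = g_eu, g_as = g_as, T_af = T_af, T_b = T_b,
            T_eu_as = T_eu_as, m_af_b = m_af_b, m_af_eu = m_af_eu,
            m_af_as = m_af_as, m_eu_as = m_eu_as, mu = mu, rec = rec,
            lambda = lambda, burnin_factor = burnin_factor, npop = npop,
            m_scale = m_scale)
  validate_model(m)
  structure(m, class = "demographic_model")
}

validate_model <- function(m) {
  num_fields <- setdiff(names(m), "npop")
  for (f in num_fields)
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || is.na(m[[f]]))
      stop("invalid demographic model field: ", f)
  if (m$lambda < 1) stop("invalid demographic model field: lambda")
  for (f in c("m_af_b", "m_af_eu", "m_af_as", "m_eu_as", "mu", "rec",
              "m_scale", "g_eu", "g_as"))
    if (m[[f]] < 0) stop("invalid demographic model field: ", f)
  if (m$npop == 3 && !(m$T_af > m$T_b && m$T_b > m$T_eu_as))
    stop("invalid demographic model field: event times must be nested (T_af > T_b > T_eu_as)")
  invisible(m)
}

#' Load a demographic model from a YAML configuration
#' @param path YAML file whose keys are [demographic_model()] arguments; the
#'   packaged default lives at
#'   `system.file("extdata", "ooa_model.yaml", package = "popdiffscan")`.
#' @return object of class `demographic_model`.
#' @export
read_model <- function(path) {
  do.call(demographic_model, yaml::read_yaml(path))
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model (", x$npop, "population(s), lambda =", x$lambda, ")\n")
  cat("  sizes: anc", x$N_anc, "| AFR", x$N_af, "| B", x$N_b,
      "| EUR0", x$N_eu0, "| ASN0", x$N_as0, "\n")
  cat("  times (gen ago): T_af", x$T_af, "| T_b", x$T_b,
      "| T_eu_as", x$T_eu_as, "\n")
  cat("  mu", x$mu, "rec", x$rec, "per bp per generation\n")
  invisible(x)
}

#' Selective sweep scenario
#'
#' Additive selection (relative fitnesses 1, 1+s, 1+2s) on a new variant at
#' the centre of the simulated region. The sweep lasts `duration` generations
#' and always ends `end_time` generations before sampling; the selection
#' coefficient is tuned at run time (logistic initial guess, multiplicative
#' logit-path correction between attempts) and replicates are rejected until
#' the realized final frequency in the selected population is within `band`
#' of `target_af`.
#'
#' @param target_af target final derived allele frequency in the selected
#'   population: one of 0.2, 0.4, 0.6, 0.8, 1.0 (other values in (0, 1] are
#'   accepted).
#' @param duration sweep duration in generations, within `[200, 1200]`.
#' @param end_time generations before sampling at which the sweep ends
#'   (default 401).
#' @param pop selected population: `"AFR"`, `"EUR"` or `"ASN"`. If the sweep
#'   begins before the selected population exists, selection acts in its
#'   ancestor until the split.
#' @param position focal bp position; default the region centre.
#' @param band acceptance half-width on the realized final frequency.
#' @param max_attempts attempts before giving up with an error.
#' @return object of class `sweep_scenario`.
#' @export
sweep_scenario <- function(target_af, duration = 700, end_time = 401,
                           pop = "ASN", position = NULL, band = 0.05,
                           max_attempts = 20000) {
  if (!is.numeric(target_af) || target_af <= 0 || target_af > 1)
    stop("target_af must be in (0, 1]")
  if (duration < 200 || duration > 1200)
    stop("sweep duration must lie in [200, 1200] generations")
  if (!pop %in% c("AFR", "EUR", "ASN")) stop("pop must be AFR, EUR or ASN")
  structure(list(target_af = target_af, duration = duration,
                 end_time = end_time, pop = pop, position = position,
                 band = band, max_attempts = max_attempts),
            class = "sweep_scenario")
}

pop_names <- c("AFR", "EUR", "ASN")

scale_model <- function(model, region_bp) {
  lam <- model$lambda
  ms <- function(m) min(0.45, m * lam * model$m_scale)
  N_anc <- max(2L, as.integer(round(model$N_anc / lam)))
  list(L = as.integer(region_bp), npop = as.integer(model$npop),
       N_anc = N_anc,
       N_af = max(2L, as.integer(round(model$N_af / lam))),
       N_b = max(2L, as.integer(round(model$N_b / lam))),
       N_eu0 = max(2L, as.integer(round(model$N_eu0 / lam))),
       N_as0 = max(2L, as.integer(round(model$N_as0 / lam))),
       g_eu = model$g_eu * lam, g_as = model$g_as * lam,
       T_af = as.integer(round(model$T_af / lam)),
       T_b = as.integer(round(model$T_b / lam)),
       T_euas = as.integer(round(model$T_eu_as / lam)),
       m_af_b = ms(model$m_af_b), m_af_eu = ms(model$m_af_eu),
       m_af_as = ms(model$m_af_as), m_eu_as = ms(model$m_eu_as),
       mu = model$mu * lam, rec = model$rec * lam,
       burnin = as.integer(round(model$burnin_factor * N_anc)))
}

# deterministic per-replicate seed derived from a base seed (kept < 2^31)
replicate_seed <- function(seed, index) {
  (as.double(seed) * 2654435761 + as.double(index) * 40503) %% 2147483647 + 1
}

run_wf <- function(model, region_bp, n_per_pop, seed, scenario = NULL) {
  par <- scale_model(model, region_bp)
  lam <- model$lambda
  if (is.null(scenario)) {
    par$has_sweep <- FALSE
    par$sel_pop <- 0L; par$focal <- 0L; par$target <- 0; par$band <- 0
    par$sweep_start <- 0L; par$sweep_end <- 0L; par$s_init <- 0
    par$max_attempts <- 0L
  } else {
    par$has_sweep <- TRUE
    par$sel_pop <- match(scenario$pop, pop_names) - 1L
    focal <- if (is.null(scenario$position)) as.integer(region_bp / 2)
             else as.integer(scenario$position)
    par$focal <- focal - 1L   # 0-based internally
    par$target <- scenario$target_af
    par$band <- scenario$band
    par$sweep_start <- as.integer(round((scenario$end_time + scenario$duration) / lam))
    par$sweep_end <- as.integer(round(scenario$end_time / lam))
    if (par$sweep_start <= par$sweep_end)
      par$sweep_start <- par$sweep_end + 1L
    # logistic initial guess for the rescaled selection coefficient, with the
    # effective starting frequency inflated for conditioning on establishment
    dur_r <- par$sweep_start - par$sweep_end
    sel_slot_start <- sweep_start_slot(par)
    N_start <- start_pop_size(par, sel_slot_start)
    f0 <- min(0.4, 2 / (2 * N_start))
    tgt <- min(scenario$target_af, 0.995)
    s0 <- (log(tgt / (1 - tgt)) - log(f0 / (1 - f0))) / dur_r
    par$s_init <- max(s0, 1e-3)
    par$max_attempts <- as.integer(scenario$max_attempts)
  }
  par$n_samp <- as.integer(n_per_pop)
  par$seed <- as.double(seed)
  .wf_simulate_cpp(par)
}

sweep_start_slot <- function(par) {
  if (par$sel_pop == 0L) return(0L)
  if (par$sweep_start > par$T_b) return(0L)
  if (par$sweep_start > par$T_euas) return(1L)
  par$sel_pop
}

start_pop_size <- function(par, slot) {
  g <- par$sweep_start
  if (par$npop == 1) return(par$N_anc)
  if (slot == 0L) return(if (g > par$T_af) par$N_anc else par$N_af)
  if (slot == 1L) {
    if (g > par$T_euas) return(par$N_b)
    return(max(2, round(par$N_eu0 * exp(par$g_eu * (par$T_euas - g)))))
  }
  max(2, round(par$N_as0 * exp(par$g_as * (par$T_euas - g))))
}

build_replicate <- function(res, model, region_bp, n_per_pop, seed, scenario) {
  nsite <- length(res$positions)
  conts <- pop_names[res$pop_of + 1L]
  idx_within <- stats::ave(seq_along(conts), conts, FUN = seq_along)
  samples <- sprintf("%s_%03d", conts, idx_within)
  # ~3 exchangeable subpopulation labels per continental group
  subpop <- sprintf("%s%d", conts, (idx_within - 1L) %% 3L + 1L)
  panel <- make_panel(samples, subpop, conts)
  variants <- data.frame(chrom = rep("sim1", nsite), pos = res$positions,
                         ref = rep("A", nsite), alt = rep("C", nsite),
                         vclass = rep("SNP", nsite),
                         ancestral = rep("A", nsite),
                         impq = rep(NA_real_, nsite),
                         stringsAsFactors = FALSE)
  gts <- polarized_genotypes(variants, res$H, samples, phased = TRUE)
  sel_index <- res$selected_index
  if (!is.null(scenario) && !is.na(sel_index)) {
    # constructor sorts by (chrom, pos, alt); positions were already sorted
    stopifnot(gts$variants$pos[sel_index] == res$positions[sel_index])
  }
  structure(list(
    gts = gts, panel = panel,
    map = uniform_map(region_bp, model$rec * 1e8),
    region_bp = region_bp, n_per_pop = n_per_pop,
    selected_index = if (is.null(scenario)) NA_integer_ else sel_index,
    selected_pos = if (is.null(scenario)) NA_integer_ else
      res$positions[sel_index],
    pop_freq = setNames(as.numeric(res$pop_freq), pop_names),
    attempts = res$attempts, s_used = res$s_used,
    scenario = scenario, seed = seed), class = "wf_replicate")
}

#' @export
print.wf_replicate <- function(x, ...) {
  cat("wf_replicate:", nrow(x$gts$variants), "segregating sites,",
      length(x$gts$samples), "samples,", x$region_bp, "bp\n")
  if (!is.na(x$selected_index))
    cat("  sweep:", x$scenario$pop, "target", x$scenario$target_af,
        "realized", round(x$pop_freq[x$scenario$pop], 3),
        "( attempts:", x$attempts, ", s =", signif(x$s_used, 3), ")\n")
  invisible(x)
}

#' Simulate a neutral replicate
#'
#' Forward Wright-Fisher simulation under the demographic model, without any
#' selected variant. Polarization is exact by construction: the simulated
#' ancestral state is known.
#'
#' @param model a [demographic_model()].
#' @param region_bp simulated region length in bp (>= 10 kb recommended;
#'   shorter regions are permitted for unit tests).
#' @param n_per_pop diploid individuals sampled per population.
#' @param seed integer seed; the same seed reproduces the replicate exactly.
#' @return object of class `wf_replicate`: `gts` (a
#'   [polarized_genotypes()]), `panel`, `map`, and sweep metadata (all `NA`
#'   here).
#' @export
simulate_neutral <- function(model, region_bp = 1e5, n_per_pop = 50,
                             seed = 1) {
  validate_model(model)
  res <- run_wf(model, region_bp, n_per_pop, seed, scenario = NULL)
  build_replicate(res, model, region_bp, n_per_pop, seed, NULL)
}

#' Simulate a selective sweep replicate
#'
#' As [simulate_neutral()], but a new variant is introduced at the focal
#' position and driven by additive selection so that the sweep ends
#' `end_time` generations before sampling with final frequency within
#' `band` of `target_af` in the selected population (rejection-controlled;
#' the selection coefficient is retuned between attempts). The pre-sweep
#' history is simulated once and checkpointed, so rejected attempts only
#' replay the sweep phase.
#'
#' @inheritParams simulate_neutral
#' @param scenario a [sweep_scenario()].
#' @return object of class `wf_replicate`; `selected_index` is the row of
#'   the focal variant, `pop_freq` its realized population frequencies and
#'   `s_used` the accepted (rescaled) selection coefficient.
#' @export
simulate_sweep <- function(model, scenario, region_bp = 1e5, n_per_pop = 50,
                           seed = 1) {
  validate_model(model)
  stopifnot(inherits(scenario, "sweep_scenario"))
  res <- run_wf(model, region_bp, n_per_pop, seed, scenario = scenario)
  build_replicate(res, model, region_bp, n_per_pop, seed, scenario)
}

#' Expected number of HighD sites under neutrality
#'
#' Simulates neutral replicates, runs the between-continent HighD scan on
#' each, and scales the retained-site count to the size of the accessible
#' genome. A basic nonparametric bootstrap over replicates gives the
#' confidence interval.
#'
#' @param model a [demographic_model()].
#' @param n_replicates number of neutral replicates.
#' @param region_bp region length per replicate.
#' @param scan_cfg a [scan_config()]; the between-continent threshold is
#'   used.
#' @param n_per_pop diploids sampled per population.
#' @param accessible_bp accessible-genome size used for scaling (default
#'   2,526,390,487 bp).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param n_boot bootstrap resamples for the CI.
#' @return list: `scaled_count`, `ci` (2.5/97.5% bootstrap), `raw_count`,
#'   `simulated_bp`, `per_replicate` counts.
#' @export
expected_neutral_highd <- function(model, n_replicates = 20, region_bp = 1e5,
                                   scan_cfg = scan_config(),
                                   n_per_pop = 50,
                                   accessible_bp = 2526390487,
                                   seed = 1, n_boot = 200) {
  counts <- integer(n_replicates)
  n_variants <- 0
  for (r in seq_len(n_replicates)) {
    rep <- simulate_neutral(model, region_bp, n_per_pop,
                            seed = replicate_seed(seed, r))
    n_variants <- n_variants + nrow(rep$gts$variants)
    if (nrow(rep$gts$variants) == 0L) next
    ft <- daf(rep$gts, rep$panel, level = "continent")
    n_hits <- 0L
    for (pair in list(c("AFR", "EUR"), c("AFR", "ASN"), c("EUR", "ASN"))) {
      sc <- delta_daf(ft, pair)
      sc <- rank_pvalues(sc)
      res <- highd_scan(sc, scan_cfg, level = "between")
      n_hits <- n_hits + nrow(res$sites)
    }
    counts[r] <- n_hits
  }
  sim_bp <- as.double(n_replicates) * region_bp
  if (sim_bp <= 0) stop("zero simulated sequence")
  if (n_variants == 0) stop("zero simulated variants")
  scaled <- sum(counts) * accessible_bp / sim_bp
  set.seed(replicate_seed(seed, 999983))
  boot <- replicate(n_boot, {
    idx <- sample.int(n_replicates, replace = TRUE)
    sum(counts[idx]) * accessible_bp / sim_bp
  })
  list(scaled_count = scaled,
       ci = unname(quantile(boot, c(0.025, 0.975))),
       raw_count = sum(counts), simulated_bp = sim_bp,
       per_replicate = counts)
}

#' Sensitivity of the neutral HighD expectation to migration rate
#'
#' Re-evaluates [expected_neutral_highd()] under a grid of migration-rate
#' multipliers, holding everything else (including replicate seeds) fixed.
#' Higher migration homogenizes allele frequencies across populations, so
#' the expected count should trend downward.
#'
#' @param model a [demographic_model()].
#' @param m_scales numeric vector (>= 2 values) of multipliers applied to
#'   all migration rates.
#' @param ... passed to [expected_neutral_highd()].
#' @return data.frame with one row per rate: `m_scale`, `scaled_count`,
#'   `ci_lo`, `ci_hi`; attribute `monotone_decreasing` reports the trend
#'   check.
#' @export
migration_sensitivity <- function(model, m_scales = c(0, 1, 5, 20), ...) {
  if (length(m_scales) < 1L) stop("need at least one migration rate")
  rows <- lapply(m_scales, function(ms) {
    m2 <- model
    m2$m_scale <- ms
    e <- expected_neutral_highd(m2, ...)
    data.frame(m_scale = ms, scaled_count = e$scaled_count,
               ci_lo = e$ci[1], ci_hi = e$ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_decreasing") <-
    !is.unsorted(rev(out$scaled_count), strictly = FALSE)
  out
}

#' Write a replicate to disk in the package's input dialects
#'
#' Emits `replicate.vcf` (phased VCF with AA annotations), `panel.tsv`
#' (sample, population, continent) and `map.txt` (position, rate cM/Mb,
#' cumulative cM), readable by [read_vcf()], [read_panel()] and
#' [read_recomb_map()].
#'
#' @param rep a `wf_replicate`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_replicate <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "replicate.vcf")
  panel <- file.path(dir, "panel.tsv")
  mapf <- file.path(dir, "map.txt")
  write_vcf(rep$gts, vcf)
  write.table(rep$panel, panel, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- rep$map
  write.table(data.frame(pos = m$pos, rate = m$rate, cm = m$cm), mapf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, panel = panel, map = mapf))
}

#' Watterson's estimator of theta from a replicate
#' @param rep a `wf_replicate`.
#' @return estimate of 4*N*mu*L from the number of segregating sites and the
#'   sampled haplotype count.
#' @export
watterson_theta <- function(rep) {
  n <- ncol(rep$gts$H)
  seg <- sum(!rep$gts$monomorphic)
  seg / sum(1 / seq_len(n - 1L))
}
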