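#' Simulation configuration for a two-stage salinity screening trial
#'
#' Defines the structure of a synthetic rice salinity experiment: a diversity
#' panel phenotyped in replicate under control and salt-stress conditions at a
#' germination and an early-seedling stage, plus a biallelic SNP matrix with
#' planted additive causal loci. Defaults mirror the screening design the
#' package targets: 201 genotypes, 3 replicates, 8 germination traits and 16
#' seedling traits, stress imposed at 120 mM NaCl.
#'
#' @param n_genotypes Number of genotypes in the panel.
#' @param n_replicates Replicates per genotype and condition.
#' @param stages Named list: stage label -> character vector of trait names.
#'   `SVI`/`SVII` are derived from `GP`, `TSL`, `DW` per replicate; `SES`
#'   (visual salt-injury score, 1-9) is recorded under stress only.
#' @param n_snps,n_causal Marker count and number of causal loci.
#' @param causal_effect_sizes Additive effect per alt-allele copy for each
#'   causal locus, in units of the latent-tolerance residual SD. Recycled to
#'   `n_causal`.
#' @param stress_severity Fractional mean trait reduction under stress for a
#'   fully susceptible genotype, in `[0, 1)`.
#' @param noise_cv Coefficient of variation of multiplicative replicate noise.
#' @param cross_stage_correlation Correlation of latent tolerance between the
#'   two stages, in `[-1, 1]`.
#' @param missing_genotype_rate,missing_marker_rate Probabilities in `[0, 1]`
#'   of a call being set missing via, respectively, a per-sample and a
#'   per-marker missing-completely-at-random process.
#' @param het_excess_rate Probability of a call being resampled to
#'   heterozygous, used to exercise the heterozygosity QC filter.
#' @param n_chrom Number of chromosomes markers are spread over.
#' @param trait_baselines Named numeric vector of control-condition trait
#'   means. Traits without an entry default to 1; indices downstream are
#'   scale-free so units need no calibration.
#' @param seed Integer RNG seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 201,
                       n_replicates = 3,
                       stages = default_stages(),
                       n_snps = 500,
                       n_causal = 5,
                       causal_effect_sizes = 0.8,
                       stress_severity = 0.45,
                       noise_cv = 0.10,
                       cross_stage_correlation = 0.7,
                       missing_genotype_rate = 0.01,
                       missing_marker_rate = 0.02,
                       het_excess_rate = 0.05,
                       n_chrom = 12,
                       trait_baselines = default_baselines(),
                       seed = 1L) {
  assert_scalar_number(n_genotypes, "n_genotypes", lo = 2)
  assert_scalar_number(n_replicates, "n_replicates", lo = 1)
  assert_scalar_number(n_snps, "n_snps", lo = 1)
  assert_scalar_number(n_causal, "n_causal", lo = 0)
  if (n_causal > n_snps) abort("`n_causal` cannot exceed `n_snps`.")
  assert_scalar_number(stress_severity, "stress_severity", 0, 1 - 1e-12)
  assert_scalar_number(noise_cv, "noise_cv", lo = 0)
  assert_scalar_number(cross_stage_correlation, "cross_stage_correlation", -1, 1)
  for (nm in c("missing_genotype_rate", "missing_marker_rate",
               "het_excess_rate")) {
    assert_scalar_number(get(nm), nm, 0, 1)
  }
  if (!is.list(stages) || is.null(names(stages)) ||
      any(!nzchar(names(stages)))) {
    abort("`stages` must be a named list of trait-name vectors.")
  }
  if (any(vapply(stages, length, 1L) == 0L)) {
    abort("Every stage must list at least one trait.")
  }
  effects <- rep_len(as.numeric(causal_effect_sizes), max(n_causal, 1L))
  if (n_causal == 0) effects <- numeric(0)
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    stages = stages,
    n_snps = as.integer(n_snps),
    n_causal = as.integer(n_causal),
    causal_effect_sizes = effects[seq_len(n_causal)],
    stress_severity = stress_severity,
    noise_cv = noise_cv,
    cross_stage_correlation = cross_stage_correlation,
    missing_genotype_rate = missing_genotype_rate,
    missing_marker_rate = missing_marker_rate,
    het_excess_rate = het_excess_rate,
    n_chrom = as.integer(n_chrom),
    trait_baselines = trait_baselines,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default stage/trait layout of the screening design
#' @return Named list with `germination` (8 traits) and `early_seedling`
#'   (16 traits, including ion concentrations and the SES injury score).
#' @export
default_stages <- function() {
  list(
    germination = c("GP", "RL", "SL", "TSL", "FW", "DW", "SVI", "SVII"),
    early_seedling = c("SES", "RL", "SL", "TSL", "RFW", "SFW", "TFW",
                       "RDW", "SDW", "TDW", "RNa", "RK", "RNaK",
                       "SNa", "SK", "SNaK")
  )
}

# arbitrary positive control-condition means; downstream indices are ratios
default_baselines <- function() {
  c(GP = 85, RL = 8, SL = 10, TSL = 18, FW = 0.5, DW = 0.08,
    RFW = 0.4, SFW = 1.2, TFW = 1.6, RDW = 0.05, SDW = 0.18, TDW = 0.23,
    RNa = 5, RK = 2, RNaK = 2.5, SNa = 4, SK = 3, SNaK = 1.3)
}

#' Simulate a biallelic SNP matrix
#'
#' Draws per-marker alt-allele frequencies from Beta(0.5, 0.5) truncated to
#' `[0.05, 0.95]`, genotypes samples under Hardy-Weinberg proportions, then
#' injects heterozygote excess and missing-at-random calls at the configured
#' rates. Positions are strictly increasing within each chromosome. Causal
#' loci are chosen among markers with allele frequency in `[0.2, 0.8]` (so
#' planted effects are detectable at realistic panel sizes) and flagged in the
#' marker map with their effects.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] whose marker map carries `is_causal` and
#'   `effect` columns.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genotypes
  m <- config$n_snps

  freq <- rbeta(m, 0.5, 0.5)
  for (it in 1:50) {
    out_of_range <- freq < 0.05 | freq > 0.95
    if (!any(out_of_range)) break
    freq[out_of_range] <- rbeta(sum(out_of_range), 0.5, 0.5)
  }
  freq <- clamp(freq, 0.05, 0.95)

  chrom <- sort(rep_len(seq_len(config$n_chrom), m))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(1000:50000, length(idx), replace = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  calls <- vapply(seq_len(m), function(j) rbinom(n, 2L, freq[j]),
                  integer(n))
  if (config$het_excess_rate > 0) {
    flip <- matrix(runif(n * m) < config$het_excess_rate, n, m)
    calls[flip] <- 1L
  }
  p_miss <- 1 - (1 - config$missing_marker_rate) *
    (1 - config$missing_genotype_rate)
  if (p_miss > 0) {
    miss <- matrix(runif(n * m) < p_miss, n, m)
    calls[miss] <- NA_integer_
  }
  rownames(calls) <- sprintf("G%03d", seq_len(n))

  is_causal <- rep(FALSE, m)
  effect <- rep(0, m)
  if (config$n_causal > 0) {
    eligible <- which(freq >= 0.2 & freq <= 0.8)
    if (length(eligible) < config$n_causal) eligible <- seq_len(m)
    causal <- sample(eligible, config$n_causal)
    is_causal[causal] <- TRUE
    effect[causal] <- config$causal_effect_sizes
  }

  markers <- tibble::tibble(
    marker_id = sprintf("snp_%04d", seq_len(m)),
    chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
    freq = freq, is_causal = is_causal, effect = effect
  )
  geno_matrix(calls, markers)
}

#' Simulate replicate-level phenotypes from a genotype matrix
#'
#' Builds a latent tolerance score per genotype and stage and derives trait
#' values from it. The stage-1 latent score is the standardized sum of
#' causal-allele dosages plus an independent standard-normal residual; the
#' stage-2 score is `rho * latent1 + sqrt(1 - rho^2) * z` with `z` independent,
#' so the between-stage correlation targets `cross_stage_correlation` exactly
#' (including equality at `rho = 1`). Control replicate values are the trait
#' baseline times lognormal noise with CV `noise_cv`; stress values shrink the
#' control expectation by `stress_severity * (1 - sigmoid(latent))`, so more
#' tolerant genotypes lose less. `SVI`/`SVII` are computed per replicate as
#' `GP * TSL` and `GP * DW`; `SES` is an integer 1-9 injury score emitted under
#' stress only, decreasing in latent tolerance.
#'
#' @param config A [sim_config()].
#' @param genotypes The matching [simulate_genotypes()] output.
#' @return List with `phenotypes` (tibble: `genotype_id`, `stage`, `trait`,
#'   `condition`, `replicate`, `value`) and `latent` (tibble: `genotype_id`,
#'   `stage`, `latent`).
#' @export
simulate_phenotypes <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(config$seed + 1L)
  n <- config$n_genotypes
  ids <- gm_samples(genotypes)
  if (length(ids) != n) abort("Genotype matrix does not match the config.")

  mk <- gm_markers(genotypes)
  causal <- which(mk$is_causal)
  g <- rep(0, n)
  if (length(causal) > 0 && any(mk$effect[causal] != 0)) {
    D <- gm_dosage(genotypes)[, causal, drop = FALSE]
    # mean-impute missing causal calls for the latent signal only
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
    }
    g <- as.numeric(D %*% mk$effect[causal])
    g <- g - mean(g)
  }
  latent1 <- g + rnorm(n)
  latent1 <- as.numeric(scale(latent1))
  rho <- config$cross_stage_correlation
  latent2 <- rho * latent1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)

  stage_latent <- stats::setNames(
    list(latent1, latent2)[seq_along(config$stages)], names(config$stages))
  if (length(config$stages) > 2) {
    for (s in names(config$stages)[-(1:2)]) stage_latent[[s]] <- latent2
  }

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  reps <- config$n_replicates
  rows <- list()
  for (stage in names(config$stages)) {
    lat <- stage_latent[[stage]]
    keep_frac <- 1 - config$stress_severity * (1 - plogis(lat))
    traits <- config$stages[[stage]]
    base_traits <- setdiff(traits, c("SVI", "SVII", "SES"))
    vals <- list()
    for (tr in base_traits) {
      b <- config$trait_baselines[tr]
      if (is.na(b)) b <- 1
      ctrl <- b * exp(rnorm(n * reps, 0, sdlog))
      strs <- b * rep(keep_frac, each = reps) * exp(rnorm(n * reps, 0, sdlog))
      vals[[tr]] <- list(control = ctrl, stress = strs)
    }
    for (vi in intersect(c("SVI", "SVII"), traits)) {
      comp <- if (vi == "SVI") "TSL" else "DW"
      if (!all(c("GP", comp) %in% base_traits)) {
        abort(sprintf("Stage '%s' lists %s but not its components GP and %s.",
                      stage, vi, comp))
      }
      vals[[vi]] <- list(control = vals$GP$control * vals[[comp]]$control,
                         stress = vals$GP$stress * vals[[comp]]$stress)
    }
    for (tr in traits) {
      if (tr == "SES") next
      for (cond in c("control", "stress")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          genotype_id = rep(ids, each = reps), stage = stage, trait = tr,
          condition = cond, replicate = rep(seq_len(reps), times = n),
          value = pmax(vals[[tr]][[cond]], 0)
        )
      }
    }
    if ("SES" %in% traits) {
      ses_raw <- 1 + 8 * config$stress_severity * (1 - plogis(rep(lat, each = reps))) +
        rnorm(n * reps, 0, 0.4)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genotype_id = rep(ids, each = reps), stage = stage, trait = "SES",
        condition = "stress", replicate = rep(seq_len(reps), times = n),
        value = as.numeric(clamp(round(ses_raw), 1, 9))
      )
    }
  }
  phenotypes <- dplyr::bind_rows(rows)
  latent <- tibble::tibble(
    genotype_id = rep(ids, times = length(config$stages)),
    stage = rep(names(config$stages), each = n),
    latent = unlist(stage_latent, use.names = FALSE)
  )
  list(phenotypes = phenotypes, latent = latent)
}

#' Simulate a complete synthetic screening dataset
#'
#' Convenience wrapper calling [simulate_genotypes()] then
#' [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `phenotypes`, `latent` and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  ph <- simulate_phenotypes(config, genotypes)
  list(genotypes = genotypes, phenotypes = ph$phenotypes,
       latent = ph$latent, config = config)
}
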