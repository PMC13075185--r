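#' Build a pipeline run configuration
#'
#' A run either simulates its data (`simulate` = a [sim_config()]) or reads
#' them from files (`phenotype_csv` plus `genotype_vcf` or
#' `genotype_hapmap`, optional `gff3`). Exactly one of the two sources must
#' be present.
#'
#' @param simulate Optional [sim_config()].
#' @param phenotype_csv,genotype_vcf,genotype_hapmap,gff3 Optional input
#'   paths.
#' @param sti_orientation STI orientation (see [compute_sti()]).
#' @param train_fraction Stratified-split training fraction.
#' @param cv_k,alpha_grid Cross-validation folds and mixing-parameter grid.
#' @param qc QC thresholds from [qc_thresholds()].
#' @param association_alpha Family-wise level for the Bonferroni threshold.
#' @param window_kb Candidate-gene window half-width in kb.
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = NULL, phenotype_csv = NULL,
                       genotype_vcf = NULL, genotype_hapmap = NULL,
                       gff3 = NULL,
                       sti_orientation = "stress_over_control",
                       train_fraction = 0.8, cv_k = 10,
                       alpha_grid = seq(0, 1, by = 0.1),
                       qc = qc_thresholds(), association_alpha = 0.05,
                       window_kb = 150, seed = 1L) {
  has_files <- !is.null(phenotype_csv) &&
    (!is.null(genotype_vcf) || !is.null(genotype_hapmap))
  if (is.null(simulate) && !has_files) {
    abort(paste("Config must carry either a `simulate` block or input paths",
                "(phenotype_csv plus genotype_vcf or genotype_hapmap)."))
  }
  if (!is.null(simulate) && has_files) {
    abort("Provide either a `simulate` block or input paths, not both.")
  }
  assert_scalar_number(train_fraction, "train_fraction", 0, 1)
  assert_scalar_number(association_alpha, "association_alpha", 1e-300, 1)
  assert_scalar_number(window_kb, "window_kb", lo = 0)
  structure(list(
    simulate = simulate, phenotype_csv = phenotype_csv,
    genotype_vcf = genotype_vcf, genotype_hapmap = genotype_hapmap,
    gff3 = gff3, sti_orientation = sti_orientation,
    train_fraction = train_fraction, cv_k = cv_k, alpha_grid = alpha_grid,
    qc = qc, association_alpha = association_alpha, window_kb = window_kb,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate` map
#' is passed to [sim_config()] and a `qc` map to [qc_thresholds()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(sim_config, raw$simulate)
  }
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  if (!is.null(raw$alpha_grid)) raw$alpha_grid <- as.numeric(raw$alpha_grid)
  do.call(run_config, raw)
}

# deterministic per-stage seed fan-out from the master seed
stage_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max

#' Run the full stage-wise salinity-tolerance analysis
#'
#' Orchestrates the pipeline end to end: data simulation or loading,
#' vigour-index derivation, per-stage STI, MFV/AMFV scoring and five-class
#' classification, cross-stage transition dynamics, per-stage stratified
#' split, VIF diagnostics and cross-validated elastic-net prediction of
#' AMFV, SNP QC, Bonferroni-controlled association scans of stress-condition
#' trait means, and favourable-allele / combination / candidate-gene mining.
#' Every tabular output is written as TSV (JSON for the model and manifest)
#' under `out_dir`; rerunning with the same config reproduces all outputs
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)
  tsv <- function(x, name) readr::write_tsv(x, out(name))

  # --- data ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    dat <- simulate_dataset(config$simulate)
    genotypes <- dat$genotypes
    phenotypes <- dat$phenotypes
    write_phenotypes(phenotypes, out("phenotypes.csv"))
    write_vcf(genotypes, out("genotypes.vcf"))
    truth <- gm_markers(genotypes) |>
      dplyr::filter(.data$is_causal) |>
      dplyr::select("marker_id", "chrom", "pos", "effect")
    tsv(truth, "truth_causal_loci.tsv")
    tsv(dat$latent, "truth_latent.tsv")
  } else {
    phenotypes <- read_phenotypes(config$phenotype_csv)
    genotypes <- if (!is.null(config$genotype_vcf)) {
      read_vcf(config$genotype_vcf)
    } else {
      read_hapmap(config$genotype_hapmap)
    }
  }

  # --- indices and scores ---------------------------------------------------
  germ_traits <- unique(phenotypes$trait[phenotypes$stage == "germination"])
  if (all(c("GP", "TSL", "DW") %in% germ_traits) &&
      !all(c("SVI", "SVII") %in% germ_traits)) {
    phenotypes <- derive_vigour_indices(phenotypes)
  }
  sti <- compute_sti(phenotypes, orientation = config$sti_orientation)
  tsv(sti, "sti.tsv")
  scores <- score_tolerance(sti)
  tsv(scores, "scores.tsv")
  thresholds <- attr(scores, "thresholds")
  jsonlite::write_json(
    lapply(thresholds, function(th) list(mean = th$mean, sd = th$sd,
                                         cuts = as.list(th$cuts))),
    out("thresholds.json"), auto_unbox = TRUE, digits = NA)

  stages <- unique(scores$stage)
  crossing <- NULL
  if (length(stages) >= 2) {
    s1 <- dplyr::filter(scores, .data$stage == stages[1])
    s2 <- dplyr::filter(scores, .data$stage == stages[2])
    crossing <- cross_stage(s1, s2)
    tsv(crossing$transitions, "transitions.tsv")
    tsv(crossing$summary, "transition_summary.tsv")
  }

  # --- prediction models ----------------------------------------------------
  models <- list()
  for (stg in stages) {
    sti_wide <- sti |>
      dplyr::filter(.data$stage == stg, !.data$flagged) |>
      dplyr::select("genotype_id", "trait", "sti") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "sti") |>
      tidyr::drop_na()
    sc <- dplyr::filter(scores, .data$stage == stg,
                        .data$genotype_id %in% sti_wide$genotype_id)
    split <- stratified_split(sc, config$train_fraction,
                              seed = stage_seed(config$seed, 101L))
    x <- as.matrix(sti_wide[, -1])
    rownames(x) <- sti_wide$genotype_id
    y <- setNames(sc$amfv, sc$genotype_id)[sti_wide$genotype_id]
    vif_tab <- vif(x[split$train, , drop = FALSE])
    cv <- cv_select(x[split$train, , drop = FALSE], y[split$train],
                    alpha_grid = config$alpha_grid, k = config$cv_k,
                    seed = stage_seed(config$seed, 211L))
    report <- prediction_report(cv, x[split$test, , drop = FALSE],
                                y[split$test], ids = split$test)
    metrics <- fit_metrics(report$observed, report$predicted,
                           p = length(cv$model$active))
    models[[stg]] <- list(split = split, vif = vif_tab, cv = cv,
                          report = report, metrics = metrics,
                          equation = format_equation(cv))
    tsv(vif_tab, paste0("vif_", stg, ".tsv"))
    tsv(report, paste0("predictions_", stg, ".tsv"))
    r2_tab <- single_trait_r2_table(
      sti_wide[sti_wide$genotype_id %in% split$train, ],
      dplyr::select(sc, "genotype_id", "amfv"))
    tsv(r2_tab, paste0("single_trait_r2_", stg, ".tsv"))
    models[[stg]]$single_trait_r2 <- r2_tab
    jsonlite::write_json(list(
      stage = stg, alpha = cv$best_alpha, lambda_min = cv$lambda_min,
      lambda_1se = cv$lambda_1se, intercept = cv$model$intercept,
      coefficients = as.list(cv$model$coefficients),
      equation = models[[stg]]$equation, metrics = as.list(metrics)
    ), out(paste0("model_", stg, ".json")), auto_unbox = TRUE, digits = NA)
  }

  # --- genotype QC and association -----------------------------------------
  qc <- apply_qc(genotypes, config$qc)
  tsv(qc$report, "qc_report.tsv")
  gm <- qc$genotypes
  stress_means <- phenotypes |>
    dplyr::filter(.data$condition == "stress",
                  .data$genotype_id %in% gm_samples(gm)) |>
    dplyr::group_by(.data$stage, .data$trait, .data$genotype_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(trait = .data$trait)
  assoc <- scan_traits(gm, stress_means, alpha = config$association_alpha)
  tsv(assoc$scan, "association_scan.tsv")
  tsv(dplyr::select(assoc$mtas, -dplyr::any_of("carriers")), "mtas.tsv")

  # --- allele mining --------------------------------------------------------
  mining <- list()
  if (nrow(assoc$mtas) > 0) {
    fa <- purrr::pmap(assoc$mtas, function(trait, marker_id, ...) {
      vals <- dplyr::filter(stress_means, .data$trait == !!trait)
      favourable_allele(gm, marker_id, vals) |>
        dplyr::mutate(trait = trait, .before = 1)
    }) |> dplyr::bind_rows()
    fa <- dplyr::left_join(
      fa, dplyr::select(assoc$mtas, "trait", "marker_id", "mta_name"),
      by = c("trait", "marker_id"))
    tsv(fa, "favourable_alleles.tsv")
    mining$favourable <- fa

    multi <- assoc$mtas |>
      dplyr::count(.data$trait) |>
      dplyr::filter(.data$n > 1)
    combos <- list()
    for (tr in multi$trait) {
      loci <- assoc$mtas$marker_id[assoc$mtas$trait == tr]
      vals <- dplyr::filter(stress_means, .data$trait == tr)
      combos[[tr]] <- combination_analysis(gm, vals, loci)
    }
    mining$combinations <- combos
    if (length(combos) > 0) {
      combo_tab <- purrr::imap(combos, ~ dplyr::mutate(
        dplyr::select(.x, -"carriers"), trait = .y, .before = 1)) |>
        dplyr::bind_rows()
      tsv(combo_tab, "combinations.tsv")
      sup <- tryCatch(superior_genotypes(combos), error = function(e) NULL)
      if (!is.null(sup)) {
        tsv(sup$membership, "superior_genotypes.tsv")
        mining$superior <- sup
      }
    }
    if (!is.null(config$gff3)) {
      genes <- read_gff_genes(config$gff3)
      hits <- candidate_gene_scan(
        dplyr::select(assoc$mtas, "mta_name", "chrom", "pos"),
        genes, window_kb = config$window_kb)
      tsv(hits, "candidate_genes.tsv")
      mining$genes <- hits
    }
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(packageVersion("ricesalt")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(split = stage_seed(config$seed, 101L),
                       cv = stage_seed(config$seed, 211L)),
    sti_orientation = config$sti_orientation,
    association_threshold = assoc$threshold,
    counts = list(
      genotypes_phenotyped = length(unique(phenotypes$genotype_id)),
      genotypes_classified = length(unique(scores$genotype_id)),
      samples_post_qc = length(gm_samples(gm)),
      markers_post_qc = ncol(gm_dosage(gm)),
      n_mtas = nrow(assoc$mtas)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(phenotypes = phenotypes, genotypes = genotypes, sti = sti,
                 scores = scores, cross_stage = crossing, models = models,
                 qc = qc, association = assoc, mining = mining,
                 manifest = manifest, out_dir = out_dir))
}
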