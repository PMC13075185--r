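#' Derive seedling vigour indices from germination traits
#'
#' Adds the two composite vigour traits per genotype, condition and replicate:
#' seedling vigour index I (`SVI = GP * TSL`) and II (`SVII = GP * DW`).
#' Existing records are untouched; any previously present `SVI`/`SVII` rows
#' for the stage are replaced.
#'
#' @param phenotypes Tibble with columns `genotype_id`, `stage`, `trait`,
#'   `condition`, `replicate`, `value`.
#' @param stage Stage whose records the indices are derived from.
#' @return The input tibble with `SVI` and `SVII` rows appended.
#' @export
derive_vigour_indices <- function(phenotypes, stage = "germination") {
  stage_tab <- dplyr::filter(phenotypes, .data$stage == !!stage)
  need <- c("GP", "TSL", "DW")
  have <- unique(stage_tab$trait)
  if (!all(need %in% have)) {
    abort(sprintf("Stage '%s' is missing required trait(s): %s.", stage,
                  paste(setdiff(need, have), collapse = ", ")))
  }
  wide <- stage_tab |>
    dplyr::filter(.data$trait %in% need) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  derived <- wide |>
    dplyr::mutate(SVI = .data$GP * .data$TSL, SVII = .data$GP * .data$DW) |>
    dplyr::select(-dplyr::all_of(need)) |>
    tidyr::pivot_longer(c("SVI", "SVII"), names_to = "trait",
                        values_to = "value") |>
    dplyr::select(dplyr::all_of(names(phenotypes)))
  phenotypes |>
    dplyr::filter(!(.data$stage == !!stage & .data$trait %in% c("SVI", "SVII"))) |>
    dplyr::bind_rows(derived)
}

#' Tissue ion concentration from a flame-photometer reading
#'
#' Converts a reading in mg/L to mmol per g dry weight:
#' `reading * digest_volume / (dry_weight * molar_mass)`.
#'
#' @param reading_mg_per_l Reading in mg/L (vectorized).
#' @param digest_volume_l Final digest volume in litres (default 0.01 L).
#' @param dry_weight_g Sample dry weight in g; must be positive.
#' @param molar_mass_g_per_mol Molar mass (23 for Na, 39.1 for K); positive.
#' @return Concentration in mmol per g dry weight.
#' @export
ion_concentration <- function(reading_mg_per_l, digest_volume_l = 0.01,
                              dry_weight_g, molar_mass_g_per_mol) {
  if (any(dry_weight_g <= 0)) abort("`dry_weight_g` must be positive.")
  if (any(molar_mass_g_per_mol <= 0)) {
    abort("`molar_mass_g_per_mol` must be positive.")
  }
  reading_mg_per_l * digest_volume_l / (dry_weight_g * molar_mass_g_per_mol)
}

#' Per-trait stress tolerance index
#'
#' STI compares a genotype's performance under salinity with its non-stressed
#' performance, one value per genotype, stage and trait, computed from the
#' per-condition replicate means. The default orientation is
#' `stress_over_control`, under which STI > 1 means stressed performance above
#' the non-stressed mean and higher STI means stronger tolerance; the inverse
#' ratio is available via `orientation = "control_over_stress"`. The visual
#' injury score `SES` (recorded under stress only, 1 = symptom-free) has no
#' control reading; its index is the convention `1 / mean(SES)`, which equals
#' 1 for symptom-free genotypes.
#'
#' Records whose denominator mean is zero or missing are returned with
#' `sti = NA` and `flagged = TRUE`, with a warning; drop them before scaling.
#'
#' @param phenotypes Replicate-level tibble (`genotype_id`, `stage`, `trait`,
#'   `condition`, `replicate`, `value`).
#' @param orientation `"stress_over_control"` (default) or
#'   `"control_over_stress"`.
#' @return Tibble: `genotype_id`, `stage`, `trait`, `control_mean`,
#'   `stress_mean`, `sti`, `flagged`.
#' @export
compute_sti <- function(phenotypes,
                        orientation = c("stress_over_control",
                                        "control_over_stress")) {
  orientation <- match.arg(orientation)
  means <- phenotypes |>
    dplyr::group_by(.data$genotype_id, .data$stage, .data$trait,
                    .data$condition) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  if (!"control" %in% names(means)) means$control <- NA_real_
  if (!"stress" %in% names(means)) means$stress <- NA_real_
  out <- means |>
    dplyr::mutate(
      sti = dplyr::case_when(
        .data$trait == "SES" & !is.na(.data$stress) & .data$stress > 0 ~
          1 / .data$stress,
        orientation == "stress_over_control" & !is.na(.data$control) &
          .data$control > 0 ~ .data$stress / .data$control,
        orientation == "control_over_stress" & !is.na(.data$stress) &
          .data$stress > 0 & .data$trait != "SES" ~
          .data$control / .data$stress,
        TRUE ~ NA_real_
      ),
      flagged = !is.finite(.data$sti)
    ) |>
    dplyr::rename(control_mean = "control", stress_mean = "stress") |>
    dplyr::select("genotype_id", "stage", "trait", "control_mean",
                  "stress_mean", "sti", "flagged")
  if (any(out$flagged)) {
    warn(sprintf(
      "%d genotype/trait record(s) had an undefined STI (zero or missing denominator) and were flagged.",
      sum(out$flagged)))
  }
  out
}

#' Replicate-level stress tolerance indices
#'
#' One STI value per stress replicate (stress replicate value divided by the
#' genotype's control mean; `SES` replicates are inverted), suitable for the
#' replicate-based check comparisons of [compare_to_checks()].
#'
#' @inheritParams compute_sti
#' @return Tibble: `genotype_id`, `stage`, `trait`, `replicate`, `sti`.
#' @export
sti_replicates <- function(phenotypes,
                           orientation = c("stress_over_control",
                                           "control_over_stress")) {
  orientation <- match.arg(orientation)
  ctrl <- phenotypes |>
    dplyr::filter(.data$condition == "control") |>
    dplyr::group_by(.data$genotype_id, .data$stage, .data$trait) |>
    dplyr::summarise(control_mean = mean(.data$value), .groups = "drop")
  phenotypes |>
    dplyr::filter(.data$condition == "stress") |>
    dplyr::left_join(ctrl, by = c("genotype_id", "stage", "trait")) |>
    dplyr::mutate(sti = dplyr::case_when(
      .data$trait == "SES" & .data$value > 0 ~ 1 / .data$value,
      orientation == "stress_over_control" & .data$control_mean > 0 ~
        .data$value / .data$control_mean,
      orientation == "control_over_stress" & .data$value > 0 &
        .data$trait != "SES" ~ .data$control_mean / .data$value,
      TRUE ~ NA_real_
    )) |>
    dplyr::select("genotype_id", "stage", "trait", "replicate", "sti")
}

# one-sided Welch two-sample t-test; returns p-value (NA if untestable)
welch_p <- function(x, y, direction) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else NA_real_)
  }
  alt <- if (direction == "higher") "greater" else "less"
  stats::t.test(x, y, alternative = alt)$p.value
}

#' Compare genotype STI replicates against a check genotype
#'
#' For each genotype and trait, a one-sided Welch two-sample t-test of its
#' replicate STI values against the check's, in the stated direction
#' (`"higher"`: genotype exceeds the check, as used against a tolerant check;
#' `"lower"` against a susceptible check). Genotype/trait pairs with fewer
#' than two replicates on either side are untestable and reported as not
#' significant.
#'
#' @param sti_reps Replicate-level STI tibble from [sti_replicates()].
#' @param check_id Genotype id of the check; must be present in `sti_reps`.
#' @param direction `"higher"` or `"lower"`.
#' @param alpha Significance level (default 0.05); significance is `p < alpha`.
#' @return List with `tests` (per genotype x stage x trait: `p_value`,
#'   `significant`, `testable`) and `summary` (per genotype x stage: count of
#'   significant traits).
#' @export
compare_to_checks <- function(sti_reps, check_id,
                              direction = c("higher", "lower"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (!check_id %in% sti_reps$genotype_id) {
    abort(sprintf("Check genotype '%s' not found.", check_id))
  }
  check <- sti_reps |>
    dplyr::filter(.data$genotype_id == check_id) |>
    dplyr::group_by(.data$stage, .data$trait) |>
    dplyr::summarise(check_reps = list(.data$sti), .groups = "drop")
  tests <- sti_reps |>
    dplyr::filter(.data$genotype_id != check_id) |>
    dplyr::group_by(.data$genotype_id, .data$stage, .data$trait) |>
    dplyr::summarise(reps = list(.data$sti), .groups = "drop") |>
    dplyr::inner_join(check, by = c("stage", "trait")) |>
    dplyr::mutate(
      p_value = purrr::map2_dbl(.data$reps, .data$check_reps,
                                ~ welch_p(.x, .y, direction)),
      testable = !is.na(.data$p_value),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) |>
    dplyr::select(-"reps", -"check_reps")
  summary <- tests |>
    dplyr::group_by(.data$genotype_id, .data$stage) |>
    dplyr::summarise(n_significant = sum(.data$significant),
                     n_traits = dplyr::n(), .groups = "drop")
  list(tests = tests, summary = summary)
}
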