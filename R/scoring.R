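#' Membership-function values from STIs
#'
#' Per-trait min-max scaling of STI across genotypes within a stage:
#' `MFV = (X - Xmin) / (Xmax - Xmin)`, so the best genotype for a trait gets
#' 1 and the worst gets 0. Flagged or missing STI records are dropped with a
#' warning before scaling. A trait whose STI values are all equal within a
#' stage has no defined scaling and raises an error naming it.
#'
#' @param sti STI tibble from [compute_sti()] (columns `genotype_id`, `stage`,
#'   `trait`, `sti`; a `flagged` column is honoured if present).
#' @return Tibble: `genotype_id`, `stage`, `trait`, `mfv` in `[0, 1]`.
#' @export
compute_mfv <- function(sti) {
  if ("flagged" %in% names(sti) && any(sti$flagged, na.rm = TRUE)) {
    warn(sprintf("Dropping %d flagged STI record(s) before scaling.",
                 sum(sti$flagged, na.rm = TRUE)))
    sti <- dplyr::filter(sti, !.data$flagged)
  }
  sti <- dplyr::filter(sti, is.finite(.data$sti))
  counts <- dplyr::count(sti, .data$stage, .data$trait)
  if (any(counts$n < 2)) {
    abort("Each stage/trait needs STI values for at least 2 genotypes.")
  }
  out <- sti |>
    dplyr::group_by(.data$stage, .data$trait) |>
    dplyr::mutate(.min = min(.data$sti), .max = max(.data$sti)) |>
    dplyr::ungroup()
  degenerate <- out |>
    dplyr::filter(.data$.max == .data$.min) |>
    dplyr::distinct(.data$stage, .data$trait)
  if (nrow(degenerate) > 0) {
    abort(paste0("No MFV scaling for constant trait(s): ",
                 paste(degenerate$trait, " (", degenerate$stage, ")",
                       sep = "", collapse = ", ")))
  }
  out |>
    dplyr::mutate(mfv = clamp((.data$sti - .data$.min) /
                                (.data$.max - .data$.min), 0, 1)) |>
    dplyr::select("genotype_id", "stage", "trait", "mfv")
}

#' Average membership-function value per genotype
#'
#' Unweighted arithmetic mean of a genotype's trait MFVs within each stage,
#' the single multi-trait tolerance score. Every genotype must have an MFV
#' for every trait of its stage; gaps raise an error listing them.
#'
#' @param mfv Tibble from [compute_mfv()].
#' @return Tibble: `genotype_id`, `stage`, `amfv`.
#' @export
compute_amfv <- function(mfv) {
  full <- mfv |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(.n_traits = dplyr::n_distinct(.data$trait)) |>
    dplyr::group_by(.data$genotype_id, .data$stage) |>
    dplyr::summarise(amfv = mean(.data$mfv), n = dplyr::n(),
                     expected = .data$.n_traits[1], .groups = "drop")
  gaps <- dplyr::filter(full, .data$n != .data$expected)
  if (nrow(gaps) > 0) {
    abort(paste0("Missing trait MFVs for: ",
                 paste(gaps$genotype_id, " (", gaps$stage, ")",
                       sep = "", collapse = ", ")))
  }
  dplyr::select(full, "genotype_id", "stage", "amfv")
}

#' Classification thresholds from an AMFV sample
#'
#' Cut points at the sample mean plus/minus 1 and 1.64 standard deviations
#' (sample SD, n-1 denominator), computed at full precision.
#'
#' @param amfv Numeric vector of AMFV values.
#' @return Object of class `tol_thresholds`: `mean`, `sd` and the four cut
#'   points.
#' @export
classification_thresholds <- function(amfv) {
  amfv <- amfv[is.finite(amfv)]
  if (length(amfv) < 2) abort("Need at least 2 AMFV values.")
  m <- mean(amfv); s <- sd(amfv)
  if (s <= 0) abort("AMFV standard deviation must be positive.")
  structure(list(
    mean = m, sd = s,
    cuts = c(lower_164 = m - 1.64 * s, lower_1 = m - s,
             upper_1 = m + s, upper_164 = m + 1.64 * s)
  ), class = "tol_thresholds")
}

#' @export
print.tol_thresholds <- function(x, ...) {
  cat(sprintf("<tol_thresholds> mean = %.4f, sd = %.4f\n", x$mean, x$sd))
  cat(sprintf("  HS < %.4f <= S < %.4f <= MT < %.4f <= T < %.4f <= HT\n",
              x$cuts[1], x$cuts[2], x$cuts[3], x$cuts[4]))
  invisible(x)
}

#' Assign five-class tolerance labels
#'
#' `HT` if `AMFV >= mean + 1.64 SD`; `T` down to `mean + 1 SD`; `MT` down to
#' `mean - 1 SD`; `S` down to `mean - 1.64 SD`; `HS` below that. Lower bounds
#' are inclusive.
#'
#' @param amfv Numeric vector.
#' @param thresholds A [classification_thresholds()] object.
#' @return Ordered factor with levels `HS < S < MT < T < HT`.
#' @export
classify_tolerance <- function(amfv, thresholds) {
  stopifnot(inherits(thresholds, "tol_thresholds"))
  cuts <- thresholds$cuts
  cls <- dplyr::case_when(
    amfv >= cuts[["upper_164"]] ~ "HT",
    amfv >= cuts[["upper_1"]] ~ "T",
    amfv >= cuts[["lower_1"]] ~ "MT",
    amfv >= cuts[["lower_164"]] ~ "S",
    TRUE ~ "HS"
  )
  tolerance_factor(cls)
}

#' Score and classify a panel from its STI table
#'
#' Chains [compute_mfv()], [compute_amfv()] and per-stage classification with
#' thresholds estimated from that stage's AMFV distribution.
#'
#' @param sti STI tibble from [compute_sti()].
#' @return Tibble `genotype_id`, `stage`, `amfv`, `class`, with the per-stage
#'   [classification_thresholds()] objects in the `thresholds` attribute.
#' @export
score_tolerance <- function(sti) {
  amfv <- compute_amfv(compute_mfv(sti))
  thresholds <- lapply(split(amfv$amfv, amfv$stage), classification_thresholds)
  out <- amfv |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(class = classify_tolerance(
      .data$amfv, thresholds[[.data$stage[1]]])) |>
    dplyr::ungroup()
  attr(out, "thresholds") <- thresholds
  out
}

#' Cross-stage tolerance-class dynamics
#'
#' Pairs each genotype's class at two stages and labels the transition as
#' `improved`, `declined` or `stable` under the ordinal order
#' `HS < S < MT < T < HT`. Both inputs must cover the same genotype set.
#'
#' @param scores_stage1,scores_stage2 Tibbles with `genotype_id` and `class`
#'   (e.g. per-stage slices of [score_tolerance()] output).
#' @return List with `transitions` (per genotype), `summary` (counts and
#'   percentages per direction, percentages to 1 decimal) and `alluvial`
#'   (long-format genotype x stage x class table for flow plots).
#' @export
cross_stage <- function(scores_stage1, scores_stage2) {
  only1 <- setdiff(scores_stage1$genotype_id, scores_stage2$genotype_id)
  only2 <- setdiff(scores_stage2$genotype_id, scores_stage1$genotype_id)
  if (length(only1) + length(only2) > 0) {
    abort(paste0("Genotypes present at only one stage: ",
                 paste(c(only1, only2), collapse = ", ")))
  }
  transitions <- dplyr::inner_join(
    dplyr::select(scores_stage1, "genotype_id", class_stage1 = "class"),
    dplyr::select(scores_stage2, "genotype_id", class_stage2 = "class"),
    by = "genotype_id") |>
    dplyr::mutate(
      class_stage1 = tolerance_factor(.data$class_stage1),
      class_stage2 = tolerance_factor(.data$class_stage2),
      direction = dplyr::case_when(
        as.integer(.data$class_stage2) > as.integer(.data$class_stage1) ~ "improved",
        as.integer(.data$class_stage2) < as.integer(.data$class_stage1) ~ "declined",
        TRUE ~ "stable"
      )
    )
  summary <- transition_summary(transitions)
  alluvial <- transitions |>
    tidyr::pivot_longer(c("class_stage1", "class_stage2"),
                        names_to = "stage", values_to = "class") |>
    dplyr::mutate(stage = sub("class_", "", .data$stage))
  list(transitions = transitions, summary = summary, alluvial = alluvial)
}

#' Summarise transition directions
#'
#' Counts and percentages (to 1 decimal) of improved / declined / stable
#' transitions.
#'
#' @param transitions Tibble with a `direction` column, as produced by
#'   [cross_stage()].
#' @return Tibble: `direction`, `n`, `pct`.
#' @export
transition_summary <- function(transitions) {
  total <- nrow(transitions)
  tibble::tibble(direction = c("improved", "declined", "stable")) |>
    dplyr::left_join(dplyr::count(transitions, .data$direction),
                     by = "direction") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round(100 * .data$n / total, 1))
}
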