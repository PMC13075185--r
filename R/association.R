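#' Single-marker association scan
#'
#' Per-marker ordinary least squares of the trait on alt-allele dosage
#' (0/1/2) over non-missing samples: a simple additive fixed-effect scan with
#' two-sided p-values from the slope t-statistic and PVE (phenotypic variance
#' explained) as 100 times the model R-squared. This is a transparent
#' stand-in for multi-locus mixed/iterative GWAS models; it fits no kinship
#' or structure covariates by default, though a covariate matrix can be
#' supplied and is residualized out of both trait and dosage beforehand.
#' Monomorphic markers, or markers with fewer than 3 informative samples,
#' yield `NA` statistics and are excluded from significance testing.
#'
#' @param gm A [geno_matrix()].
#' @param trait_values Named numeric vector (names = sample ids) or tibble
#'   with `genotype_id` and `value`.
#' @param covariates Optional numeric matrix of per-sample covariates.
#' @return Tibble: `marker_id`, `chrom`, `pos`, `ref`, `alt`, `n`, `effect`
#'   (trait units per alt-allele copy), `se`, `p_value`, `pve` (percent).
#' @export
association_scan <- function(gm, trait_values, covariates = NULL) {
  if (is.data.frame(trait_values)) {
    trait_values <- setNames(trait_values$value, trait_values$genotype_id)
  }
  ids <- gm_samples(gm)
  if (!all(ids %in% names(trait_values))) {
    abort("Every sample needs a trait value (matched by name).")
  }
  y <- as.numeric(trait_values[ids])
  d <- gm_dosage(gm)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    q <- qr(cbind(1, covariates))
    y <- qr.resid(q, y)
    d_res <- apply(d, 2, function(col) {
      out <- rep(NA_real_, length(col))
      ok <- !is.na(col)
      out[ok] <- qr.resid(qr(cbind(1, covariates[ok, , drop = FALSE])),
                          col[ok])
      out
    })
    d <- d_res
  }
  mk <- gm_markers(gm)
  m <- ncol(d)
  res <- if (!anyNA(d) && !anyNA(y)) {
    scan_complete(d, y)
  } else {
    scan_with_missing(d, y)
  }
  tibble::tibble(
    marker_id = mk$marker_id, chrom = mk$chrom, pos = mk$pos,
    ref = mk$ref, alt = mk$alt,
    n = unname(res$n), effect = unname(res$effect), se = unname(res$se),
    p_value = unname(res$p), pve = unname(res$pve)
  )
}

# fully vectorized path when no calls are missing
scan_complete <- function(d, y) {
  n <- length(y)
  dm <- colMeans(d)
  sxx <- colSums(d^2) - n * dm^2
  yc <- y - mean(y)
  sxy <- as.numeric(crossprod(d, yc))
  syy <- sum(yc^2)
  ok <- sxx > 0 & syy > 0 & n >= 3
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  sse <- syy - ifelse(ok, sxy^2 / sxx, 0)
  se <- ifelse(ok, sqrt(pmax(sse, 0) / (n - 2) / sxx), NA_real_)
  tval <- slope / se
  p <- ifelse(ok & se > 0, 2 * pt(abs(tval), n - 2, lower.tail = FALSE),
              ifelse(ok, 0, NA_real_))
  r2 <- ifelse(ok, sxy^2 / (sxx * syy), NA_real_)
  list(n = rep(n, ncol(d)), effect = slope, se = se, p = p, pve = 100 * r2)
}

scan_with_missing <- function(d, y) {
  m <- ncol(d)
  out <- list(n = integer(m), effect = rep(NA_real_, m),
              se = rep(NA_real_, m), p = rep(NA_real_, m),
              pve = rep(NA_real_, m))
  for (j in seq_len(m)) {
    ok <- !is.na(d[, j]) & !is.na(y)
    x <- d[ok, j]; yy <- y[ok]
    out$n[j] <- length(x)
    if (length(x) < 3 || sd(x) == 0 || sd(yy) == 0) next
    one <- scan_complete(matrix(x, ncol = 1), yy)
    out$effect[j] <- one$effect; out$se[j] <- one$se
    out$p[j] <- one$p; out$pve[j] <- one$pve
  }
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @param m Number of markers tested (`>= 1`).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  assert_scalar_number(alpha, "alpha", 1e-300, 1 - 1e-12)
  assert_scalar_number(m, "m", lo = 1)
  alpha / m
}

#' Name significant marker-trait associations
#'
#' Within each trait and chromosome, significant markers are ordered by
#' position and numbered from 1 in the format `q<TRAIT><chrom>.<index>`
#' (e.g. `qGP12.1`).
#'
#' @param sig Tibble of significant hits with `trait`, `chrom`, `pos` and
#'   `marker_id`.
#' @return Input with an `mta_name` column, ordered by trait, chromosome and
#'   position.
#' @export
name_mtas <- function(sig) {
  sig |>
    dplyr::arrange(.data$trait, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$trait, .data$chrom) |>
    dplyr::mutate(mta_name = sprintf("q%s%s.%d", .data$trait, .data$chrom,
                                     dplyr::row_number())) |>
    dplyr::ungroup()
}

#' Scan one or more traits and collect significant MTAs
#'
#' Runs [association_scan()] per trait, applies the Bonferroni threshold over
#' the number of markers tested, and names the significant hits.
#'
#' @param gm A [geno_matrix()].
#' @param trait_table Tibble with `genotype_id`, `trait`, `value` (one value
#'   per genotype and trait, e.g. stress-condition replicate means).
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return List with `scan` (all per-marker results, with `trait` column),
#'   `mtas` (significant named hits) and `threshold`.
#' @export
scan_traits <- function(gm, trait_table, alpha = 0.05) {
  threshold <- bonferroni_threshold(alpha, ncol(gm_dosage(gm)))
  scans <- trait_table |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_map(function(df, key) {
      association_scan(gm, setNames(df$value, df$genotype_id)) |>
        dplyr::mutate(trait = key$trait, .before = 1)
    }) |>
    dplyr::bind_rows()
  sig <- scans |>
    dplyr::filter(!is.na(.data$p_value) & .data$p_value < threshold)
  mtas <- if (nrow(sig) > 0) name_mtas(sig) else
    dplyr::mutate(sig, mta_name = character(0))
  list(scan = scans, mtas = mtas, threshold = threshold)
}
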