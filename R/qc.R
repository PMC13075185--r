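#' Per-marker genotype statistics
#'
#' Missing fraction over samples, minor allele frequency among non-missing
#' calls (`p = (2 hom-alt + het) / (2 called)`, `MAF = min(p, 1 - p)`), and
#' heterozygosity fraction among non-missing calls. A marker with zero
#' non-missing calls gets `NA` statistics (it falls to the missingness
#' filter).
#'
#' @param gm A [geno_matrix()].
#' @return Tibble: `marker_id`, `n_called`, `missing_frac`, `maf`,
#'   `het_frac`.
#' @export
marker_stats <- function(gm) {
  d <- gm_dosage(gm)
  if (length(d) == 0) abort("Empty genotype matrix.")
  n <- nrow(d)
  called <- colSums(!is.na(d))
  alt_count <- colSums(d, na.rm = TRUE)
  het <- colSums(d == 1L, na.rm = TRUE)
  p <- ifelse(called > 0, alt_count / (2 * called), NA_real_)
  tibble::tibble(
    marker_id = colnames(d),
    n_called = unname(called),
    missing_frac = unname(1 - called / n),
    maf = unname(pmin(p, 1 - p)),
    het_frac = unname(ifelse(called > 0, het / called, NA_real_))
  )
}

#' Per-sample missingness
#'
#' @param gm A [geno_matrix()].
#' @return Tibble: `sample_id`, `missing_frac`.
#' @export
sample_stats <- function(gm) {
  d <- gm_dosage(gm)
  tibble::tibble(sample_id = rownames(d),
                 missing_frac = rowMeans(is.na(d)))
}

#' QC thresholds for a SNP matrix
#'
#' The screening defaults remove samples with more than 20% missing calls,
#' markers with more than 10% missing calls, minor allele frequency below 5%,
#' or heterozygosity above 50%. Thresholds quoted with strict inequalities
#' are honoured strictly: a marker exactly at a threshold is retained.
#'
#' @param sample_missing,marker_missing,maf,het Thresholds in `[0, 1]`.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(sample_missing = 0.20, marker_missing = 0.10,
                          maf = 0.05, het = 0.50) {
  th <- list(sample_missing = sample_missing, marker_missing = marker_missing,
             maf = maf, het = het)
  for (nm in names(th)) assert_scalar_number(th[[nm]], nm, 0, 1)
  th
}

#' Apply quality-control filters to a SNP matrix
#'
#' One filter cycle runs, in order: (1) samples with missing fraction above
#' `sample_missing`; marker statistics are then recomputed on the surviving
#' samples; (2) markers with missing fraction above `marker_missing`;
#' (3) markers with MAF strictly below `maf` (a marker with undefined MAF at
#' this point has already been removed by the missingness filter);
#' (4) markers with heterozygosity above `het`. All comparisons are strict,
#' so exactly-at-threshold entries are retained (and exactly-at-`maf`
#' markers are retained because removal requires `maf <` threshold).
#'
#' Because marker removal changes per-sample missingness, the cycle repeats
#' until a full pass removes nothing, so the returned matrix is a fixed
#' point of its own filters (applying `apply_qc` to the output changes
#' nothing). On clean data the first cycle already converges; the report
#' records every cycle.
#'
#' @param gm A [geno_matrix()].
#' @param thresholds A [qc_thresholds()] list.
#' @return List of class `qc_result` with `genotypes` (filtered
#'   [geno_matrix()]) and `report` (one row per filter step and cycle:
#'   kind, threshold, removed and retained counts).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  report <- list()
  log_step <- function(cycle, step, kind, threshold, removed, retained) {
    tibble::tibble(cycle = cycle, step = step, filter = kind,
                   threshold = threshold, removed = removed,
                   retained = retained)
  }

  for (cycle in 1:100) {
    removed_this_cycle <- 0L

    ss <- sample_stats(gm)
    drop_samples <- ss$sample_id[ss$missing_frac > thresholds$sample_missing]
    keep_samples <- setdiff(ss$sample_id, drop_samples)
    report[[length(report) + 1L]] <- log_step(
      cycle, 1L, "sample_missing", thresholds$sample_missing,
      length(drop_samples), length(keep_samples))
    if (length(keep_samples) == 0) {
      abort("All samples removed by QC.", report = dplyr::bind_rows(report))
    }
    removed_this_cycle <- removed_this_cycle + length(drop_samples)
    gm <- gm_subset(gm, samples = keep_samples)

    ms <- marker_stats(gm)
    keep <- ms$missing_frac <= thresholds$marker_missing & ms$n_called > 0
    report[[length(report) + 1L]] <- log_step(
      cycle, 2L, "marker_missing", thresholds$marker_missing,
      sum(!keep), sum(keep))
    removed_this_cycle <- removed_this_cycle + sum(!keep)
    ms <- ms[keep, ]
    gm <- gm_subset(gm, markers = ms$marker_id)

    keep <- !is.na(ms$maf) & ms$maf >= thresholds$maf
    report[[length(report) + 1L]] <- log_step(
      cycle, 3L, "maf", thresholds$maf, sum(!keep), sum(keep))
    removed_this_cycle <- removed_this_cycle + sum(!keep)
    ms <- ms[keep, ]
    gm <- gm_subset(gm, markers = ms$marker_id)

    keep <- ms$het_frac <= thresholds$het
    report[[length(report) + 1L]] <- log_step(
      cycle, 4L, "het", thresholds$het, sum(!keep), sum(keep))
    removed_this_cycle <- removed_this_cycle + sum(!keep)
    ms <- ms[keep, ]
    if (nrow(ms) == 0) {
      abort("All markers removed by QC.", report = dplyr::bind_rows(report))
    }
    gm <- gm_subset(gm, markers = ms$marker_id)

    if (removed_this_cycle == 0L) break
  }

  structure(list(genotypes = gm, report = dplyr::bind_rows(report),
                 thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  print(x$genotypes)
  invisible(x)
}
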