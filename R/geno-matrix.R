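#' Biallelic SNP genotype matrix
#'
#' A `geno_matrix` bundles a samples-by-markers matrix of alt-allele dosages
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing) with a marker map. Dosage coding keeps the matrix numeric
#' for association scans; the ref/alt letters in the map recover the actual
#' alleles where they matter (favourable-allele and combination mining).
#'
#' @param calls Integer matrix, samples in rows, markers in columns, entries
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names marker ids.
#' @param markers Data frame with one row per matrix column: `marker_id`,
#'   `chrom`, `pos` (1-based bp), `ref`, `alt` single-nucleotide alleles.
#'   Extra columns (e.g. simulation truth) are carried along.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- tibble::as_tibble(markers)
  required <- c("marker_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0("`markers` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (ncol(calls) != nrow(markers)) {
    abort("`calls` must have one column per marker row.")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  }
  colnames(calls) <- markers$marker_id
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0) abort("`calls` entries must be 0, 1, 2 or NA.")
  if (any(markers$pos <= 0)) abort("Marker positions must be positive.")
  if (any(nchar(markers$ref) != 1L | nchar(markers$alt) != 1L)) {
    abort("Only single-nucleotide ref/alt alleles are supported.")
  }
  ord <- order(markers$chrom, markers$pos)
  dup <- duplicated(markers$marker_id)
  if (any(dup)) abort("Duplicate marker ids.")
  structure(list(calls = calls, markers = markers[, , drop = FALSE]),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  n_missing <- sum(is.na(x$calls))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$markers$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", n_missing,
              100 * n_missing / length(x$calls)))
  invisible(x)
}

#' Sample identifiers of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Character vector of sample ids.
#' @export
gm_samples <- function(gm) rownames(gm$calls)

#' Marker map of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Tibble with one row per marker.
#' @export
gm_markers <- function(gm) gm$markers

#' Alt-allele dosage matrix
#' @param gm A [geno_matrix()].
#' @return Integer matrix (samples x markers) with entries 0/1/2/NA.
#' @export
gm_dosage <- function(gm) gm$calls

#' Subset a genotype matrix
#' @param gm A [geno_matrix()].
#' @param samples,markers Character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return A [geno_matrix()].
#' @export
gm_subset <- function(gm, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(gm$calls)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(gm$calls)) else markers
  if (is.character(mi)) mi <- match(mi, gm$markers$marker_id)
  geno_matrix(gm$calls[si, mi, drop = FALSE], gm$markers[mi, , drop = FALSE])
}

# allele letters for the homozygous calls of one marker; hets and missing -> NA
gm_hom_allele <- function(gm, marker_id) {
  j <- match(marker_id, gm$markers$marker_id)
  if (is.na(j)) abort(sprintf("Unknown marker id '%s'.", marker_id))
  d <- gm$calls[, j]
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d == 0L] <- gm$markers$ref[j]
  out[!is.na(d) & d == 2L] <- gm$markers$alt[j]
  names(out) <- rownames(gm$calls)
  out
}

#' Long-format view of genotype calls
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `marker_id`, `dosage`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$calls), times = ncol(x$calls)),
    marker_id = rep(colnames(x$calls), each = nrow(x$calls)),
    dosage = as.integer(x$calls)
  )
}
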