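# small builders shared across test files

# replicate-level phenotype rows from a named list:
# pheno_rows("G1", "germination", GP = list(control = c(...), stress = c(...)))
pheno_rows <- function(genotype_id, stage, ...) {
  traits <- list(...)
  purrr::imap(traits, function(conds, trait) {
    purrr::imap(conds, function(vals, cond) {
      tibble::tibble(genotype_id = genotype_id, stage = stage, trait = trait,
                     condition = cond, replicate = seq_along(vals),
                     value = vals)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

# toy geno_matrix from a dosage matrix (samples x markers)
toy_gm <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("G", seq_len(nrow(calls)))
  geno_matrix(calls, tibble::tibble(
    marker_id = colnames(calls) %||% paste0("M", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq(1000, by = 1000, length.out = m),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("T", m)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-entry QC oracle, deliberately loop-based; repeats the
# sample-then-marker filter cycle until nothing more is removed
brute_qc <- function(calls, sample_missing = 0.20, marker_missing = 0.10,
                     maf = 0.05, het = 0.50) {
  marker_names <- colnames(calls)
  repeat {
    n_before <- nrow(calls) + ncol(calls)
    keep_s <- c()
    for (i in seq_len(nrow(calls))) {
      if (mean(is.na(calls[i, ])) <= sample_missing) keep_s <- c(keep_s, i)
    }
    calls <- calls[keep_s, , drop = FALSE]
    keep_m <- c()
    for (j in seq_len(ncol(calls))) {
      col <- calls[, j]
      miss <- mean(is.na(col))
      if (miss > marker_missing) next
      obs <- col[!is.na(col)]
      if (length(obs) == 0) next
      p <- sum(obs) / (2 * length(obs))
      if (min(p, 1 - p) < maf) next
      if (mean(obs == 1) > het) next
      keep_m <- c(keep_m, j)
    }
    calls <- calls[, keep_m, drop = FALSE]
    if (nrow(calls) + ncol(calls) == n_before) break
    if (nrow(calls) == 0 || ncol(calls) == 0) break
  }
  list(samples = rownames(calls), markers = match(colnames(calls),
                                                 marker_names))
}

# brute-force all-pairs interval scan oracle
brute_gene_scan <- function(mtas, genes, window_kb = 150) {
  w <- window_kb * 1000
  out <- list()
  for (i in seq_len(nrow(mtas))) {
    for (g in seq_len(nrow(genes))) {
      if (mtas$chrom[i] != genes$chrom[g]) next
      if (genes$end[g] < mtas$pos[i] - w || genes$start[g] > mtas$pos[i] + w) next
      inside <- mtas$pos[i] >= genes$start[g] && mtas$pos[i] <= genes$end[g]
      d <- if (inside) 0 else
        min(abs(mtas$pos[i] - genes$start[g]), abs(mtas$pos[i] - genes$end[g])) / 1000
      out[[length(out) + 1]] <- tibble::tibble(
        mta_name = mtas$mta_name[i], gene_id = genes$gene_id[g],
        distance_kb = d, within_gene = inside)
    }
  }
  dplyr::bind_rows(out)
}
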