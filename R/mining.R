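#' Favourable allele at a marker
#'
#' Compares mean trait performance between the two homozygote classes of a
#' marker (heterozygotes are excluded). Under `higher_is_better` the
#' favourable allele (FA) is the one whose homozygous carriers show the
#' higher mean; the allelic advantage is `100 * (FA mean - AA mean) / AA
#' mean` where AA is the alternate (non-favourable) allele. Under
#' `lower_is_better` the FA is the lower-mean allele and the advantage is
#' `100 * (AA mean - FA mean) / AA mean`, so the advantage is non-negative in
#' both directions. A tie is broken alphabetically with a warning. If either
#' homozygote class has no carriers the record is flagged and FA left
#' undefined.
#'
#' @param gm A [geno_matrix()].
#' @param marker_id Marker to evaluate.
#' @param trait_values Named numeric vector (sample ids) or tibble with
#'   `genotype_id`, `value`.
#' @param direction `"higher_is_better"` (default) or `"lower_is_better"`.
#' @return One-row tibble: `marker_id`, per-allele means and counts,
#'   `favourable_allele`, `alternate_allele`, `advantage_pct`, `flagged`.
#' @export
favourable_allele <- function(gm, marker_id, trait_values,
                              direction = c("higher_is_better",
                                            "lower_is_better")) {
  direction <- match.arg(direction)
  if (is.data.frame(trait_values)) {
    trait_values <- setNames(trait_values$value, trait_values$genotype_id)
  }
  alleles <- gm_hom_allele(gm, marker_id)
  j <- match(marker_id, gm_markers(gm)$marker_id)
  ref <- gm_markers(gm)$ref[j]; alt <- gm_markers(gm)$alt[j]
  y <- trait_values[names(alleles)]
  ok <- !is.na(alleles) & !is.na(y)
  ref_mean <- if (any(ok & alleles == ref)) mean(y[ok & alleles == ref]) else NA_real_
  alt_mean <- if (any(ok & alleles == alt)) mean(y[ok & alleles == alt]) else NA_real_
  n_ref <- sum(ok & alleles == ref); n_alt <- sum(ok & alleles == alt)
  flagged <- is.na(ref_mean) || is.na(alt_mean)
  fa <- aa <- NA_character_; adv <- NA_real_
  if (!flagged) {
    means <- setNames(c(ref_mean, alt_mean), c(ref, alt))
    if (means[1] == means[2]) {
      warn(sprintf("Tie at marker %s; favourable allele assigned alphabetically.",
                   marker_id))
      fa <- sort(names(means))[1]
    } else if (direction == "higher_is_better") {
      fa <- names(means)[which.max(means)]
    } else {
      fa <- names(means)[which.min(means)]
    }
    aa <- setdiff(names(means), fa)
    if (direction == "higher_is_better") {
      adv <- 100 * (means[[fa]] - means[[aa]]) / means[[aa]]
    } else {
      adv <- 100 * (means[[aa]] - means[[fa]]) / means[[aa]]
    }
  }
  tibble::tibble(
    marker_id = marker_id, ref = ref, alt = alt,
    ref_mean = ref_mean, alt_mean = alt_mean,
    n_ref_hom = n_ref, n_alt_hom = n_alt,
    favourable_allele = fa, alternate_allele = aa,
    fa_mean = if (flagged) NA_real_ else
      ifelse(fa == ref, ref_mean, alt_mean),
    aa_mean = if (flagged) NA_real_ else
      ifelse(fa == ref, alt_mean, ref_mean),
    advantage_pct = as.numeric(adv), flagged = flagged
  )
}

#' Allelic advantage from two class means
#'
#' `100 * (fa_mean - aa_mean) / aa_mean`: the favourable-allele mean's
#' relative advantage over the alternate-allele mean, in percent.
#'
#' @param fa_mean,aa_mean Homozygote-class means.
#' @return Percentage (vectorized).
#' @export
allelic_advantage <- function(fa_mean, aa_mean) {
  100 * (fa_mean - aa_mean) / aa_mean
}

#' Homozygous multilocus allelic combinations
#'
#' Groups genotypes that are homozygous at every listed locus by their allele
#' string (one letter per locus, in the given locus order), and ranks the
#' groups by mean trait value. Genotypes heterozygous or missing at any
#' listed locus are excluded from every group.
#'
#' @param gm A [geno_matrix()].
#' @param trait_values Named numeric vector or tibble (`genotype_id`,
#'   `value`).
#' @param loci Ordered character vector of at least two marker ids.
#' @return Tibble ranked by decreasing mean: `combination`, `n`, `mean_value`,
#'   `carriers` (list column of genotype ids), `rank`. Empty (with a warning)
#'   if no genotype is homozygous at all loci.
#' @export
combination_analysis <- function(gm, trait_values, loci) {
  if (length(loci) < 2) abort("Need at least 2 loci.")
  if (is.data.frame(trait_values)) {
    trait_values <- setNames(trait_values$value, trait_values$genotype_id)
  }
  letters_mat <- vapply(loci, function(l) gm_hom_allele(gm, l),
                        character(nrow(gm_dosage(gm))))
  full <- rowSums(is.na(letters_mat)) == 0
  y <- trait_values[gm_samples(gm)]
  full <- full & !is.na(y)
  if (!any(full)) {
    warn("No genotype is homozygous at all listed loci.")
    return(tibble::tibble(combination = character(0), n = integer(0),
                          mean_value = numeric(0), carriers = list(),
                          rank = integer(0)))
  }
  combo <- unname(apply(letters_mat[full, , drop = FALSE], 1, paste,
                        collapse = ""))
  ids <- gm_samples(gm)[full]
  tibble::tibble(combination = combo, genotype_id = ids,
                 value = as.numeric(y[full])) |>
    dplyr::group_by(.data$combination) |>
    dplyr::summarise(n = dplyr::n(), mean_value = mean(.data$value),
                     carriers = list(.data$genotype_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_value)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Candidate-gene window scan around significant SNPs
#'
#' For each MTA, reports every gene whose interval intersects the window
#' `[pos - W, pos + W]` (W in bp from `window_kb`). Distance is 0 kb if the
#' SNP lies inside the gene (`within_gene = TRUE`), otherwise the distance
#' from the SNP to the nearest gene boundary in kb. The nearest gene per MTA
#' is flagged. Chromosome names must match between SNPs and annotation (use
#' the `chrom_map` of [read_gff_genes()] to reconcile naming).
#'
#' @param mtas Tibble with `mta_name`, `chrom`, `pos`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_gff_genes()].
#' @param window_kb Window half-width in kb (default 150).
#' @return Tibble: `mta_name`, `gene_id`, `chrom`, `start`, `end`,
#'   `distance_kb`, `within_gene`, `nearest`.
#' @export
candidate_gene_scan <- function(mtas, genes, window_kb = 150) {
  unmatched <- setdiff(unique(mtas$chrom), unique(genes$chrom))
  if (length(unmatched) > 0) {
    abort(paste0("SNP chromosome(s) absent from annotation: ",
                 paste(unmatched, collapse = ", ")))
  }
  w <- round(window_kb * 1000)
  snp_gr <- GenomicRanges::GRanges(
    mtas$chrom, IRanges::IRanges(pmax(mtas$pos - w, 1), mtas$pos + w))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    return(tibble::tibble(mta_name = character(0), gene_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), distance_kb = numeric(0),
                          within_gene = logical(0), nearest = logical(0)))
  }
  pos <- mtas$pos[qi]
  start <- genes$start[si]; end <- genes$end[si]
  inside <- pos >= start & pos <= end
  dist_kb <- ifelse(inside, 0,
                    pmin(abs(pos - start), abs(pos - end)) / 1000)
  tibble::tibble(
    mta_name = mtas$mta_name[qi], gene_id = genes$gene_id[si],
    chrom = genes$chrom[si], start = start, end = end,
    distance_kb = dist_kb, within_gene = inside
  ) |>
    dplyr::group_by(.data$mta_name) |>
    dplyr::mutate(nearest = dplyr::row_number(.data$distance_kb) == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$mta_name, .data$distance_kb)
}

#' Genotypes carrying the best allelic combination across traits
#'
#' Takes per-trait [combination_analysis()] results, finds the top-ranked
#' (highest-mean) combination of each trait, and tabulates which genotypes
#' carry it. Only genotypes carrying at least one best combination appear in
#' the output, which is shaped for UpSet-style intersection plots.
#'
#' @param combinations Named list: trait -> [combination_analysis()] result.
#' @return List with `membership` (tibble: `genotype_id`, one logical column
#'   per trait, `n_traits`) and `best` (tibble: `trait`, `combination`,
#'   `mean_value`).
#' @export
superior_genotypes <- function(combinations) {
  combinations <- combinations[vapply(combinations, nrow, 1L) > 0]
  if (length(combinations) == 0) abort("No non-empty combination results.")
  best <- purrr::imap(combinations, function(res, trait) {
    top <- res[res$rank == 1L, ]
    tibble::tibble(trait = trait, combination = top$combination,
                   mean_value = top$mean_value,
                   carriers = top$carriers)
  }) |> dplyr::bind_rows()
  long <- best |>
    dplyr::select("trait", "carriers") |>
    tidyr::unnest("carriers") |>
    dplyr::rename(genotype_id = "carriers") |>
    dplyr::mutate(carries = TRUE)
  membership <- long |>
    tidyr::pivot_wider(names_from = "trait", values_from = "carries",
                       values_fill = FALSE)
  membership$n_traits <- rowSums(membership[, -1, drop = FALSE])
  list(membership = dplyr::arrange(membership,
                                   dplyr::desc(.data$n_traits)),
       best = dplyr::select(best, -"carriers"))
}
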