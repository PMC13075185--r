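#' Read / write replicate-level phenotype tables
#'
#' CSV with columns `genotype_id`, `stage`, `trait`, `condition`,
#' `replicate`, `value`.
#'
#' @param path File path.
#' @return [read_phenotypes()] returns the phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           genotype_id = readr::col_character(),
                           stage = readr::col_character(),
                           trait = readr::col_character(),
                           condition = readr::col_character(),
                           replicate = readr::col_integer(),
                           value = readr::col_double()))
  bad <- setdiff(unique(tab$condition), c("control", "stress"))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition value(s): ", paste(bad, collapse = ", ")))
  }
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' Read a biallelic SNP matrix from VCF
#'
#' Keeps biallelic SNP records only; multi-allelic or indel records are
#' skipped with a message giving the count. Genotypes are taken from the GT
#' field (`/` or `|` separators); anything other than 0 and 1 alleles is
#' treated as missing.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(sprintf("Skipped %d non-biallelic-SNP record(s).", n_skip))
  }
  if (!any(keep)) abort("No biallelic SNP records in VCF.")
  gt <- vcfR::extract.gt(v[keep, ])
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  core <- gsub("\\|", "/", gt)
  dosage[core %in% c("0/0")] <- 0L
  dosage[core %in% c("0/1", "1/0")] <- 1L
  dosage[core %in% c("1/1")] <- 2L
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  markers <- tibble::tibble(
    marker_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)
  geno_matrix(t(dosage), markers)
}

#' Write a genotype matrix as plain-text VCF
#'
#' Minimal VCFv4.2 with a GT-only FORMAT field; missing calls become `./.`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(gm, path) {
  mk <- gm_markers(gm)
  d <- t(gm_dosage(gm))  # markers x samples
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ricesalt",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm_samples(gm)), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$marker_id, mk$ref, mk$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# IUPAC single-letter heterozygote codes
iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a HapMap-format genotype table
#'
#' Tab-separated HapMap dialect: 11 metadata columns (`rs#`, `alleles`,
#' `chrom`, `pos`, ...) followed by one column per sample. Diploid calls may
#' be two allele letters (`AG`), a single IUPAC ambiguity letter for
#' heterozygotes (`R`), or a doubled homozygote letter (`AA`); `NN`, `--` and
#' `N` are missing.
#'
#' @param path File path.
#' @return A [geno_matrix()].
#' @export
read_hapmap <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  meta_n <- 11L
  if (ncol(tab) <= meta_n) abort("HapMap file has no sample columns.")
  alleles <- stringr::str_split_fixed(tab[[2]], "/", 2)
  ref <- alleles[, 1]; alt <- alleles[, 2]
  samples <- names(tab)[-(1:meta_n)]
  m <- nrow(tab)
  dosage <- matrix(NA_integer_, length(samples), m,
                   dimnames = list(samples, tab[[1]]))
  for (i in seq_len(m)) {
    calls <- toupper(unlist(tab[i, -(1:meta_n)], use.names = FALSE))
    expanded <- ifelse(nchar(calls) == 1 & calls %in% names(iupac_het),
                       iupac_het[calls],
                       ifelse(nchar(calls) == 1, strrep(calls, 2), calls))
    a1 <- substr(expanded, 1, 1); a2 <- substr(expanded, 2, 2)
    ok <- a1 %in% c(ref[i], alt[i]) & a2 %in% c(ref[i], alt[i])
    dosage[ok, i] <- (a1[ok] == alt[i]) + (a2[ok] == alt[i])
  }
  markers <- tibble::tibble(
    marker_id = tab[[1]], chrom = as.character(tab[[3]]),
    pos = as.integer(tab[[4]]), ref = ref, alt = alt)
  geno_matrix(dosage, markers)
}

#' Write a genotype matrix in HapMap format
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @export
write_hapmap <- function(gm, path) {
  mk <- gm_markers(gm)
  d <- gm_dosage(gm)  # samples x markers
  calls <- matrix("NN", ncol(d), nrow(d))  # markers x samples
  for (j in seq_len(ncol(d))) {
    col <- d[, j]
    calls[j, !is.na(col) & col == 0L] <- strrep(mk$ref[j], 2)
    calls[j, !is.na(col) & col == 1L] <- paste0(mk$ref[j], mk$alt[j])
    calls[j, !is.na(col) & col == 2L] <- strrep(mk$alt[j], 2)
  }
  meta <- data.frame(
    `rs#` = mk$marker_id, alleles = paste0(mk$ref, "/", mk$alt),
    chrom = mk$chrom, pos = mk$pos, strand = "+", `assembly#` = NA,
    center = NA, protLSID = NA, assayLSID = NA, panelLSID = NA,
    QCcode = NA, check.names = FALSE)
  body <- cbind(meta, as.data.frame(calls, col.names = rownames(d)))
  names(body)[-(1:11)] <- rownames(d)
  readr::write_tsv(body, path, na = "NA")
  invisible(path)
}

#' Read gene intervals from a GFF3 annotation
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @param chrom_map Optional named character vector renaming annotation
#'   chromosomes to the SNP naming (e.g. `c(Chr1 = "1")`).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand` (1-based
#'   inclusive coordinates).
#' @export
read_gff_genes <- function(path, feature = "gene", chrom_map = NULL) {
  g <- rtracklayer::import(path)
  g <- g[as.character(g$type) == feature]
  if (length(g) == 0) abort(sprintf("No '%s' features in %s.", feature, path))
  ids <- g$ID %||% rep(NA_character_, length(g))
  if ("Name" %in% names(S4Vectors::mcols(g))) {
    ids <- ifelse(is.na(ids), g$Name, ids)
  }
  ids[is.na(ids)] <- paste0("gene_", seq_len(length(g)))[is.na(ids)]
  chrom <- as.character(GenomicRanges::seqnames(g))
  if (!is.null(chrom_map)) {
    mapped <- chrom_map[chrom]
    chrom <- ifelse(is.na(mapped), chrom, mapped)
  }
  tibble::tibble(
    gene_id = ids, chrom = chrom,
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)))
}
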