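test_that("marker statistics follow the allele-counting definitions", {
  # all heterozygous
  gm <- toy_gm(matrix(1L, 4, 1, dimnames = list(NULL, "M1")))
  ms <- marker_stats(gm)
  expect_equal(ms$maf, 0.5)
  expect_equal(ms$het_frac, 1)

  # monomorphic reference
  gm2 <- toy_gm(matrix(0L, 4, 1, dimnames = list(NULL, "M1")))
  expect_equal(marker_stats(gm2)$maf, 0)

  # hand count: 6 homRef, 2 het, 2 homAlt -> p = (4 + 2) / 20 = 0.3
  gm3 <- toy_gm(matrix(c(rep(0L, 6), rep(1L, 2), rep(2L, 2)), 10, 1,
                       dimnames = list(NULL, "M1")))
  ms3 <- marker_stats(gm3)
  expect_equal(ms3$maf, 0.3)
  expect_equal(ms3$het_frac, 0.2)
  expect_equal(ms3$missing_frac, 0)
})

test_that("a clean matrix passes QC untouched with an all-zero report", {
  set.seed(30)
  calls <- matrix(sample(0:2, 60, replace = TRUE, prob = c(0.4, 0.3, 0.3)),
                  10, 6, dimnames = list(NULL, paste0("M", 1:6)))
  gm <- toy_gm(calls)
  res <- apply_qc(gm)
  expect_equal(res$report$removed, rep(0L, 4))
  expect_identical(gm_dosage(res$genotypes), gm_dosage(gm))
})

test_that("QC removes the hand-identified sample and marker from a toy fixture", {
  # 5 samples x 6 markers; S5 is 50% missing; M6 monomorphic (MAF 0 < 0.05)
  calls <- rbind(
    c(0L, 1L, 2L, 0L, 1L, 0L),
    c(1L, 0L, 2L, 1L, 0L, 0L),
    c(2L, 1L, 0L, 0L, 2L, 0L),
    c(0L, 2L, 1L, 1L, 1L, 0L),
    c(NA, NA, NA, 0L, 2L, 0L))
  rownames(calls) <- paste0("S", 1:5)
  colnames(calls) <- paste0("M", 1:6)
  res <- apply_qc(toy_gm(calls))
  expect_setequal(gm_samples(res$genotypes), paste0("S", 1:4))
  expect_setequal(gm_markers(res$genotypes)$marker_id, paste0("M", 1:5))
  first <- dplyr::filter(res$report, cycle == 1)
  expect_equal(first$removed, c(1L, 0L, 1L, 0L))
  # the final cycle confirms the fixed point
  last <- dplyr::filter(res$report, cycle == max(cycle))
  expect_equal(last$removed, rep(0L, 4))
})

test_that("exactly-at-threshold markers are retained", {
  # MAF exactly 0.05: 10 samples, 1 alt allele in 20 -> p = 0.05
  calls <- cbind(M1 = c(1L, rep(0L, 9)),
                 M2 = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L))
  gm <- toy_gm(calls)
  expect_equal(marker_stats(gm)$maf[1], 0.05)
  res <- apply_qc(gm)
  expect_true("M1" %in% gm_markers(res$genotypes)$marker_id)

  # marker missingness exactly 10%: retained
  calls2 <- cbind(M1 = c(NA, rep(c(0L, 1L, 2L), 3)),
                  M2 = rep(c(0L, 1L, 2L), length.out = 10))
  res2 <- apply_qc(toy_gm(calls2))
  expect_true("M1" %in% gm_markers(res2$genotypes)$marker_id)
})

test_that("QC is idempotent and conserves counts at every step", {
  set.seed(31)
  calls <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE,
                         prob = c(0.35, 0.25, 0.3, 0.1)), 20, 50,
                  dimnames = list(NULL, sprintf("M%02d", 1:50)))
  gm <- toy_gm(calls)
  r1 <- apply_qc(gm)
  r2 <- apply_qc(r1$genotypes)
  expect_identical(gm_dosage(r2$genotypes), gm_dosage(r1$genotypes))
  expect_equal(r2$report$removed, rep(0L, 4))
  # conservation: removed + retained equals the previous step's retained
  rep1 <- dplyr::filter(r1$report, cycle == 1)
  expect_equal(rep1$removed[1] + rep1$retained[1], 20)
  expect_equal(rep1$removed[2] + rep1$retained[2], 50)
  for (i in 3:4) {
    expect_equal(rep1$removed[i] + rep1$retained[i], rep1$retained[i - 1])
  }
})

test_that("QC agrees with a brute-force per-entry oracle", {
  set.seed(32)
  for (i in 1:20) {
    calls <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE,
                           prob = c(0.3, 0.25, 0.3, 0.15)), 20, 50,
                    dimnames = list(paste0("S", 1:20), sprintf("M%02d", 1:50)))
    gm <- toy_gm(calls)
    ours <- tryCatch(apply_qc(gm), error = function(e) NULL)
    oracle <- brute_qc(calls)
    if (is.null(ours)) {
      expect_true(length(oracle$markers) == 0 || length(oracle$samples) == 0)
    } else {
      expect_setequal(gm_samples(ours$genotypes), oracle$samples)
      expect_setequal(gm_markers(ours$genotypes)$marker_id,
                      colnames(calls)[oracle$markers])
    }
  }
})

test_that("HapMap reader accepts two-letter and IUPAC heterozygote codes", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    "S1", "S2", "S3", "S4"), collapse = "\t")
  rows <- c(paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6),
                    "AA", "AG", "R", "GG"), collapse = "\t"),
            paste(c("m2", "C/T", "2", "200", "+", rep("NA", 6),
                    "CC", "Y", "NN", "TT"), collapse = "\t"))
  writeLines(c(header, rows), path)
  gm <- read_hapmap(path)
  expect_equal(unname(gm_dosage(gm)[, 1]), c(0L, 1L, 1L, 2L))
  expect_equal(unname(gm_dosage(gm)[, 2]), c(0L, 1L, NA, 2L))
  expect_equal(gm_markers(gm)$ref, c("A", "C"))
})

test_that("VCF writer emits plain text that rereads bit-identically", {
  dat <- simulate_dataset(sim_config(n_genotypes = 12, n_snps = 15, seed = 33))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(dat$genotypes, path)
  lines <- readLines(path)
  expect_match(lines[1], "fileformat=VCFv4.2")
  back <- read_vcf(path)
  expect_identical(unname(gm_dosage(back)),
                   unname(gm_dosage(dat$genotypes)))
  expect_equal(gm_markers(back)$pos, gm_markers(dat$genotypes)$pos)
  # writing the reread matrix reproduces the same file
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  expect_identical(readLines(path2), lines)
})
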