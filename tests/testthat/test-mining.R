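test_that("favourable allele is the better homozygote class mean", {
  # 4 TT carriers at 83.63, 4 AA carriers at 67.17, 2 hets ignored
  calls <- matrix(c(rep(2L, 4), rep(0L, 4), 1L, 1L), 10, 1,
                  dimnames = list(paste0("G", 1:10), "M1"))
  gm <- toy_gm(calls, ref = "A", alt = "T")
  y <- setNames(c(rep(83.63, 4), rep(67.17, 4), 5, 5), rownames(calls))
  fa <- favourable_allele(gm, "M1", y)
  expect_equal(fa$favourable_allele, "T")
  expect_equal(fa$alternate_allele, "A")
  expect_equal(fa$fa_mean, 83.63)
  expect_equal(fa$n_alt_hom, 4L)
  expect_equal(fa$advantage_pct, 100 * (83.63 - 67.17) / 67.17)
  expect_false(fa$flagged)

  # direction flip picks the lower mean (e.g. sodium accumulation)
  fa_low <- favourable_allele(gm, "M1", y, direction = "lower_is_better")
  expect_equal(fa_low$favourable_allele, "A")
  expect_equal(fa_low$advantage_pct, 100 * (83.63 - 67.17) / 83.63)

  # tie broken alphabetically with a warning
  y_tie <- setNames(rep(1, 10), rownames(calls))
  expect_warning(fa_tie <- favourable_allele(gm, "M1", y_tie), "Tie")
  expect_equal(fa_tie$favourable_allele, "A")

  # empty homozygote class flags the record
  calls2 <- matrix(c(rep(2L, 5), rep(1L, 5)), 10, 1,
                   dimnames = list(paste0("G", 1:10), "M1"))
  fa2 <- favourable_allele(toy_gm(calls2, ref = "A", alt = "T"), "M1", y)
  expect_true(fa2$flagged)
  expect_true(is.na(fa2$favourable_allele))
})

test_that("allelic advantage is antisymmetric under mean exchange", {
  set.seed(50)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    adv <- allelic_advantage(a, b)
    expect_equal(allelic_advantage(b, a), -100 * adv / (100 + adv),
                 tolerance = 1e-10)
  }
})

test_that("combination analysis groups fully homozygous genotypes", {
  # 6 genotypes x 2 loci; G5 is het at locus 1, G6 missing at locus 2
  calls <- rbind(G1 = c(2L, 2L), G2 = c(2L, 2L), G3 = c(0L, 2L),
                 G4 = c(0L, 0L), G5 = c(1L, 2L), G6 = c(2L, NA))
  colnames(calls) <- c("M1", "M2")
  gm <- toy_gm(calls, ref = c("C", "G"), alt = c("T", "A"))
  y <- setNames(c(1.2, 1.0, 0.8, 0.4, 9, 9), rownames(calls))
  res <- combination_analysis(gm, y, c("M1", "M2"))
  expect_equal(res$combination, c("TA", "CA", "CG"))
  expect_equal(res$n, c(2L, 1L, 1L))
  expect_equal(res$mean_value, c(1.1, 0.8, 0.4))
  expect_equal(res$rank, 1:3)
  expect_setequal(res$carriers[[1]], c("G1", "G2"))
  # hets and missing excluded from every group
  expect_false(any(c("G5", "G6") %in% unlist(res$carriers)))
  expect_equal(sum(res$n), 4L)
  expect_error(combination_analysis(gm, y, "M1"), "2 loci")
  all_het <- toy_gm(matrix(1L, 3, 2, dimnames = list(NULL, c("M1", "M2"))))
  expect_warning(empty <- combination_analysis(
    all_het, setNames(1:3, paste0("G", 1:3)), c("M1", "M2")), "homozygous")
  expect_equal(nrow(empty), 0)
})

test_that("candidate-gene windows report distances and the nearest gene", {
  mtas <- tibble::tibble(mta_name = "qSNaK2.1", chrom = "2", pos = 839096L)
  genes <- tibble::tibble(
    gene_id = c("inwin_353bp", "inwin_5kb", "inwin_149kb", "outside_160kb",
                "otherchrom"),
    chrom = c("2", "2", "2", "2", "3"),
    start = c(839449L, 844096L, 988096L, 999996L, 839000L),
    end = c(840000L, 845000L, 989000L, 1000500L, 840000L))
  hits <- candidate_gene_scan(mtas, genes, window_kb = 150)
  expect_setequal(hits$gene_id, c("inwin_353bp", "inwin_5kb", "inwin_149kb"))
  expect_equal(hits$distance_kb[hits$gene_id == "inwin_353bp"], 0.353)
  expect_true(hits$nearest[hits$gene_id == "inwin_353bp"])
  expect_false(any(hits$nearest[hits$gene_id != "inwin_353bp"]))

  # a SNP inside a gene is at distance zero
  inside <- candidate_gene_scan(
    tibble::tibble(mta_name = "qX1.1", chrom = "2", pos = 839500L),
    genes, window_kb = 150)
  g1 <- inside[inside$gene_id == "inwin_353bp", ]
  expect_true(g1$within_gene)
  expect_equal(g1$distance_kb, 0)

  expect_error(candidate_gene_scan(
    tibble::tibble(mta_name = "qY5.1", chrom = "5", pos = 1L), genes),
    "absent")
})

test_that("window scan agrees with a brute-force interval oracle", {
  set.seed(51)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:2000),
    chrom = sample(as.character(1:3), 2000, replace = TRUE),
    start = sample.int(5e6, 2000))
  genes$end <- genes$start + sample.int(20000, 2000)
  mtas <- tibble::tibble(mta_name = paste0("qT", 1:25, ".1"),
                         chrom = sample(as.character(1:3), 25, replace = TRUE),
                         pos = sample.int(5e6, 25))
  ours <- candidate_gene_scan(mtas, genes, window_kb = 150)
  oracle <- brute_gene_scan(mtas, genes, window_kb = 150)
  key <- function(d) paste(d$mta_name, d$gene_id)
  expect_setequal(key(ours), key(oracle))
  merged <- dplyr::inner_join(ours, oracle, by = c("mta_name", "gene_id"))
  expect_equal(merged$distance_kb.x, merged$distance_kb.y, tolerance = 1e-12)
  expect_equal(merged$within_gene.x, merged$within_gene.y)
})

test_that("GFF3 genes feed the window scan", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "2\ttest\tgene\t839449\t840000\t.\t+\t.\tID=LOC_A;Name=LOC_A",
    "2\ttest\tmRNA\t839449\t840000\t.\t+\t.\tID=LOC_A.1;Parent=LOC_A",
    "2\ttest\tgene\t999996\t1000500\t.\t-\t.\tID=LOC_B"), path)
  genes <- read_gff_genes(path)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$gene_id, c("LOC_A", "LOC_B"))
  hits <- candidate_gene_scan(
    tibble::tibble(mta_name = "qZ2.1", chrom = "2", pos = 839096L),
    genes, window_kb = 150)
  expect_equal(hits$gene_id, "LOC_A")
  expect_equal(hits$distance_kb, 0.353)
})

test_that("superior genotypes collect carriers of each trait's best combination", {
  combos <- list(
    GP = tibble::tibble(combination = c("TT", "AA"), n = c(2L, 1L),
                        mean_value = c(2, 1),
                        carriers = list(c("G1", "G2"), "G3"), rank = 1:2),
    RL = tibble::tibble(combination = c("CC", "GG"), n = c(1L, 2L),
                        mean_value = c(5, 4),
                        carriers = list("G1", c("G2", "G4")), rank = 1:2),
    FW = tibble::tibble(combination = "AT", n = 1L, mean_value = 3,
                        carriers = list("G1"), rank = 1L))
  sup <- superior_genotypes(combos)
  mem <- sup$membership
  expect_equal(mem$genotype_id[mem$n_traits == 3], "G1")
  expect_equal(mem$n_traits[mem$genotype_id == "G2"], 1)
  # G3 and G4 carry no best combination and are absent
  expect_false(any(c("G3", "G4") %in% mem$genotype_id))
  expect_equal(sup$best$combination, c("TT", "CC", "AT"))
})
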