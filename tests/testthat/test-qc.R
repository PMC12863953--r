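test_that("contemporary-group labels are deterministic concatenations", {
  rec <- data.frame(animal = sprintf("a%02d", 1:80),
                    year = rep(c(2020, 2021), each = 40),
                    sex = rep(rep(c("M", "F"), each = 20), 2),
                    farm = rep(rep(c("1", "2"), each = 10), 4),
                    stringsAsFactors = FALSE)
  cg <- build_contemporary_groups(rec, c("year", "sex", "farm"))
  # 3 factors x 2 levels fully crossed and balanced: 8 CGs of 10
  expect_equal(length(unique(cg$cg)), 8L)
  expect_true(all(table(cg$cg) == 10))
  # identical factor combinations share a label
  expect_equal(cg$cg[1], cg$cg[2])

  one <- build_contemporary_groups(
    data.frame(animal = c("x", "y"), lvl = c("A", "B")), "lvl")
  expect_equal(length(unique(one$cg)), 2L)

  rec$year[3] <- NA
  expect_message(cg2 <- build_contemporary_groups(rec, c("year", "sex", "farm")),
                 "excluded")
  expect_equal(attr(cg2, "excluded"), "a03")
})

test_that("CG size and variability filters follow the stated thresholds", {
  # 9 in small, 50 all-zero, 10 in ok1 (mixed), 12 in ok2 (mixed)
  phen <- data.frame(
    animal = sprintf("a%02d", 1:81),
    cg = c(rep("small", 9), rep("allzero", 50), rep("ok1", 10), rep("ok2", 12)),
    y = c(rep(1, 9), rep(0, 50), rep(c(0, 1), 5), rep(c(1, 0), 6)),
    stringsAsFactors = FALSE)
  out <- filter_cgs(phen, min_size = 10)
  kept <- unique(out$phenotypes$cg)
  expect_setequal(kept, c("ok1", "ok2"))
  expect_equal(out$report$cg_removed_size, 1L)
  expect_equal(out$report$cg_removed_novar, 1L)
  # conservation: removed + kept = input
  expect_equal(out$report$n_records_out + out$report$records_removed,
               out$report$n_records_in)
  # all-pass input is a no-op
  clean <- filter_cgs(out$phenotypes, min_size = 10)
  expect_equal(clean$phenotypes, out$phenotypes)
  expect_error(filter_cgs(phen[phen$cg == "small", ], min_size = 10),
               "no analyzable data")
})

test_that("connectedness keeps chains of sire-linked CGs and drops islands", {
  # sires s1..s4; CG1-CG2 share s2, CG2-CG3 share s3; CG4 is an island
  ped <- as_pedigree(data.frame(
    animal = c(paste0("s", 1:4), paste0("k", 1:40)),
    sire = c(rep("0", 4), rep(c("s1", "s2"), 5), rep(c("s2", "s3"), 5),
             rep("s3", 10), rep("s4", 10)),
    dam = rep("0", 44), stringsAsFactors = FALSE))
  phen <- data.frame(animal = paste0("k", 1:40),
                     cg = rep(c("CG1", "CG2", "CG3", "CG4"), each = 10),
                     y = rep(c(0, 1), 20), stringsAsFactors = FALSE)
  out <- check_connectedness(phen, ped)
  expect_setequal(unique(out$phenotypes$cg), c("CG1", "CG2", "CG3"))
  expect_equal(out$report$cg_removed_disconnected, 1L)

  # single shared sire everywhere: nothing removed
  ped1 <- as_pedigree(data.frame(animal = c("s", paste0("k", 1:20)),
                                 sire = c("0", rep("s", 20)),
                                 dam = rep("0", 21), stringsAsFactors = FALSE))
  phen1 <- data.frame(animal = paste0("k", 1:20),
                      cg = rep(c("A", "B"), each = 10),
                      y = rep(c(0, 1), 10), stringsAsFactors = FALSE)
  out1 <- check_connectedness(phen1, ped1)
  expect_equal(nrow(out1$phenotypes), 20L)
  expect_equal(out1$report$cg_removed_disconnected, 0L)
})

test_that("genotype QC applies HWE, call-rate and MAF marker filters", {
  set.seed(42)
  n <- 1000
  good <- matrix(rbinom(3 * n, 2, 0.4), n, 3)
  mono <- rep(0L, n)                       # MAF 0
  halfmiss <- c(rbinom(n / 2, 2, 0.4), rep(NA, n / 2))  # call rate 0.5
  allhet <- rep(1L, n)                     # p = 0.5, chi-square = n
  M <- cbind(good, mono, halfmiss, allhet)
  colnames(M) <- c("g1", "g2", "g3", "mono", "miss", "het")
  rownames(M) <- sprintf("a%04d", 1:n)
  out <- genotype_qc(M)
  expect_setequal(colnames(out$genotypes), c("g1", "g2", "g3"))
  expect_equal(out$report$snps_removed_maf, 1L)
  expect_equal(out$report$snps_removed_callrate, 1L)
  expect_equal(out$report$snps_removed_hwe, 1L)
  expect_equal(out$report$n_snps_in,
               out$report$n_snps_out + out$report$snps_removed_maf +
                 out$report$snps_removed_callrate + out$report$snps_removed_hwe)
  # idempotence
  again <- genotype_qc(out$genotypes)
  expect_identical(again$genotypes, out$genotypes)
  expect_error(genotype_qc(matrix(0L, 10, 2)), "every SNP")
  expect_error(genotype_qc(matrix(3L, 2, 2)), "0/1/2")
})

test_that("all-heterozygote HWE chi-square equals the sample size", {
  # closed form: p = 0.5, expected (n/4, n/2, n/4), observed (0, n, 0),
  # so chi-square = n and the p-value vanishes for n = 1000
  expect_lt(defectEval:::.hwe_pvalue(rep(1L, 1000)), 1e-15)
  expect_equal(defectEval:::.hwe_pvalue(rep(0L, 50)), 1)
})
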