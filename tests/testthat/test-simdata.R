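test_that("sim_config rejects out-of-range parameters", {
  expect_error(sim_config(n_founders = 5), "even")
  expect_error(sim_config(h2_liability = 1), "h2_liability")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(prop_genotyped = 1.2), "prop_genotyped")
})

test_that("simulated pedigree has discrete generations with parents one back", {
  ped <- simulate_pedigree(sim_config(n_founders = 4, n_generations = 0, seed = 1))
  expect_equal(nrow(ped), 4L)
  expect_true(all(ped$sire == "0" & ped$dam == "0"))

  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    offspring_per_mating = 2, seed = 3)
  ped <- simulate_pedigree(cfg)
  # 5 pairs x 2 offspring keeps each generation at 10 animals
  expect_equal(nrow(ped), 10L + 3L * 10L)
  gen <- ped$generation
  non_founders <- which(ped$sire != "0")
  for (i in non_founders) {
    expect_equal(gen[match(ped$sire[i], ped$animal)], gen[i] - 1L)
    expect_equal(gen[match(ped$dam[i], ped$animal)], gen[i] - 1L)
    expect_false(ped$sire[i] == ped$dam[i])
  }
  # determinism
  expect_identical(ped, simulate_pedigree(cfg))
})

test_that("gene dropping obeys fixation and Mendelian constraints", {
  ped <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 2, seed = 2))
  M <- simulate_genotypes(ped, n_snps = 3, seed = 5, founder_freqs = 1.0)
  expect_true(all(M == 2L))

  M0 <- simulate_genotypes(ped, n_snps = 3, seed = 5, founder_freqs = 0)
  expect_true(all(M0 == 0L))

  # no opposing homozygotes in any trio, any locus
  M <- simulate_genotypes(ped, n_snps = 100, seed = 9)
  for (i in which(ped$sire_idx > 0)) {
    for (p in c(ped$sire_idx[i], ped$dam_idx[i])) {
      # offspring cannot be the opposite homozygote of a parent
      expect_false(any(M[p, ] == 0 & M[i, ] == 2))
      expect_false(any(M[p, ] == 2 & M[i, ] == 0))
    }
  }

  # realized founder frequency within 3 binomial SDs of the target
  ped_f <- simulate_pedigree(sim_config(n_founders = 200, n_generations = 0, seed = 4))
  Mf <- simulate_genotypes(ped_f, n_snps = 1, seed = 11, founder_freqs = 0.3)
  p_hat <- mean(Mf) / 2
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 200)))
})

test_that("liability phenotypes match their threshold and stored truths", {
  cfg <- sim_config(n_founders = 200, n_generations = 2, prevalence = 0.5,
                    h2_liability = 0.3, seed = 13)
  ped <- simulate_pedigree(cfg)
  pop <- simulate_phenotypes(ped, cfg)
  expect_equal(unname(pop$true_params["threshold"]), 0)
  n <- nrow(pop$phenotypes)
  expect_lt(abs(mean(pop$phenotypes$y) - 0.5), 3 * sqrt(0.25 / n))
  # phenotype is 1 iff CG-centred liability exceeds the threshold
  centred <- pop$liabilities - pop$cg_effects[pop$phenotypes$cg]
  expect_equal(pop$phenotypes$y,
               as.integer(centred > pop$true_params["threshold"]))
  # every phenotyped animal is in the pedigree
  expect_true(all(pop$phenotypes$animal %in% ped$animal))
})

test_that("founder breeding-value variance and prevalence track the config", {
  pop <- small_population(seed = 21, n_founders = 400, n_generations = 1,
                          h2 = 0.4, alpha = 0.1)
  founders <- pop$pedigree$animal[pop$pedigree$generation == 0]
  v <- var(pop$true_bv[founders])
  # chi-square sampling band for a variance at n = 400
  expect_lt(abs(v - 0.4), 4 * 0.4 * sqrt(2 / 399))
  n <- nrow(pop$phenotypes)
  expect_lt(abs(mean(pop$phenotypes$y) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("offspring breeding values regress on the midparent with slope 1", {
  cfg <- sim_config(n_founders = 1000, n_generations = 2, n_snps = 2,
                    h2_liability = 0.35, prevalence = 0.10, seed = 17)
  ped <- simulate_pedigree(cfg)
  pop <- simulate_phenotypes(ped, cfg)
  kids <- which(ped$sire_idx > 0)
  mid <- 0.5 * (pop$true_bv[ped$sire_idx[kids]] + pop$true_bv[ped$dam_idx[kids]])
  slope <- unname(coef(lm(pop$true_bv[kids] ~ mid))[2])
  expect_lt(abs(slope - 1), 0.1)
})

test_that("simulate_population is reproducible and internally consistent", {
  cfg <- sim_config(n_founders = 50, n_generations = 2, n_snps = 40, seed = 31)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$true_bv, b$true_bv)
  expect_true(all(rownames(a$genotypes) %in% a$pedigree$animal))
})
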