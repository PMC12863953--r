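# Wright's path-counting oracle: a_xy = sum over paths 0.5^L (1 + F_anc),
# evaluated by hand on the small fixtures.

test_that("tabular A reproduces classical kinship identities", {
  A <- build_A(ped_family())
  expect_equal(unname(A["s", "d"]), 0)       # unrelated founders
  expect_equal(unname(diag(A)), rep(1, 6))   # non-inbred
  expect_equal(unname(A["s", "o1"]), 0.5)    # parent-offspring
  expect_equal(unname(A["o1", "o2"]), 0.5)   # full sibs
  expect_equal(unname(A["o1", "h1"]), 0.25)  # half sibs
  expect_true(isSymmetric(unclass(A)))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("full-sib mating gives F = 0.25 and matching A entries", {
  A <- build_A(ped_inbred())
  expect_equal(unname(A["x", "x"]), 1.25)
  expect_equal(unname(inbreeding(ped_inbred())["x"]), 0.25)
  # parent-offspring with related parents: a(a,x) = 0.5 (a_aa + a_ab)
  expect_equal(unname(A["a", "x"]), 0.5 * (1 + 0.5))
})

test_that("sparse Henderson A-inverse equals the dense inverse", {
  for (ped in list(ped_family(), ped_inbred(),
                   small_population(seed = 3, n_founders = 30)$pedigree)) {
    A <- build_A(ped)
    Ainv <- build_A_inverse(ped)
    expect_lt(max(abs(as.matrix(Ainv) - solve(A))), 1e-8)
  }
})

test_that("pedigree truncation recodes parents beyond the horizon", {
  chain <- as_pedigree(data.frame(animal = c("g3", "g2", "g1", "g0"),
                                  sire = c("0", "g3", "g2", "g1"),
                                  dam = c("0", "0", "0", "0"),
                                  stringsAsFactors = FALSE))
  t0 <- truncate_pedigree(chain, n_generations = 0, anchors = "g0")
  expect_equal(t0$animal, "g0")
  expect_true(all(t0$sire == "0" & t0$dam == "0"))

  t3 <- truncate_pedigree(chain, n_generations = 3, anchors = "g0")
  expect_setequal(t3$animal, c("g0", "g1", "g2", "g3"))
  # the animal on the horizon keeps no parents
  expect_equal(t3$sire[t3$animal == "g3"], "0")
  expect_equal(t3$sire[t3$animal == "g2"], "g3")

  # horizon >= depth with all animals anchored: identity
  full <- truncate_pedigree(chain, n_generations = 10)
  expect_setequal(full$animal, chain$animal)
  expect_equal(full$sire[match(chain$animal, full$animal)], chain$sire)
  expect_error(truncate_pedigree(chain, anchors = "nope"), "absent")
})

test_that("G matches the hand-worked single-SNP example and centres fully", {
  # one SNP, p = 0.5: both animals coded 1 gives Z = 0
  M1 <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "s1"))
  G1 <- build_G(M1, freq_source = "supplied", freqs = 0.5)
  expect_true(all(G1 == 0))

  # codes (0, 2): denominator 2 * 0.25 = 0.5, Z = (-1, 1)
  M2 <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G2 <- build_G(M2, freq_source = "supplied", freqs = 0.5)
  expect_equal(unname(G2), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  expect_error(build_G(matrix(c(0, 0), 2, 1)), "fixed")
})

test_that("blending is the stated convex combination", {
  M <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- build_G(M, freq_source = "supplied", freqs = 0.5)
  A22 <- diag(2); dimnames(A22) <- dimnames(G)
  expect_equal(unname(blend_G(G, A22, weight = 1)), unname(G), ignore_attr = TRUE)
  expect_equal(unname(blend_G(G, A22, weight = 0)), A22, ignore_attr = TRUE)
  Gb <- blend_G(G, A22, weight = 0.95)
  expect_equal(unname(diag(Gb)), rep(0.95 * 2 + 0.05, 2))
})

test_that("mean diagonal of G tracks mean diagonal of A22 on simulated data", {
  pop <- small_population(seed = 11, n_founders = 200, n_generations = 2,
                          n_snps = 800)
  A <- build_A(pop$pedigree)
  g_ids <- rownames(pop$genotypes)
  G <- build_G(pop$genotypes)
  expect_lt(abs(mean(diag(G)) - mean(diag(A[g_ids, g_ids]))), 0.05)
})

test_that("H-inverse equals its dense-oracle assembly and A-inverse limits", {
  ped <- ped_family()
  Ainv <- build_A_inverse(ped)
  # no genotyped animals: H-inverse is exactly A-inverse
  H0 <- build_H_inverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), character(0))
  expect_lt(max(abs(as.matrix(H0) - as.matrix(Ainv))), 1e-12)

  # 2 genotyped of 6: dense brute-force assembly from plain inverses
  A <- build_A(ped)
  gids <- c("o1", "h1")
  set.seed(5)
  M <- matrix(rbinom(2 * 40, 2, 0.4), 2, 40,
              dimnames = list(gids, sprintf("s%02d", 1:40)))
  G <- build_G(M)
  A22 <- A[gids, gids]
  Gb <- blend_G(G, A22, 0.95)
  H <- build_H_inverse(Ainv, solve(Gb), solve(A22), gids)
  dense <- solve(A)
  idx <- match(gids, rownames(A))
  dense[idx, idx] <- dense[idx, idx] + solve(Gb) - solve(A22)
  expect_lt(max(abs(as.matrix(H) - dense)), 1e-8)

  # non-genotyped block is untouched
  rest <- setdiff(rownames(A), gids)
  expect_lt(max(abs(as.matrix(H)[rest, rest] - solve(A)[rest, rest])), 1e-8)

  # all genotyped with G_b = A: increment cancels
  Hc <- build_H_inverse(Ainv, solve(A), solve(A), rownames(A))
  expect_lt(max(abs(as.matrix(Hc) - solve(A))), 1e-8)
})
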