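#' Configuration for a synthetic population
#'
#' Collects the generative parameters for the simulator: herd structure,
#' marker panel, and the liability model that produces binary defect
#' phenotypes. The total liability variance is standardized to 1, so the
#' additive variance equals `h2_liability` and the residual variance is
#' `1 - h2_liability`; the defect threshold is `qnorm(1 - prevalence)`.
#'
#' @param n_founders even number of unrelated base animals.
#' @param n_generations number of discrete generations bred after the base.
#' @param offspring_per_mating litter size per monogamous pair.
#' @param n_snps number of biallelic neutral markers gene-dropped through
#'   the pedigree.
#' @param maf_range interval in (0, 0.5] from which founder allele
#'   frequencies are drawn uniformly, one per locus.
#' @param h2_liability narrow-sense heritability on the liability scale,
#'   in (0, 1); also the additive variance under the unit-variance
#'   standardization.
#' @param prevalence target defect prevalence alpha in (0, 1).
#' @param n_cgs contemporary groups per generation.
#' @param cg_effect_sd liability-scale SD of contemporary-group effects.
#' @param prop_genotyped fraction of animals carrying genotypes, in (0, 1].
#' @param seed integer RNG seed; every simulator output is deterministic
#'   given the seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 3,
                       offspring_per_mating = 2,
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       h2_liability = 0.35,
                       prevalence = 0.06,
                       n_cgs = 5,
                       cg_effect_sd = 0.25,
                       prop_genotyped = 0.2,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              h2_liability = as.numeric(h2_liability),
              prevalence = as.numeric(prevalence),
              n_cgs = as.integer(n_cgs),
              cg_effect_sd = as.numeric(cg_effect_sd),
              prop_genotyped = as.numeric(prop_genotyped),
              seed = as.integer(seed))
  with(cfg, {
    if (n_founders < 1 || n_generations < 0 || offspring_per_mating < 1 ||
        n_snps < 1 || n_cgs < 1)
      stop("counts must be >= 1 (n_generations >= 0)")
    if (n_founders %% 2 != 0) stop("n_founders must be even (monogamous pairing)")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must be an interval inside (0, 0.5]")
    if (h2_liability <= 0 || h2_liability >= 1)
      stop("h2_liability must lie strictly inside (0, 1)")
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must lie strictly inside (0, 1)")
    if (prop_genotyped <= 0 || prop_genotyped > 1)
      stop("prop_genotyped must lie in (0, 1]")
    if (cg_effect_sd < 0) stop("cg_effect_sd must be >= 0")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Discrete non-overlapping generations. Founders (generation 0) have
#' unknown parents. Within each generation animals are randomly paired
#' into monogamous sire/dam couples (half of the generation acts as sires,
#' half as dams) and each pair leaves `offspring_per_mating` offspring in
#' the next generation.
#'
#' @param config a [sim_config()].
#' @return a [as_pedigree()] object with a `generation` column.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n0 <- config$n_founders
  animal <- sprintf("G0_%04d", seq_len(n0))
  sire <- rep("0", n0)
  dam <- rep("0", n0)
  generation <- rep(0L, n0)
  current <- animal
  for (g in seq_len(config$n_generations)) {
    n_par <- length(current)
    if (n_par < 2) break
    perm <- sample(current)
    n_pairs <- n_par %/% 2
    sires <- perm[seq_len(n_pairs)]
    dams <- perm[n_pairs + seq_len(n_pairs)]
    n_off <- n_pairs * config$offspring_per_mating
    kid <- sprintf("G%d_%04d", g, seq_len(n_off))
    pair_of <- rep(seq_len(n_pairs), each = config$offspring_per_mating)
    animal <- c(animal, kid)
    sire <- c(sire, sires[pair_of])
    dam <- c(dam, dams[pair_of])
    generation <- c(generation, rep(g, n_off))
    current <- kid
  }
  as_pedigree(data.frame(animal = animal, sire = sire, dam = dam,
                         generation = generation,
                         stringsAsFactors = FALSE))
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn independently per locus at a frequency sampled
#' uniformly from `maf_range`; every non-founder inherits one allele from
#' each parent (Mendelian transmission, no linkage).
#'
#' @param ped a [as_pedigree()] object.
#' @param n_snps number of loci.
#' @param maf_range interval for founder allele frequencies.
#' @param seed RNG seed.
#' @param founder_freqs optional fixed per-locus founder frequencies
#'   (overrides `maf_range`), mainly for tests.
#' @return integer matrix (animals x SNPs, 0/1/2) with animal/SNP dimnames.
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1L, founder_freqs = NULL) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (n == 0) stop("empty pedigree")
  set.seed(seed)
  p <- if (is.null(founder_freqs))
    stats::runif(n_snps, maf_range[1], maf_range[2])
  else rep_len(founder_freqs, n_snps)
  # paternal/maternal allele per animal per locus
  pat <- matrix(0L, n, n_snps)
  mat <- matrix(0L, n, n_snps)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    pat[i, ] <- if (s > 0L) {
      ifelse(stats::runif(n_snps) < 0.5, pat[s, ], mat[s, ])
    } else as.integer(stats::runif(n_snps) < p)
    mat[i, ] <- if (d > 0L) {
      ifelse(stats::runif(n_snps) < 0.5, pat[d, ], mat[d, ])
    } else as.integer(stats::runif(n_snps) < p)
  }
  M <- pat + mat
  dimnames(M) <- list(ped$animal, sprintf("SNP%05d", seq_len(n_snps)))
  attr(M, "founder_freqs") <- p
  M
}

#' Simulate liability-model binary phenotypes over a pedigree
#'
#' Founder breeding values are N(0, h2); descendants get the parental mean
#' plus a Mendelian-sampling deviate with variance
#' `0.5 h2 (1 - (F_s + F_d)/2)`. The liability of an animal is its
#' contemporary-group effect plus breeding value plus a N(0, 1 - h2)
#' residual. The binary defect indicator compares the CG-centred liability
#' (breeding value + residual) against the threshold
#' `t = qnorm(1 - prevalence)`, so the realized prevalence converges to the
#' configured value irrespective of the CG-effect spread. Contemporary
#' groups are assigned at random within generation, keeping them
#' independent of the genetics.
#'
#' @param ped a [as_pedigree()] object (normally from
#'   [simulate_pedigree()]).
#' @param config a [sim_config()].
#' @return a list of class `sim_population` with elements `pedigree`,
#'   `phenotypes` (animal, cg, y), `true_bv`, `liabilities`, `cg_effects`
#'   and `true_params` (sigma2a, sigma2e, h2_liability, prevalence,
#'   threshold).
#' @export
simulate_phenotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- as_pedigree(ped)
  h2 <- config$h2_liability
  set.seed(config$seed + 1L)
  n <- nrow(ped)
  f <- .inbreeding_from_pedigree(ped$sire_idx, ped$dam_idx)
  bv <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (s > 0L && d > 0L) {
      ms_var <- 0.5 * h2 * (1 - (f[s] + f[d]) / 2)
      bv[i] <- 0.5 * (bv[s] + bv[d]) + stats::rnorm(1, 0, sqrt(ms_var))
    } else {
      bv[i] <- stats::rnorm(1, 0, sqrt(h2))
    }
  }
  # n_cgs management groups; membership randomized within each generation so
  # groups stay independent of the genetics yet every group spans the
  # generations (keeping the CG graph sire-connected)
  cg_label <- character(n)
  for (g in unique(ped$generation)) {
    in_g <- which(ped$generation == g)
    cg_label[in_g] <- sprintf("CG%02d",
                              sample.int(config$n_cgs, length(in_g), replace = TRUE))
  }
  cg_levels <- sort(unique(cg_label))
  cg_eff <- stats::rnorm(length(cg_levels), 0, config$cg_effect_sd)
  names(cg_eff) <- cg_levels
  resid <- stats::rnorm(n, 0, sqrt(1 - h2))
  liab <- cg_eff[cg_label] + bv + resid
  thr <- stats::qnorm(1 - config$prevalence)
  y <- as.integer(bv + resid > thr)
  phen <- data.frame(animal = ped$animal, cg = cg_label, y = y,
                     stringsAsFactors = FALSE)
  names(bv) <- names(liab) <- ped$animal
  out <- list(pedigree = ped,
              phenotypes = phen,
              true_bv = bv,
              liabilities = liab,
              cg_effects = cg_eff,
              true_params = c(sigma2a = h2, sigma2e = 1 - h2,
                              h2_liability = h2,
                              prevalence = config$prevalence,
                              threshold = thr))
  class(out) <- "sim_population"
  out
}

#' Simulate a complete population
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] (on a random subset
#' of animals of size `prop_genotyped * n`) and [simulate_phenotypes()]
#' under one configuration.
#'
#' @param config a [sim_config()].
#' @return a `sim_population` with an additional `genotypes` element
#'   covering the genotyped subset.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)
  M <- simulate_genotypes(ped, config$n_snps, config$maf_range,
                          seed = config$seed + 2L)
  pop <- simulate_phenotypes(ped, config)
  set.seed(config$seed + 3L)
  n_g <- max(1L, round(config$prop_genotyped * nrow(ped)))
  keep <- sort(sample.int(nrow(ped), n_g))
  pop$genotypes <- M[keep, , drop = FALSE]
  pop$config <- config
  pop
}
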