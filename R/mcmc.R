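#' Sampler settings for the animal model
#'
#' Defaults are desk-scale (50K iterations, 10K burn-in, thin 50); routine
#' large-population evaluations of binary defects run far longer chains,
#' and the fields accept any lengths. The contemporary-group effects get a
#' vague normal prior (variance `1e10`); variance components get flat
#' scaled-inverse-chi-square priors (`nu = -2`, `scale = 0`). For the
#' threshold model the residual variance is fixed at 1 and the threshold
#' at 0 (absorbed by the CG effects).
#'
#' @param model_type `"linear"` or `"threshold"`.
#' @param n_iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations.
#' @param thin thinning interval for retained samples.
#' @param seed RNG seed.
#' @param sigma2_cg prior variance of contemporary-group effects.
#' @param nu_a,scale_a prior degrees of freedom and scale for the additive
#'   variance.
#' @param nu_e,scale_e prior degrees of freedom and scale for the residual
#'   variance (linear model only).
#' @param start_sigma2a,start_sigma2e starting values.
#' @param fix_variances if TRUE the variances are held at their starting
#'   values (used for validation against the exact mixed-model solve).
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(model_type = c("threshold", "linear"),
                       n_iterations = 50000, burn_in = 10000, thin = 50,
                       seed = 1L,
                       sigma2_cg = 1e10,
                       nu_a = -2, scale_a = 0, nu_e = -2, scale_e = 0,
                       start_sigma2a = 0.25, start_sigma2e = 0.75,
                       fix_variances = FALSE) {
  model_type <- match.arg(model_type)
  stopifnot(burn_in < n_iterations, thin >= 1, start_sigma2a > 0,
            start_sigma2e > 0, sigma2_cg > 0)
  out <- list(model_type = model_type,
              n_iterations = as.integer(n_iterations),
              burn_in = as.integer(burn_in), thin = as.integer(thin),
              seed = as.integer(seed), sigma2_cg = sigma2_cg,
              nu_a = nu_a, scale_a = scale_a, nu_e = nu_e, scale_e = scale_e,
              start_sigma2a = start_sigma2a, start_sigma2e = start_sigma2e,
              fix_variances = isTRUE(fix_variances))
  class(out) <- "model_spec"
  out
}

#' Design of a single-trait animal model
#'
#' Assembles the record-level design linking binary phenotypes to
#' contemporary-group effects and animal additive effects, with the given
#' precision structure (H-inverse or A-inverse) as prior for the latter.
#' Phenotypes are 0/1; internally the defect (1) is the upper liability
#' category of the threshold model.
#'
#' @param phenotypes data.frame (animal, cg, y) after QC.
#' @param Hinv symmetric (sparse) precision structure over all evaluated
#'   animals, with animal ids as dimnames.
#' @return a list of class `model_design`.
#' @export
model_design <- function(phenotypes, Hinv) {
  stopifnot(all(c("animal", "cg", "y") %in% names(phenotypes)))
  ids <- rownames(Hinv)
  if (is.null(ids)) stop("Hinv needs animal ids as dimnames")
  if (!all(phenotypes$animal %in% ids))
    stop("phenotyped animals absent from the relationship structure: ",
         paste(utils::head(setdiff(phenotypes$animal, ids), 5), collapse = ", "))
  if (!all(phenotypes$y %in% c(0, 1))) stop("phenotypes must be coded 0/1")
  if (all(phenotypes$y == 0) || all(phenotypes$y == 1))
    stop("phenotype shows no variability; nothing to estimate")
  cg_levels <- sort(unique(phenotypes$cg))
  out <- list(y = as.numeric(phenotypes$y),
              record_animal = match(phenotypes$animal, ids),
              record_cg = match(phenotypes$cg, cg_levels),
              cg_levels = cg_levels,
              animal_ids = ids,
              Hinv = methods::as(Matrix::Matrix(Hinv, sparse = TRUE), "CsparseMatrix"))
  class(out) <- "model_design"
  out
}

#' Gibbs sampling of the linear or threshold animal model
#'
#' Single-site Gibbs sampler for
#' \deqn{y = X\beta + Za + e,\qquad a \sim N(0, H\sigma^2_a),}
#' where for the threshold model `y` is replaced by a latent liability
#' refreshed each iteration from truncated-normal full conditionals
#' (defect records above the threshold 0, others below) and the residual
#' variance is fixed at 1. Variance components are drawn from their
#' scaled-inverse-chi-square full conditionals unless held fixed.
#'
#' @param design a [model_design()].
#' @param spec a [model_spec()].
#' @return object of class `mcmc_chain`: retained draws of `sigma2a`,
#'   `sigma2e`, per-draw heritability `h2`, the matrix `a_draws`
#'   (draws x animals) and metadata.
#' @export
run_gibbs <- function(design, spec) {
  stopifnot(inherits(design, "model_design"), inherits(spec, "model_spec"))
  Hinv <- design$Hinv
  set.seed(spec$seed)
  res <- .gibbs_animal_model(
    y = design$y,
    record_animal = as.integer(design$record_animal),
    record_cg = as.integer(design$record_cg),
    n_animals = length(design$animal_ids),
    n_cg = length(design$cg_levels),
    Hi = Hinv@i, Hp = Hinv@p, Hx = Hinv@x,
    threshold = spec$model_type == "threshold",
    n_iter = spec$n_iterations, burn_in = spec$burn_in, thin = spec$thin,
    sigma2a_start = spec$start_sigma2a, sigma2e_start = spec$start_sigma2e,
    sigma2b = spec$sigma2_cg,
    nu_a = spec$nu_a, scale_a = spec$scale_a,
    nu_e = spec$nu_e, scale_e = spec$scale_e,
    fix_variances = spec$fix_variances)
  colnames(res$a_draws) <- design$animal_ids
  out <- list(sigma2a = res$sigma2a, sigma2e = res$sigma2e,
              h2 = res$sigma2a / (res$sigma2a + res$sigma2e),
              a_draws = res$a_draws,
              model_type = spec$model_type, spec = spec,
              animal_ids = design$animal_ids)
  class(out) <- "mcmc_chain"
  out
}

#' Exact mixed-model-equation solve
#'
#' Henderson's mixed-model equations for the same design and fixed
#' variance components; the deterministic BLUP counterpart of the Gibbs
#' sampler (its validation oracle, and a fast solver in its own right).
#'
#' @param design a [model_design()].
#' @param sigma2a additive variance.
#' @param sigma2e residual variance.
#' @param sigma2_cg prior variance of CG effects (a huge value approximates
#'   fixed effects while keeping the system full rank).
#' @return named numeric vector of BLUP additive effects (all animals);
#'   attribute `beta` holds the CG-effect solutions.
#' @export
solve_mme <- function(design, sigma2a, sigma2e, sigma2_cg = 1e10) {
  stopifnot(inherits(design, "model_design"), sigma2a > 0, sigma2e > 0)
  nb <- length(design$cg_levels)
  nq <- length(design$animal_ids)
  nrec <- length(design$y)
  X <- Matrix::sparseMatrix(i = seq_len(nrec), j = design$record_cg, x = 1,
                            dims = c(nrec, nb))
  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = design$record_animal, x = 1,
                            dims = c(nrec, nq))
  lambda <- sigma2e / sigma2a
  LHS <- rbind(
    cbind(Matrix::crossprod(X) + Matrix::Diagonal(nb, sigma2e / sigma2_cg),
          Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X),
          Matrix::crossprod(Z) + design$Hinv * lambda))
  RHS <- rbind(Matrix::crossprod(X, design$y), Matrix::crossprod(Z, design$y))
  sol <- tryCatch(Matrix::solve(LHS, RHS), error = function(e)
    stop("singular mixed-model equations: ", conditionMessage(e)))
  sol <- as.numeric(sol)
  a <- sol[nb + seq_len(nq)]
  names(a) <- design$animal_ids
  attr(a, "beta") <- stats::setNames(sol[seq_len(nb)], design$cg_levels)
  a
}

#' Posterior summaries of a Gibbs chain
#'
#' Posterior means and 95% highest-posterior-density intervals (shortest
#' contiguous interval over the retained draws) for the variance
#' components and heritability, plus posterior-mean breeding values as a
#' GEBV table. Heritability is computed per draw as
#' `sigma2a / (sigma2a + sigma2e)`: the liability scale for the threshold
#' model (residual 1), the observed scale for the linear model.
#'
#' @param chain an `mcmc_chain` from [run_gibbs()].
#' @param mass HPD probability mass.
#' @return a list of class `posterior_summary` with elements `params`
#'   (data.frame parameter/mean/hpd_lower/hpd_upper), `gebv` (a GEBV
#'   table: animal, model, scale, value), `h2_scale` and `n_draws`.
#' @export
summarize_chain <- function(chain, mass = 0.95) {
  stopifnot(inherits(chain, "mcmc_chain"))
  n <- length(chain$sigma2a)
  if (n == 0) stop("empty chain")
  low_draws <- n < 50
  stats_for <- function(x) {
    h <- hpd(x, mass = mass)
    c(mean = mean(x), hpd_lower = unname(h[1]), hpd_upper = unname(h[2]))
  }
  pars <- rbind(sigma2a = stats_for(chain$sigma2a),
                sigma2e = stats_for(chain$sigma2e),
                h2 = stats_for(chain$h2))
  params <- data.frame(parameter = rownames(pars), pars, row.names = NULL)
  scale <- if (chain$model_type == "threshold") "liability" else "observed"
  gebv <- data.frame(animal = chain$animal_ids,
                     model = chain$model_type,
                     scale = scale,
                     value = colMeans(chain$a_draws),
                     stringsAsFactors = FALSE)
  rownames(gebv) <- NULL
  out <- list(params = params, gebv = gebv, h2_scale = scale,
              n_draws = n, low_draws = low_draws)
  if (low_draws) warning("fewer than 50 retained draws; summaries are noisy")
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d retained draws, h2 on the %s scale)\n",
              x$n_draws, x$h2_scale))
  print(x$params, digits = 4)
  invisible(x)
}
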