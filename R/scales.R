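#' Threshold and ordinate implied by a trait prevalence
#'
#' For a binary trait with prevalence `alpha`, the liability threshold is
#' `t = qnorm(1 - alpha)` and the ordinate is the standard-normal density
#' at the threshold, `z = dnorm(t)` -- the two quantities driving every
#' scale conversion for categorical traits.
#'
#' @param alpha prevalence in (0, 1).
#' @return list(alpha, threshold, ordinate) of class `scale_params`.
#' @export
scale_params <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value strictly inside (0, 1)")
  t <- stats::qnorm(1 - alpha)
  structure(list(alpha = alpha, threshold = t, ordinate = stats::dnorm(t)),
            class = "scale_params")
}

#' Heritability conversion from the liability to the observed scale
#'
#' Dempster-Lerner conversion
#' \deqn{h^2_o = z^2 h^2_l / (\alpha (1 - \alpha))}
#' with `z` the normal ordinate at the prevalence threshold. Since
#' `z^2 < alpha (1 - alpha)` for every prevalence, the observed-scale value
#' is always the smaller one.
#'
#' @param h2_liability heritability on the liability scale, in (0, 1).
#' @param alpha trait prevalence in (0, 1).
#' @return heritability on the observed (0/1) scale.
#' @export
h2_liability_to_observed <- function(h2_liability, alpha) {
  stopifnot(h2_liability > 0, h2_liability <= 1)
  sp <- scale_params(alpha)
  out <- sp$ordinate^2 * h2_liability / (alpha * (1 - alpha))
  if (out >= 1)
    stop("conversion produced h2 >= 1; inputs are inconsistent")
  out
}

#' Heritability conversion from the observed to the liability scale
#'
#' Exact inverse of [h2_liability_to_observed()]:
#' `h2_l = h2_o * alpha (1 - alpha) / z^2`.
#'
#' @param h2_observed heritability on the observed scale.
#' @param alpha trait prevalence in (0, 1).
#' @return heritability on the liability scale.
#' @export
h2_observed_to_liability <- function(h2_observed, alpha) {
  stopifnot(h2_observed > 0)
  sp <- scale_params(alpha)
  out <- h2_observed * alpha * (1 - alpha) / sp$ordinate^2
  if (out >= 1)
    stop("conversion produced h2 >= 1; inputs are inconsistent")
  out
}

.check_gebv_table <- function(gebv) {
  stopifnot(is.data.frame(gebv), all(c("animal", "value") %in% names(gebv)))
  gebv
}

#' Observed-to-liability GEBV adjustment via residual variance and
#' heritability ratio
#'
#' First of two alternative linear rescalings of observed-scale breeding
#' values onto the liability scale, driven by the observed-scale residual
#' variance and the ratio of observed to liability heritability. The
#' flattened printed form of this adjustment admits two algebraic
#' readings; both are provided:
#' `parse = "product"` gives `BV_l = BV_o / sigma2e_o * (1 - h2_o / h2_l)`,
#' `parse = "ratio"` gives `BV_l = BV_o / (sigma2e_o * (1 - h2_o / h2_l))`.
#' Either way the map is linear through the origin, so rankings are
#' preserved exactly.
#'
#' @param gebv GEBV table (animal, value, ...) on the observed scale.
#' @param sigma2e_o residual variance on the observed scale.
#' @param h2_o observed-scale heritability (must be < `h2_l`).
#' @param h2_l liability-scale heritability.
#' @param parse which algebraic reading to use.
#' @return the GEBV table with rescaled `value` and `scale = "liability"`;
#'   attribute `adjustment` records method and factor.
#' @export
gebv_var_heritability_adjust <- function(gebv, sigma2e_o, h2_o, h2_l,
                                         parse = c("product", "ratio")) {
  parse <- match.arg(parse)
  gebv <- .check_gebv_table(gebv)
  stopifnot(sigma2e_o > 0, h2_o > 0, h2_l > 0, h2_l < 1)
  if (h2_o >= h2_l)
    stop("h2_o must be smaller than h2_l; the adjustment is undefined otherwise")
  factor <- if (parse == "product") (1 - h2_o / h2_l) / sigma2e_o
            else 1 / (sigma2e_o * (1 - h2_o / h2_l))
  gebv$value <- gebv$value * factor
  gebv$scale <- "liability"
  attr(gebv, "adjustment") <- list(method = "variance_heritability",
                                   parse = parse, factor = factor)
  gebv
}

#' Observed-to-liability GEBV adjustment via the threshold ordinate
#'
#' Second rescaling: the scaling factor is
#' \deqn{z^* = \sqrt{(h^2_o / h^2_l)\, \alpha (1 - \alpha)}}
#' and `BV_l = BV_o / z*`. When `h2_o` and `h2_l` satisfy the
#' Dempster-Lerner relation exactly, `z*` equals the normal ordinate at
#' the prevalence threshold, which is what earns the adjustment its
#' "threshold density" name.
#'
#' @param gebv GEBV table on the observed scale.
#' @param h2_o observed-scale heritability.
#' @param h2_l liability-scale heritability.
#' @param alpha trait prevalence.
#' @return GEBV table on the liability scale; attribute `adjustment`
#'   records the factor `z*`.
#' @export
gebv_threshold_density_adjust <- function(gebv, h2_o, h2_l, alpha) {
  gebv <- .check_gebv_table(gebv)
  stopifnot(h2_o > 0, h2_l > 0, h2_l < 1, alpha > 0, alpha < 1)
  zstar <- sqrt((h2_o / h2_l) * alpha * (1 - alpha))
  if (zstar <= 0) stop("scaling factor z* is zero; check inputs")
  gebv$value <- gebv$value / zstar
  gebv$scale <- "liability"
  attr(gebv, "adjustment") <- list(method = "threshold_density",
                                   zstar = zstar)
  gebv
}

#' Liability-scale GEBVs to defect probabilities
#'
#' Maps each animal's liability-scale GEBV `U_i` to the probability of
#' expressing the defect,
#' \deqn{P_i = 1 - \Phi\left((t - (U_i - \mu_U)) / \sigma_e\right),}
#' with `t` the prevalence threshold and `mu_U` the mean GEBV over the
#' reference set (all animals in the table by default), so the
#' population-average animal sits exactly at `P = alpha`. The map is
#' strictly increasing in the GEBV. `orientation = "printed"` exposes the
#' complementary (decreasing) form `Phi((t - mu_U - U_i)/sigma_e)` for
#' comparison with reports using that convention.
#'
#' @param gebv GEBV table on the liability scale.
#' @param alpha trait prevalence.
#' @param sigma_e residual SD on the liability scale (1 under the usual
#'   threshold-model identification).
#' @param reference_ids animals defining `mu_U` (default: all in table).
#' @param orientation `"complement"` (increasing in GEBV, default) or
#'   `"printed"`.
#' @return GEBV table with `value` in (0, 1) and `scale = "probability"`;
#'   attribute `conversion` records alpha, t, mu_U, sigma_e.
#' @export
gebv_to_probability <- function(gebv, alpha, sigma_e = 1,
                                reference_ids = NULL,
                                orientation = c("complement", "printed")) {
  orientation <- match.arg(orientation)
  gebv <- .check_gebv_table(gebv)
  if (sigma_e <= 0) stop("sigma_e must be > 0")
  sp <- scale_params(alpha)
  ref <- if (is.null(reference_ids)) gebv$value
         else gebv$value[gebv$animal %in% reference_ids]
  if (!length(ref)) stop("empty reference set for mu_U")
  mu <- mean(ref)
  gebv$value <- if (orientation == "complement")
    1 - stats::pnorm((sp$threshold - (gebv$value - mu)) / sigma_e)
  else stats::pnorm((sp$threshold - mu - gebv$value) / sigma_e)
  gebv$scale <- "probability"
  attr(gebv, "conversion") <- list(alpha = alpha, threshold = sp$threshold,
                                   mu_U = mu, sigma_e = sigma_e,
                                   orientation = orientation)
  gebv
}
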