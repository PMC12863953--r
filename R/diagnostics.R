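# Spectral density at zero estimated by non-overlapping batch means:
# var of the batch means times the batch length. Returns the squared
# standard error of the overall mean.
.batch_se2 <- function(x, n_batches = 20) {
  n <- length(x)
  n_batches <- max(2L, min(n_batches, n %/% 2L))
  bl <- n %/% n_batches
  x <- x[seq_len(bl * n_batches)]
  bm <- colMeans(matrix(x, nrow = bl))
  stats::var(bm) / n_batches
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early window against the mean of a late window
#' of a chain, standardized by spectral standard errors estimated with
#' non-overlapping batch means. |z| below ~2 is consistent with
#' stationarity (advisory, not a hard pass/fail).
#'
#' @param draws ordered numeric sequence (length >= 100).
#' @param frac_first fraction of the chain in the early window.
#' @param frac_last fraction of the chain in the late window.
#' @param n_batches batches for the spectral standard errors.
#' @return z statistic; a constant chain returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
geweke_z <- function(draws, frac_first = 0.1, frac_last = 0.5,
                     n_batches = 20) {
  stopifnot(length(draws) >= 100, frac_first > 0, frac_last > 0,
            frac_first + frac_last <= 1)
  if (stats::sd(draws) == 0)
    return(structure(0, degenerate = TRUE))
  n <- length(draws)
  first <- draws[seq_len(floor(frac_first * n))]
  last <- draws[seq.int(n - floor(frac_last * n) + 1L, n)]
  z <- (mean(first) - mean(last)) /
    sqrt(.batch_se2(first, n_batches) + .batch_se2(last, n_batches))
  z
}

# Cramer-von Mises critical values (Brownian-bridge limit) by alpha.
.cvm_crit <- c("0.1" = 0.3473, "0.05" = 0.4614, "0.01" = 0.7435)

#' Heidelberger-Welch stationarity and halfwidth test
#'
#' Stationarity: a Cramer-von-Mises test on the Brownian bridge of
#' cumulative sums, applied to the full chain and then repeatedly after
#' discarding initial 10% increments (up to 50%) until the test passes.
#' Halfwidth: the 95% halfwidth of the retained-portion mean (spectral SE
#' by batch means) relative to the mean's magnitude must not exceed `eps`.
#'
#' @param draws ordered numeric sequence (length >= 100).
#' @param eps halfwidth tolerance relative to |mean|.
#' @param alpha stationarity test level (0.1, 0.05 or 0.01).
#' @param n_batches batches for spectral variance estimates.
#' @return list(stationary, halfwidth_passed, halfwidth_ratio,
#'   start_fraction, mean). `halfwidth_ratio` is NA when the mean is
#'   indistinguishable from zero.
#' @export
heidelberger_welch <- function(draws, eps = 0.1, alpha = 0.05,
                               n_batches = 20) {
  stopifnot(length(draws) >= 100)
  crit <- .cvm_crit[as.character(alpha)]
  if (is.na(crit)) stop("alpha must be one of 0.1, 0.05, 0.01")
  if (stats::sd(draws) == 0) {
    return(list(stationary = TRUE, halfwidth_passed = TRUE,
                halfwidth_ratio = 0, start_fraction = 0,
                mean = draws[1]))
  }
  n <- length(draws)
  stationary <- FALSE
  start_frac <- 0
  kept <- draws
  for (frac in seq(0, 0.5, by = 0.1)) {
    kept <- draws[seq.int(floor(frac * n) + 1L, n)]
    m <- length(kept)
    s0 <- .batch_se2(kept, n_batches) * m   # spectral density at zero / 1
    if (s0 <= 0) break
    cs <- cumsum(kept) - seq_len(m) * mean(kept)
    bridge <- cs / sqrt(m * s0)
    cvm <- sum(bridge^2) / m
    if (cvm < crit) {
      stationary <- TRUE
      start_frac <- frac
      break
    }
  }
  mu <- mean(kept)
  half <- stats::qnorm(0.975) * sqrt(.batch_se2(kept, n_batches))
  ratio <- if (abs(mu) < sqrt(.Machine$double.eps)) NA_real_ else half / abs(mu)
  list(stationary = stationary,
       halfwidth_passed = stationary && !is.na(ratio) && ratio <= eps,
       halfwidth_ratio = ratio,
       start_fraction = start_frac,
       mean = mu)
}

#' Highest-posterior-density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws numeric sample (length >= 1).
#' @param mass probability mass in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Convergence report for a Gibbs chain
#'
#' Applies [geweke_z()] and [heidelberger_welch()] to the variance and
#' heritability draws of a chain.
#'
#' @param chain an `mcmc_chain` from [run_gibbs()].
#' @param ... passed to the individual diagnostics.
#' @return data.frame of class `diagnostic_report` with one row per
#'   parameter.
#' @export
diagnose_chain <- function(chain, ...) {
  stopifnot(inherits(chain, "mcmc_chain"))
  pars <- list(sigma2a = chain$sigma2a, sigma2e = chain$sigma2e,
               h2 = chain$h2)
  rows <- lapply(names(pars), function(nm) {
    x <- pars[[nm]]
    if (length(x) < 100) {
      return(data.frame(parameter = nm, geweke_z = NA_real_,
                        stationary = NA, halfwidth_ratio = NA_real_,
                        n_draws = length(x), stringsAsFactors = FALSE))
    }
    hw <- heidelberger_welch(x, ...)
    data.frame(parameter = nm,
               geweke_z = as.numeric(geweke_z(x)),
               stationary = hw$stationary,
               halfwidth_ratio = hw$halfwidth_ratio,
               n_draws = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diagnostic_report", "data.frame")
  out
}
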