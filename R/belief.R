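#' Gaussian payoff beliefs
#'
#' An agent's belief about one strategy's payoff is a Gaussian summarised by
#' its mean, spread and a pseudo-sample size expressing certainty: the prior
#' is treated as `pseudo_n` imaginary observations with that sample mean and
#' variance, and every real observation adds one more.
#'
#' @param mean Believed expected payoff (utility units). Vectorised; the
#'   three arguments are recycled to a common length.
#' @param sd Believed payoff spread, `>= 0`.
#' @param pseudo_n Certainty as an effective sample size, `>= 1`.
#' @return A tibble with columns `mean`, `sd`, `pseudo_n`; one row per belief.
#' @examples
#' strategy_belief(mean = 1, sd = 0.5)
#' @export
strategy_belief <- function(mean, sd, pseudo_n = 2) {
  out <- tibble::tibble(mean = as.numeric(mean), sd = as.numeric(sd),
                        pseudo_n = as.numeric(pseudo_n))
  if (any(!is.finite(out$mean)) || any(!is.finite(out$sd)) ||
      any(!is.finite(out$pseudo_n))) {
    stop("belief parameters must be finite", call. = FALSE)
  }
  if (any(out$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(out$pseudo_n < 1)) stop("pseudo_n must be >= 1", call. = FALSE)
  out
}

#' Sample a payoff draw from a belief
#'
#' One Gaussian draw per belief row, with that row's mean and spread. A
#' point-mass belief (`sd = 0`) returns its mean deterministically. Uses
#' R's global random stream; seed with [set.seed()] for reproducibility.
#'
#' @param belief A data frame with columns `mean`, `sd` (see
#'   [strategy_belief()]).
#' @return Numeric vector of draws, one per row.
#' @export
sample_value <- function(belief) {
  stats::rnorm(nrow(belief), mean = belief$mean, sd = belief$sd)
}

#' Choose a strategy by sampling both beliefs
#'
#' Each agent takes one random draw from its internal perception of each
#' strategy's payoff and plays the strategy with the highest draw. An exact
#' tie (possible only for degenerate point-mass beliefs) resolves to the
#' asocial strategy.
#'
#' @param belief_social,belief_asocial Data frames of beliefs, one row per
#'   agent, as built by [strategy_belief()].
#' @return Logical vector: `TRUE` where the social strategy is chosen.
#' @examples
#' set.seed(1)
#' choose_strategy(strategy_belief(0, 1), strategy_belief(1, 1))
#' @export
choose_strategy <- function(belief_social, belief_asocial) {
  stopifnot(nrow(belief_social) == nrow(belief_asocial))
  sample_value(belief_social) > sample_value(belief_asocial)
}

#' Bayesian belief update from one observed payoff
#'
#' Moment-matched pseudo-sample updating: the prior counts as `pseudo_n`
#' observations with sample mean `mean` and sample variance `sd^2`; an
#' observed payoff `y` is pooled in as one more observation, so
#' `n' = n + 1`, `mu' = (n mu + y) / n'` and
#' `sd'^2 = (n (sd^2 + mu^2) + y^2) / n' - mu'^2`. Equivalent to tracking
#' the sufficient statistics `(n, sum y, sum y^2)`, which makes the update
#' order-independent over a batch and gives individually experienced and
#' socially observed payoffs exactly equal weight — one call each.
#'
#' The posterior spread is floored at `sd_min` so that beliefs never collapse
#' to an absorbing point mass and agents keep occasionally re-testing a
#' strategy.
#'
#' @inheritParams sample_value
#' @param y Observed payoff(s), finite, recycled against the belief rows.
#' @param sd_min Lower bound on the posterior spread (utility units).
#' @return An updated belief tibble of the same shape.
#' @examples
#' update_belief(strategy_belief(1, 1, 2), y = 4) # mean 2, var 8/3, n 3
#' @export
update_belief <- function(belief, y, sd_min = 1e-3) {
  if (any(!is.finite(y))) stop("observation must be finite", call. = FALSE)
  n <- belief$pseudo_n
  mu <- belief$mean
  n2 <- n + 1
  mu2 <- (n * mu + y) / n2
  var2 <- (n * (belief$sd^2 + mu^2) + y^2) / n2 - mu2^2
  strategy_belief(mu2, sqrt(pmax(var2, sd_min^2)), n2)
}

#' Calibrate the shared prior spread to a target initial pilgrim proportion
#'
#' Priors are cultural expectations shared across the population and always
#' favour staying at home (`mu_asocial > mu_social`); what they control is
#' how many agents try the pilgrimage on the very first turn. With both
#' strategies given a common spread `sigma`, a first-turn agent plays social
#' with probability `Phi((mu_S - mu_A) / (sigma * sqrt(2)))`, so the spread
#' that makes an expected proportion `p0` of the group attend at the onset is
#' `sigma = (mu_A - mu_S) / (sqrt(2) * qnorm(1 - p0))`.
#'
#' @param p0 Target initial pilgrim proportion, in `(0, 0.5)`.
#' @param mu_asocial,mu_social Prior means; must satisfy
#'   `mu_asocial > mu_social`.
#' @return The common prior standard deviation.
#' @examples
#' calibrate_prior_sd(0.10, mu_asocial = 1, mu_social = 0)
#' @export
calibrate_prior_sd <- function(p0, mu_asocial, mu_social) {
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) ||
      p0 <= 0 || p0 >= 0.5) {
    stop("p0 must lie strictly between 0 and 0.5", call. = FALSE)
  }
  if (mu_asocial <= mu_social) {
    stop("calibration requires mu_asocial > mu_social", call. = FALSE)
  }
  (mu_asocial - mu_social) / (sqrt(2) * stats::qnorm(1 - p0))
}
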