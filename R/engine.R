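#' Simulation configuration
#'
#' One fully resolved parameter set for the agent-based simulator: the
#' assurance-game constants, the environmental noise level, the shared prior
#' block, the active conventions and the master seed. Exactly one row of a
#' sweep grid.
#'
#' The prior block can be given either as a target initial pilgrim
#' proportion `p0` — in which case the common prior spread is calibrated
#' with [calibrate_prior_sd()] so the expected first-turn attendance is
#' `N * p0` — or as explicit spreads `sd_asocial` / `sd_social`.
#'
#' @param N Number of agents.
#' @param TMax Turns per round.
#' @param RMax Rounds (independent replicate populations).
#' @param AP Asocial payoff `h` (utility units).
#' @param SP Social payoff `s` when the threshold is cleared; `SP > AP > 0`.
#' @param PV Environmental payoff spread: the scale of the zero-mean
#'   Gaussian frequency-independent payoff added to every agent each turn.
#'   Interpreted as a standard deviation unless `pv_is_variance = TRUE`.
#' @param M Explicit attendance threshold, or `NULL` to derive it from
#'   `M_fraction` of the group (floored, minimum 1).
#' @param M_fraction Fraction of `N` required when `M` is `NULL`.
#' @param p0 Target initial pilgrim proportion in `(0, 0.5)`, or `NULL` when
#'   explicit prior spreads are supplied.
#' @param mu_asocial,mu_social Shared prior means; the cultural expectation
#'   is that staying home pays more, so `mu_asocial > mu_social`.
#' @param sd_asocial,sd_social Explicit prior spreads; `NULL` means
#'   calibrate from `p0`.
#' @param pseudo_n Initial prior certainty (pseudo-sample size) for both
#'   strategies.
#' @param sd_min Floor on belief spread after updating.
#' @param attendance_rule `"off"` or `"three_visits"`.
#' @param transmission_rule `"baseline"`, `"site_serving"` or
#'   `"general_positivity"`.
#' @param strict_positivity Cutoff strictness for the general positivity
#'   bias; see [eligible_demonstrators()].
#' @param pv_is_variance If `TRUE`, `PV` is a variance and the noise scale
#'   is `sqrt(PV)`.
#' @param seed Master seed; every source of randomness in a run descends
#'   deterministically from it.
#' @return An object of class `sim_config` (named list) with resolved `M`
#'   and prior spreads.
#' @examples
#' sim_config(N = 10, PV = 1.2, p0 = 0.10, seed = 1)
#' @export
sim_config <- function(N = 50, TMax = 300, RMax = 50,
                       AP = 1, SP = 2, PV = 0.6,
                       M = NULL, M_fraction = 1 / 3,
                       p0 = 0.10,
                       mu_asocial = AP, mu_social = 0,
                       sd_asocial = NULL, sd_social = NULL,
                       pseudo_n = 2, sd_min = 1e-3,
                       attendance_rule = c("off", "three_visits"),
                       transmission_rule = c("baseline", "site_serving",
                                             "general_positivity"),
                       strict_positivity = FALSE,
                       pv_is_variance = FALSE,
                       seed = 1L) {
  attendance_rule <- match.arg(attendance_rule)
  transmission_rule <- match.arg(transmission_rule)
  N <- as.integer(N); TMax <- as.integer(TMax); RMax <- as.integer(RMax)
  stopifnot(N >= 1, TMax >= 1, RMax >= 1)
  if (!(SP > AP && AP > 0)) stop("need SP > AP > 0", call. = FALSE)
  if (!is.numeric(PV) || PV < 0) stop("PV must be >= 0", call. = FALSE)
  M <- if (is.null(M)) threshold_size(N, M_fraction) else as.integer(M)
  if (M < 1L || M > N) stop("need 1 <= M <= N", call. = FALSE)

  if (is.null(sd_asocial) || is.null(sd_social)) {
    if (is.null(p0)) {
      stop("supply either p0 or explicit prior spreads", call. = FALSE)
    }
    sd_asocial <- sd_social <- calibrate_prior_sd(p0, mu_asocial, mu_social)
  }

  structure(
    list(
      N = N, TMax = TMax, RMax = RMax, M = M,
      AP = AP, SP = SP, PV = PV,
      p0 = p0, mu_asocial = mu_asocial, mu_social = mu_social,
      sd_asocial = sd_asocial, sd_social = sd_social,
      pseudo_n = pseudo_n, sd_min = sd_min,
      attendance_rule = attendance_rule,
      transmission_rule = transmission_rule,
      strict_positivity = strict_positivity,
      pv_is_variance = pv_is_variance,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pilgrimage simulation configuration\n")
  cat(sprintf("  agents N = %d, threshold M = %d, turns = %d, rounds = %d\n",
              x$N, x$M, x$TMax, x$RMax))
  cat(sprintf("  payoffs: AP = %g, SP = %g; noise spread PV = %g%s\n",
              x$AP, x$SP, x$PV,
              if (x$pv_is_variance) " (variance)" else ""))
  cat(sprintf("  priors: muA = %g (sd %.4g), muS = %g (sd %.4g), nu = %g\n",
              x$mu_asocial, x$sd_asocial, x$mu_social, x$sd_social,
              x$pseudo_n))
  cat(sprintf("  rules: attendance = %s, transmission = %s; seed = %d\n",
              x$attendance_rule, x$transmission_rule, x$seed))
  invisible(x)
}

#' @method tidy sim_config
#' @export
tidy.sim_config <- function(x, ...) {
  tibble::as_tibble(x[c("N", "TMax", "RMax", "M", "AP", "SP", "PV",
                        "mu_asocial", "mu_social", "sd_asocial", "sd_social",
                        "pseudo_n", "sd_min", "attendance_rule",
                        "transmission_rule", "seed")])
}

noise_sd <- function(config) {
  if (config$pv_is_variance) sqrt(config$PV) else config$PV
}

#' Initialise a population of agents
#'
#' All agents start with identical, culturally shared priors for the two
#' strategies (one Gaussian belief each), no attendance commitment, and no
#' play history. Draws nothing from the random stream.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per agent: `id`, belief columns
#'   (`mu_social`, `sd_social`, `nu_social`, and the asocial triple),
#'   `commitment`, `last_strategy`, `last_payoff`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble::tibble(
    id = seq_len(config$N),
    mu_social = config$mu_social,
    sd_social = config$sd_social,
    nu_social = config$pseudo_n,
    mu_asocial = config$mu_asocial,
    sd_asocial = config$sd_asocial,
    nu_asocial = config$pseudo_n,
    commitment = 0L,
    last_strategy = NA_character_,
    last_payoff = NA_real_
  )
}

# One synchronous turn on the fast internal state (a list of plain vectors).
# Sequence: choice -> pilgrim count -> coordination payoff -> environmental
# payoff -> individual update -> social learning -> record. All individual
# updates complete before any social observation, and social learning sees
# this turn's strategies and payoffs.
step_population <- function(st, config) {
  n <- config$N

  # 1. strategy choice: committed agents attend without drawing comparisons
  #    (draws are still consumed to keep the stream layout fixed)
  draw_s <- stats::rnorm(n, st$mu_social, st$sd_social)
  draw_a <- stats::rnorm(n, st$mu_asocial, st$sd_asocial)
  social <- draw_s > draw_a
  forced <- st$commitment > 0L
  social[forced] <- TRUE

  if (config$attendance_rule == "three_visits") {
    st$commitment <- apply_attendance_rule(st$commitment, social)
  }

  # 2-5. payoffs
  k <- sum(social)
  cleared <- k >= config$M
  fd <- ifelse(social, if (cleared) config$SP else 0, config$AP)
  pay <- fd + stats::rnorm(n, 0, noise_sd(config))

  # 6. individual update of the played strategy's belief
  upd <- function(mu, sd, nu, y) {
    n2 <- nu + 1
    mu2 <- (nu * mu + y) / n2
    var2 <- (nu * (sd^2 + mu^2) + y^2) / n2 - mu2^2
    list(mu = mu2, sd = sqrt(pmax(var2, config$sd_min^2)), nu = n2)
  }
  is_s <- which(social); is_a <- which(!social)
  if (length(is_s)) {
    u <- upd(st$mu_social[is_s], st$sd_social[is_s], st$nu_social[is_s],
             pay[is_s])
    st$mu_social[is_s] <- u$mu
    st$sd_social[is_s] <- u$sd
    st$nu_social[is_s] <- u$nu
  }
  if (length(is_a)) {
    u <- upd(st$mu_asocial[is_a], st$sd_asocial[is_a], st$nu_asocial[is_a],
             pay[is_a])
    st$mu_asocial[is_a] <- u$mu
    st$sd_asocial[is_a] <- u$sd
    st$nu_asocial[is_a] <- u$nu
  }

  # 7. social learning: each focal observes one demonstrator drawn uniformly
  #    from the transmission-eligible pool, never itself; empty pool -> skip
  ok <- eligible_demonstrators(social, pay, config$transmission_rule,
                               config$AP, config$strict_positivity)
  pool <- which(ok)
  m <- length(pool)
  u01 <- stats::runif(n)
  if (m > 0L) {
    pos_of_focal <- match(seq_len(n), pool) # NA when focal not in pool
    demo <- integer(n)
    out_pool <- is.na(pos_of_focal)
    demo[out_pool] <- pool[floor(u01[out_pool] * m) + 1]
    in_pool <- which(!out_pool)
    if (m >= 2L) {
      d <- floor(u01[in_pool] * (m - 1)) + 1
      d <- d + (d >= pos_of_focal[in_pool])
      demo[in_pool] <- pool[d]
    } # m == 1: lone pool member observes nobody
    has_demo <- demo > 0L
    obs_social <- social[demo[has_demo]]
    obs_pay <- pay[demo[has_demo]]
    focal <- which(has_demo)
    f_s <- focal[obs_social]; y_s <- obs_pay[obs_social]
    f_a <- focal[!obs_social]; y_a <- obs_pay[!obs_social]
    if (length(f_s)) {
      u <- upd(st$mu_social[f_s], st$sd_social[f_s], st$nu_social[f_s], y_s)
      st$mu_social[f_s] <- u$mu
      st$sd_social[f_s] <- u$sd
      st$nu_social[f_s] <- u$nu
    }
    if (length(f_a)) {
      u <- upd(st$mu_asocial[f_a], st$sd_asocial[f_a], st$nu_asocial[f_a],
               y_a)
      st$mu_asocial[f_a] <- u$mu
      st$sd_asocial[f_a] <- u$sd
      st$nu_asocial[f_a] <- u$nu
    }
  }

  st$last_strategy <- ifelse(social, "social", "asocial")
  st$last_payoff <- pay
  st$k <- k
  st$cleared <- cleared
  st
}

#' Play one synchronous turn
#'
#' Executes the per-turn model sequence once: every agent chooses a strategy
#' (committed agents attend without drawing), pilgrims are counted against
#' the threshold, coordination and environmental payoffs are summed, each
#' agent updates the belief of the strategy it played with its own total
#' payoff, and then observes one demonstrator from the transmission-eligible
#' pool and updates that strategy's belief with the demonstrator's total
#' payoff. Agents thus conflate the frequency-independent noise with the
#' ritual's benefit in both learning channels.
#'
#' Uses the global random stream; callers wanting reproducibility should
#' [set.seed()] first (or use [run_round()] / [run_experiment()], which
#' seed from the configuration).
#'
#' @param agents Population tibble from [init_population()].
#' @param config The [sim_config()].
#' @return A list with `agents` (updated population) and `record` (a
#'   one-row tibble: `k`, `prop_social`, `threshold_cleared`).
#' @export
play_turn <- function(agents, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(agents) || nrow(agents) == 0L) {
    stop("empty agent list", call. = FALSE)
  }
  if (nrow(agents) != config$N) {
    stop("population size does not match config N", call. = FALSE)
  }
  st <- step_population(as.list(agents), config)
  rec <- tibble::tibble(
    k = st$k,
    prop_social = st$k / config$N,
    threshold_cleared = st$cleared
  )
  st$k <- NULL; st$cleared <- NULL
  list(agents = tibble::as_tibble(st), record = rec)
}

#' Run one round (a fresh population over `TMax` turns)
#'
#' Seeds the random stream from `config$seed`, initialises a fresh
#' population, and plays `TMax` sequential turns; beliefs persist across
#' turns within the round. Identical configurations produce bit-identical
#' trajectories.
#'
#' @inheritParams play_turn
#' @param keep_agents If `TRUE`, the final population is attached as the
#'   `"agents"` attribute of the result (for debugging belief trajectories).
#' @return A tibble with `TMax` rows: `turn`, `k`, `prop_social`,
#'   `threshold_cleared`.
#' @export
run_round <- function(config, keep_agents = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- as.list(init_population(config))
  tmax <- config$TMax
  k <- integer(tmax)
  cleared <- logical(tmax)
  for (t in seq_len(tmax)) {
    st <- step_population(st, config)
    k[t] <- st$k
    cleared[t] <- st$cleared
  }
  out <- tibble::tibble(
    turn = seq_len(tmax),
    k = k,
    prop_social = k / config$N,
    threshold_cleared = cleared
  )
  if (keep_agents) {
    st$k <- NULL; st$cleared <- NULL
    attr(out, "agents") <- tibble::as_tibble(st)
  }
  out
}

#' Run a full experiment (`RMax` independent rounds)
#'
#' Each round starts a fresh population with its own sub-seed, derived
#' deterministically from the master seed, so rounds are independent
#' replicates and the whole experiment replays exactly from `config$seed`.
#'
#' @inheritParams play_turn
#' @return A tibble of class `ritual_sim` with columns `round`, `turn`, `k`,
#'   `prop_social`, `threshold_cleared`; the configuration is attached as
#'   the `"config"` attribute.
#' @examples
#' run_experiment(sim_config(N = 10, TMax = 20, RMax = 2, seed = 42))
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(2147483646L, config$RMax)
  rounds <- purrr::map(seq_len(config$RMax), function(r) {
    cfg <- config
    cfg$seed <- sub_seeds[r]
    dplyr::mutate(run_round(cfg), round = r, .before = 1)
  })
  out <- dplyr::bind_rows(rounds)
  class(out) <- c("ritual_sim", class(out))
  attr(out, "config") <- config
  attr(out, "sub_seeds") <- sub_seeds
  out
}

#' @method tidy ritual_sim
#' @export
tidy.ritual_sim <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ritual_sim")
  attr(out, "config") <- NULL
  attr(out, "sub_seeds") <- NULL
  out
}

#' @method glance ritual_sim
#' @export
glance.ritual_sim <- function(x, fixation_cutoff = 0.9, ...) {
  config <- attr(x, "config")
  finals <- dplyr::filter(x, .data$turn == max(.data$turn))
  tibble::tibble(
    rounds = length(unique(x$round)),
    turns = max(x$turn),
    mean_final_prop = mean(finals$prop_social),
    fixation_fraction = mean(finals$prop_social >= fixation_cutoff),
    cleared_turn_fraction = mean(x$threshold_cleared),
    N = config$N, M = config$M, PV = config$PV
  )
}
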