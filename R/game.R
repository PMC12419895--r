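#' Parameters of the N-person assurance game
#'
#' Bundles the four constants of the threshold coordination game: the safe
#' asocial payoff `h` (staying at home), the social payoff `s` earned by a
#' pilgrim only when enough others attend, the group size `N`, and the
#' attendance threshold `M` at which the collective benefit unlocks.
#'
#' @param h Asocial payoff, in utility units. Must satisfy `0 < h < s`.
#' @param s Social payoff when the threshold is cleared. Must exceed `h`.
#' @param N Group size, an integer `>= 2`.
#' @param M Threshold number of pilgrims needed for the social payoff,
#'   an integer in `[1, N]`. Defaults to one third of the group
#'   (see [threshold_size()]).
#'
#' @return An object of class `game_params` (a named list).
#' @examples
#' game_params(h = 1, s = 2, N = 10)
#' @export
game_params <- function(h = 1, s = 2, N = 10, M = threshold_size(N)) {
  if (!is.numeric(h) || !is.numeric(s) || length(h) != 1L || length(s) != 1L ||
      !is.finite(h) || !is.finite(s) || h <= 0 || s <= h) {
    stop("payoffs must satisfy s > h > 0", call. = FALSE)
  }
  N <- as.integer(N)
  M <- as.integer(M)
  if (length(N) != 1L || is.na(N) || N < 2L) {
    stop("N must be an integer >= 2", call. = FALSE)
  }
  if (length(M) != 1L || is.na(M) || M < 1L || M > N) {
    stop("M must be an integer with 1 <= M <= N", call. = FALSE)
  }
  structure(list(h = h, s = s, N = N, M = M), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf(
    "N-person assurance game: h = %g, s = %g, N = %d, M = %d\n",
    x$h, x$s, x$N, x$M
  ))
  invisible(x)
}

#' Attendance threshold from a group fraction
#'
#' The collective benefit is assumed to require a fixed *proportion* of the
#' group on site, not an absolute head count; the default is one third, so
#' `N = 10` gives `M = 3`, `N = 50` gives 16 and `N = 100` gives 33. The
#' result is floored and never below 1.
#'
#' @param N Group size.
#' @param fraction Fraction of the group required, in `(0, 1]`.
#' @return Integer threshold `M`.
#' @examples
#' threshold_size(10) # 3
#' @export
threshold_size <- function(N, fraction = 1 / 3) {
  stopifnot(is.numeric(N), N >= 1, fraction > 0, fraction <= 1)
  pmax(1L, as.integer(floor(N * fraction)))
}

check_prop <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' Stage payoffs of the assurance game
#'
#' `payoff_asocial()` is the payoff to staying at home given `k` pilgrims
#' among the `N - 1` other group members: always `h`, whatever the others do.
#' `payoff_social()` is the payoff to attending when `k` pilgrims (including
#' the focal agent) show up: the stepwise `s * [k >= M]`, i.e. `s` when the
#' threshold is cleared and nothing otherwise.
#'
#' @param k Pilgrim count; for the asocial payoff this counts the *other*
#'   members (`0 <= k <= N - 1`), for the social payoff it includes the focal
#'   agent (`1 <= k <= N`). Vectorised.
#' @param params A [game_params()] object.
#' @return Numeric vector of payoffs.
#' @examples
#' p <- game_params(h = 1, s = 2, N = 10, M = 3)
#' payoff_asocial(0:9, p)
#' payoff_social(1:10, p)
#' @export
payoff_asocial <- function(k, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(k != floor(k)) || any(k < 0) || any(k > params$N - 1L)) {
    stop("k must be an integer count in [0, N - 1]", call. = FALSE)
  }
  rep_len(params$h, length(k))
}

#' @rdname payoff_asocial
#' @export
payoff_social <- function(k, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(k != floor(k)) || any(k < 1) || any(k > params$N)) {
    stop("k must be an integer count in [1, N]", call. = FALSE)
  }
  ifelse(k >= params$M, params$s, 0)
}

#' Expected fitness of each strategy in a well-mixed population
#'
#' With a proportion `x` of the (infinite, well-mixed) population willing to
#' attend, a focal agent's `N - 1` co-players are binomial draws. The social
#' strategy's expected fitness weights the stepwise payoff over every
#' co-player composition,
#' `fS(x) = sum_k C(N-1, k) x^k (1-x)^(N-1-k) * piS(k + 1)`,
#' while the asocial strategy's expected fitness is `h` for every `x` (the
#' binomial weights sum to one).
#'
#' @param x Proportion of the population playing the social strategy, in
#'   `[0, 1]`. Vectorised.
#' @inheritParams payoff_asocial
#' @return Numeric vector of expected payoffs.
#' @examples
#' p <- game_params(h = 1, s = 2, N = 3, M = 2)
#' expected_fitness_social(c(0, 0.5, 1), p)
#' @export
expected_fitness_social <- function(x, params) {
  stopifnot(inherits(params, "game_params"))
  check_prop(x)
  k <- 0:(params$N - 1L)
  pay <- payoff_social(k + 1L, params)
  vapply(
    x,
    function(xi) sum(stats::dbinom(k, params$N - 1L, xi) * pay),
    numeric(1)
  )
}

#' @rdname expected_fitness_social
#' @export
expected_fitness_asocial <- function(x, params) {
  stopifnot(inherits(params, "game_params"))
  check_prop(x)
  k <- 0:(params$N - 1L)
  pay <- payoff_asocial(k, params)
  vapply(
    x,
    function(xi) sum(stats::dbinom(k, params$N - 1L, xi) * pay),
    numeric(1)
  )
}

#' Fitness advantage of the social strategy
#'
#' The gap `fS(x) - fH(x)`, computed in closed form as
#' `-h + s * P(K >= M - 1)` with `K ~ Binomial(N - 1, x)`: the social
#' strategy gains only when at least `M - 1` co-players also attend. At
#' `x = 0` with `M >= 2` the gap is exactly `-h` — a lone pilgrim cannot
#' invade a population of homebodies.
#'
#' @inheritParams expected_fitness_social
#' @return Numeric vector, `fS - fH`.
#' @examples
#' p <- game_params(h = 1, s = 2, N = 3, M = 2)
#' fitness_gap(c(0, 0.5, 1), p) # -1 + 4x - 2x^2
#' @export
fitness_gap <- function(x, params) {
  stopifnot(inherits(params, "game_params"))
  check_prop(x)
  tail_prob <- stats::pbinom(params$M - 2L, params$N - 1L, x,
                             lower.tail = FALSE)
  -params$h + params$s * tail_prob
}

#' Replicator dynamics of the social strategy
#'
#' Rate of change of the social proportion under payoff-proportional
#' spread, `x' = x (1 - x) (fS - fH)`. Treated as a continuous-time rate:
#' its sign and zeros determine the equilibria and basins of attraction.
#'
#' @inheritParams expected_fitness_social
#' @return Numeric vector of rates; exactly zero at `x = 0` and `x = 1`.
#' @export
replicator_step <- function(x, params) {
  x * (1 - x) * fitness_gap(x, params)
}

#' Equilibria of the replicator dynamics
#'
#' Locates the fixed points of `x' = x(1-x)(fS - fH)` and classifies their
#' stability. The boundaries `x = 0` and `x = 1` are always fixed; `x = 0` is
#' stable when the gap there is negative and `x = 1` when it is positive.
#' Interior roots are found by sign-change scanning of the gap on a uniform
#' grid followed by bisection; a root where the gap crosses from negative to
#' positive is unstable (it separates the two basins of attraction), one
#' crossing from positive to negative is stable.
#'
#' For any `s > h > 0` and `2 <= M <= N` the game has exactly two stable
#' boundary equilibria and one interior unstable threshold.
#'
#' @inheritParams payoff_asocial
#' @param grid_resolution Number of grid points used for sign-change
#'   detection, at least 100.
#' @param tol Bisection stops when `|gap| < tol` at the midpoint or the
#'   bracket is narrower than `tol`.
#' @return A tibble of class `ritual_equilibria` with columns `x` and
#'   `stability` (`"stable"` or `"unstable"`).
#' @examples
#' find_equilibria(game_params(h = 1, s = 2, N = 3, M = 2))
#' @export
find_equilibria <- function(params, grid_resolution = 1001L, tol = 1e-10) {
  stopifnot(inherits(params, "game_params"))
  grid_resolution <- as.integer(grid_resolution)
  if (is.na(grid_resolution) || grid_resolution < 100L) {
    stop("grid_resolution must be at least 100", call. = FALSE)
  }

  gap <- function(x) fitness_gap(x, params)
  xs <- seq(0, 1, length.out = grid_resolution)
  g <- gap(xs)

  roots <- numeric(0)
  flat <- FALSE
  for (i in seq_len(grid_resolution - 1L)) {
    gi <- g[i]; gj <- g[i + 1L]
    if (gi == 0 && gj == 0) {
      flat <- TRUE
      next
    }
    if (gi == 0) {
      if (xs[i] > 0) roots <- c(roots, xs[i])
      next
    }
    if (gi * gj < 0) {
      lo <- xs[i]; hi <- xs[i + 1L]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        gm <- gap(mid)
        if (abs(gm) < tol) break
        if (sign(gm) == sign(gap(lo))) lo <- mid else hi <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  if (flat) {
    warning("fitness gap vanishes on an interval; reporting a single ",
            "representative root per flat stretch", call. = FALSE)
    zero_xs <- xs[g == 0 & xs > 0 & xs < 1]
    if (length(zero_xs)) roots <- c(roots, zero_xs[1])
  }
  roots <- roots[roots > tol & roots < 1 - tol]
  if (length(roots) > 1L) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 10 * tol)]
  }

  eps <- 1e-9
  interior_stab <- vapply(
    roots,
    function(r) {
      if (gap(max(r - eps, 0)) > 0 && gap(min(r + eps, 1)) < 0) "stable"
      else "unstable"
    },
    character(1)
  )

  out <- tibble::tibble(
    x = c(0, roots, 1),
    stability = c(
      if (gap(0) < 0) "stable" else "unstable",
      interior_stab,
      if (gap(1) > 0) "stable" else "unstable"
    )
  )
  class(out) <- c("ritual_equilibria", class(out))
  attr(out, "params") <- params
  out
}

#' @method tidy game_params
#' @export
tidy.game_params <- function(x, ...) {
  tibble::tibble(
    term = c("h", "s", "N", "M"),
    value = c(x$h, x$s, x$N, x$M),
    description = c(
      "asocial payoff", "social payoff (threshold cleared)",
      "group size", "attendance threshold"
    )
  )
}
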