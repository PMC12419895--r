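#' Specification of a factorial parameter sweep
#'
#' The study design crosses three factors: the target initial pilgrim
#' proportion (weak-to-strong shared priors), the environmental payoff
#' spread, and the group size. The defaults give the full
#' 3 x 8 x 3 = 72-condition design: initial proportions of 1%, 5% and 10%,
#' variance levels 0.2 to 1.6 in steps of 0.2, and groups of 10, 50 and 100
#' agents. All remaining simulation settings are shared across cells.
#'
#' @param initial_proportions Numeric vector of target `p0` values, each in
#'   `(0, 0.5)`.
#' @param pv_grid Numeric vector of environmental spread levels.
#' @param group_sizes Integer vector of group sizes `N`.
#' @param seed Master sweep seed; each condition gets a deterministic
#'   sub-seed derived from it.
#' @param ... Shared [sim_config()] arguments (e.g. `TMax`, `RMax`, `AP`,
#'   `SP`, rules).
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec() # the full 72-condition design
#' @export
sweep_spec <- function(initial_proportions = c(0.01, 0.05, 0.10),
                       pv_grid = seq(0.2, 1.6, by = 0.2),
                       group_sizes = c(10L, 50L, 100L),
                       seed = 1L, ...) {
  if (!length(initial_proportions) || !length(pv_grid) ||
      !length(group_sizes)) {
    stop("all factor lists must be non-empty", call. = FALSE)
  }
  if (any(initial_proportions <= 0) || any(initial_proportions >= 0.5)) {
    stop("every initial proportion must lie in (0, 0.5)", call. = FALSE)
  }
  structure(
    list(
      initial_proportions = initial_proportions,
      pv_grid = pv_grid,
      group_sizes = as.integer(group_sizes),
      seed = as.integer(seed),
      shared = list(...)
    ),
    class = "sweep_spec"
  )
}

# Deterministic per-condition seed; arithmetic only, so grid construction
# (and CLI --dry-run) never touches the random stream.
condition_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Build the Cartesian sweep grid
#'
#' Expands the factor lists of a [sweep_spec()] into one [sim_config()] per
#' cell, each with a readable `condition_id` and its own deterministic
#' sub-seed. Consumes no random numbers.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble with columns `condition_id`, `p0`, `PV`, `N`, `M`,
#'   `seed` and a `config` list-column of [sim_config()] objects.
#' @examples
#' nrow(build_sweep_grid(sweep_spec())) # 72
#' @export
build_sweep_grid <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- tidyr::expand_grid(
    p0 = spec$initial_proportions,
    PV = spec$pv_grid,
    N = spec$group_sizes
  )
  grid$condition_id <- sprintf("p%04.1f_pv%03.1f_n%03d",
                               100 * grid$p0, grid$PV, grid$N)
  grid$seed <- condition_seed(spec$seed, seq_len(nrow(grid)))
  grid$config <- purrr::pmap(
    grid[c("p0", "PV", "N", "seed")],
    function(p0, PV, N, seed) {
      do.call(sim_config,
              c(list(p0 = p0, PV = PV, N = N, seed = seed), spec$shared))
    }
  )
  grid$M <- purrr::map_int(grid$config, "M")
  dplyr::select(grid, "condition_id", "p0", "PV", "N", "M", "seed", "config")
}

#' Run every condition of a sweep
#'
#' Maps [run_experiment()] over the rows of a sweep grid and binds the
#' per-turn trajectories, labelled by condition.
#'
#' @param grid A grid from [build_sweep_grid()], or a [sweep_spec()] (which
#'   is expanded first).
#' @param progress Print one line per condition as it completes.
#' @return A trajectory tibble: `condition_id`, `p0`, `PV`, `N`, `round`,
#'   `turn`, `k`, `prop_social`, `threshold_cleared`.
#' @export
run_sweep <- function(grid, progress = FALSE) {
  if (inherits(grid, "sweep_spec")) grid <- build_sweep_grid(grid)
  purrr::pmap_dfr(
    grid[c("condition_id", "p0", "PV", "N", "config")],
    function(condition_id, p0, PV, N, config) {
      if (progress) {
        message(sprintf("running %s ...", condition_id))
      }
      traj <- tidy(run_experiment(config))
      dplyr::mutate(traj,
                    condition_id = condition_id, p0 = p0, PV = PV, N = N,
                    .before = 1)
    }
  )
}

#' Summarise sweep trajectories
#'
#' For each condition and turn, the mean proportion of agents playing the
#' social strategy across rounds; for each condition, the fraction of rounds
#' whose final-turn proportion reached the fixation cutoff (repeated on
#' every row of that condition).
#'
#' @param trajectories Output of [run_sweep()] or [run_experiment()] (a
#'   `condition_id` column is added if missing).
#' @param fixation_cutoff A round counts as fixed when its final-turn
#'   `prop_social` is at least this value.
#' @return A tibble with one row per (condition, turn): grouping metadata,
#'   `mean_prop_social` and `fixation_fraction`.
#' @export
summarize_trajectories <- function(trajectories, fixation_cutoff = 0.9) {
  traj <- tibble::as_tibble(trajectories)
  if (!"condition_id" %in% names(traj)) traj$condition_id <- "run"
  meta <- intersect(c("p0", "PV", "N"), names(traj))

  lens <- dplyr::summarise(
    dplyr::group_by(traj, .data$condition_id, .data$round),
    len = dplyr::n(), .groups = "drop"
  )
  if (length(unique(lens$len)) != 1L) {
    stop("trajectories have mismatched lengths across rounds", call. = FALSE)
  }

  finals <- traj |>
    dplyr::group_by(.data$condition_id, .data$round) |>
    dplyr::slice_max(.data$turn, n = 1, with_ties = FALSE) |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      fixation_fraction = mean(.data$prop_social >= fixation_cutoff),
      .groups = "drop"
    )

  traj |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("condition_id", meta, "turn")
    ))) |>
    dplyr::summarise(mean_prop_social = mean(.data$prop_social),
                     .groups = "drop") |>
    dplyr::left_join(finals, by = "condition_id")
}

#' First turn at which each round crosses an adoption level
#'
#' Used to compare how fast conventions drive the social strategy towards
#' fixation: for each round, the first turn with `prop_social` strictly
#' above `level`; rounds that never cross are dropped.
#'
#' @param trajectories A trajectory tibble with `round`, `turn`,
#'   `prop_social` (and optionally `condition_id`).
#' @param level Adoption level to cross, default 0.9.
#' @return A tibble with one row per crossing round: `condition_id` (if
#'   present), `round`, `first_passage_turn`.
#' @export
first_passage <- function(trajectories, level = 0.9) {
  traj <- tibble::as_tibble(trajectories)
  keys <- intersect(c("condition_id", "round"), names(traj))
  traj |>
    dplyr::filter(.data$prop_social > level) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(first_passage_turn = min(.data$turn), .groups = "drop")
}

#' Compare site-side conventions at one condition
#'
#' Runs the same condition under the baseline rules and each requested
#' variant: the three-visit attendance commitment and the two transmission
#' biases. All variants share the base configuration and seed, so
#' differences are attributable to the rules.
#'
#' @param config A [sim_config()] giving the base condition (its
#'   `attendance_rule`/`transmission_rule` are overridden).
#' @param variants Character vector drawn from `"baseline"`,
#'   `"three_visits"`, `"site_serving"`, `"general_positivity"`.
#' @return A trajectory tibble with a leading `variant` column.
#' @export
run_variants <- function(config,
                         variants = c("baseline", "three_visits",
                                      "site_serving",
                                      "general_positivity")) {
  stopifnot(inherits(config, "sim_config"))
  variants <- match.arg(variants, several.ok = TRUE)
  purrr::map_dfr(variants, function(v) {
    cfg <- config
    cfg$attendance_rule <- if (v == "three_visits") "three_visits" else "off"
    cfg$transmission_rule <-
      if (v %in% c("site_serving", "general_positivity")) v else "baseline"
    dplyr::mutate(tidy(run_experiment(cfg)), variant = v, .before = 1)
  })
}
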