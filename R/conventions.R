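#' Demonstrator eligibility under a transmission rule
#'
#' Site-side conventions can stifle reports of bad outcomes and thereby bias
#' who is available to be observed during social learning:
#'
#' * `baseline` — every agent may serve as a demonstrator.
#' * `site_serving` — the "lucky pilgrim" bias: among social players, only
#'   those whose total payoff was strictly better than the expected asocial
#'   payoff may be observed; asocial players are unaffected.
#' * `general_positivity` — anyone, whatever their strategy, whose payoff
#'   fell below the expected asocial payoff is removed from the pool.
#'
#' The luck cutoff is the game's configured asocial payoff `h` (an
#' environmental property), not any agent's subjective belief about it.
#' By default `general_positivity` removes strictly sub-`h` payoffs (a
#' payoff equal to `h` stays eligible); set `strict_positivity = TRUE` to
#' remove those as well. Boundary payoffs exactly equal to `h` occur with
#' probability zero whenever the environmental noise is non-degenerate.
#'
#' @param social Logical vector: strategy played this turn, `TRUE` = social.
#' @param payoff Numeric vector of total (coordination + environmental)
#'   payoffs this turn.
#' @param rule One of `"baseline"`, `"site_serving"`, `"general_positivity"`.
#' @param reference_payoff The expected asocial payoff `h` used as cutoff.
#' @param strict_positivity Logical; see Details.
#' @return Logical vector: `TRUE` where the agent may serve as demonstrator.
#' @export
eligible_demonstrators <- function(social, payoff,
                                   rule = c("baseline", "site_serving",
                                            "general_positivity"),
                                   reference_payoff,
                                   strict_positivity = FALSE) {
  rule <- match.arg(rule)
  switch(rule,
    baseline = rep_len(TRUE, length(social)),
    site_serving = !social | payoff > reference_payoff,
    general_positivity =
      if (strict_positivity) payoff > reference_payoff
      else payoff >= reference_payoff
  )
}

#' Pool of demonstrators visible to a focal agent
#'
#' Applies [eligible_demonstrators()] to a population after a turn and drops
#' the focal agent (agents never observe themselves). An empty pool is a
#' legal result — the engine then skips social learning for that agent.
#'
#' @param agents A population tibble (see [init_population()]) whose
#'   `last_strategy` and `last_payoff` columns are set for the current turn.
#' @param focal Integer id of the focal agent.
#' @inheritParams eligible_demonstrators
#' @return The subset of `agents` rows that may be observed.
#' @examples
#' pop <- tibble::tibble(
#'   id = 1:3,
#'   last_strategy = c("asocial", "social", "social"),
#'   last_payoff = c(0.9, 1.5, 0.8)
#' )
#' demonstrator_pool(pop, focal = 1, rule = "site_serving",
#'                   reference_payoff = 1)
#' @export
demonstrator_pool <- function(agents, focal,
                              rule = c("baseline", "site_serving",
                                       "general_positivity"),
                              reference_payoff,
                              strict_positivity = FALSE) {
  rule <- match.arg(rule)
  if (any(is.na(agents$last_strategy)) || any(is.na(agents$last_payoff))) {
    stop("all agents must have played (last_strategy/last_payoff set)",
         call. = FALSE)
  }
  ok <- eligible_demonstrators(
    agents$last_strategy == "social", agents$last_payoff,
    rule, reference_payoff, strict_positivity
  )
  agents[ok & agents$id != focal, , drop = FALSE]
}

#' Three-visit attendance commitment
#'
#' Under the three-visit convention, an agent who freely chooses to attend
#' commits to two further visits: it plays the social strategy on the next
#' two turns without consulting its beliefs. Committed agents still learn,
#' both from their own payoffs and from observed demonstrators; only the
#' choice step is bypassed. Commitments do not stack — a fresh commitment can
#' only begin once the previous one has run out.
#'
#' @param commitment Integer vector of remaining forced visits (0, 1 or 2)
#'   *before* this turn's choice.
#' @param chose_social Logical vector: strategy actually played this turn
#'   (forced agents count as social).
#' @return Updated commitment counters after the turn.
#' @examples
#' apply_attendance_rule(commitment = c(0, 2, 1, 0),
#'                       chose_social = c(TRUE, TRUE, TRUE, FALSE))
#' @export
apply_attendance_rule <- function(commitment, chose_social) {
  stopifnot(length(commitment) == length(chose_social),
            all(commitment %in% 0:2))
  committed <- commitment > 0
  out <- integer(length(commitment))
  out[committed] <- commitment[committed] - 1L
  out[!committed & chose_social] <- 2L
  out
}
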