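# State indices used throughout the engine and the microsimulation.
.STATES <- c("HEALTHY", "SARC", "SARC_CVD", "DEAD")
.H <- 1L; .S <- 2L; .C <- 3L; .D <- 4L

# Arm accounting conventions shared by the cohort engine and the
# microsimulation: initial state, whether the treatment-risk modifier
# applies, and for how many cycles the annual intervention cost is charged
# (lifelong for true positives; exactly one cycle for false positives, the
# only extra cost that group incurs; none otherwise).
.arm_spec <- function(arm) {
  arm <- match.arg(arm, c("TP", "FN", "TN", "FP"))
  switch(arm,
    TP = list(arm = "TP", treated = TRUE,  initial_state = .S, treat_cycles = Inf),
    FN = list(arm = "FN", treated = FALSE, initial_state = .S, treat_cycles = 0),
    TN = list(arm = "TN", treated = FALSE, initial_state = .H, treat_cycles = 0),
    FP = list(arm = "FP", treated = FALSE, initial_state = .H, treat_cycles = 1))
}

#' Per-cycle transition probabilities for one model arm
#'
#' Builds the annual transition layer of the Markov model.  Sarcopenic
#' states carry a fall-and-fracture event probability
#' `p_fall * p_fracture_given_fall`; in an event cycle the fracture
#' mortality replaces the state mortality.  Progression is forward-only:
#' healthy individuals never become sarcopenic after screening, sarcopenia
#' is irreversible, and cardiovascular disease (CVD) is absorbing among the
#' living.  In the treated arm the intervention multiplies the fall
#' probability, CVD incidence, and the sarcopenia-attributable *excess*
#' mortality (state mortality minus healthy mortality, floored at zero) by
#' `1 - efficacy`, so treated risk never drops below healthy risk.  Within a
#' cycle risks resolve in the order fracture event, death, then CVD
#' transition among survivors.
#'
#' @param params a `sarc_params` object.
#' @param treated logical; apply the intervention-efficacy risk modifier.
#' @return list of per-cycle probability vectors (length `horizon_cycles`):
#'   `p_death_healthy`, `p_death_sarc`, `p_death_sarc_cvd`, `p_death_event`,
#'   `p_event`, `p_cvd`, plus `horizon`, `treated`, `efficacy`.
#' @export
#' @examples
#' tm <- transition_model(sarc_parameters(), treated = FALSE)
#' tm$p_event[1]  # 0.273 * 0.40
transition_model <- function(params, treated = FALSE) {
  T <- as.integer(params$horizon_cycles)
  eff <- if (treated) params$efficacy else 0
  pdh <- rep_len(params$p_death_healthy, T)
  adj <- function(p) pdh + (1 - eff) * pmax(0, p - pdh)
  tm <- list(
    horizon = T, treated = treated, efficacy = eff,
    p_death_healthy = pdh,
    p_death_sarc     = adj(params$p_death_sarc),
    p_death_sarc_cvd = adj(params$p_death_sarc_cvd),
    p_death_event    = adj(params$p_death_fracture),
    p_event = rep((1 - eff) * params$p_fall * params$p_fracture_given_fall, T),
    p_cvd   = rep((1 - eff) * params$p_cvd, T)
  )
  probs <- unlist(tm[c("p_death_healthy", "p_death_sarc", "p_death_sarc_cvd",
                       "p_death_event", "p_event", "p_cvd")])
  if (any(probs < 0 | probs > 1))
    stop("transition_model: constructed probability outside [0, 1]")
  tm
}

#' Propagate a cohort through the Markov model
#'
#' Deterministic matrix propagation of state-membership fractions (no
#' sampling): each cycle, sarcopenic occupants are split into event and
#' no-event subgroups, deaths are removed at the subgroup-specific
#' mortality, and surviving sarcopenia-only occupants transition to the
#' CVD state.
#'
#' @param tm a [transition_model()].
#' @param arm one of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @param params a `sarc_params` object.
#' @return object of class `cohort_trace`: `occupancy` ((horizon+1) x 4
#'   matrix in persons, rows summing to `cohort_size`), per-cycle start
#'   occupancies of the three alive states, fracture-event counts per state,
#'   CVD entrants, and deaths.
#' @export
run_cohort <- function(tm, arm, params) {
  spec <- .arm_spec(arm)
  T <- tm$horizon
  n <- params$cohort_size
  occ <- matrix(0, nrow = T + 1L, ncol = 4L,
                dimnames = list(cycle = 0:T, state = .STATES))
  state <- c(0, 0, 0, 0)
  state[spec$initial_state] <- 1
  occ[1L, ] <- state
  start_H <- start_S <- start_C <- numeric(T)
  ev_S <- ev_C <- entrants <- deaths <- numeric(T)
  for (t in seq_len(T)) {
    H <- state[.H]; S <- state[.S]; C <- state[.C]
    start_H[t] <- H; start_S[t] <- S; start_C[t] <- C
    eS <- S * tm$p_event[t]
    eC <- C * tm$p_event[t]
    ev_S[t] <- eS; ev_C[t] <- eC
    H2 <- H * (1 - tm$p_death_healthy[t])
    S_surv <- (S - eS) * (1 - tm$p_death_sarc[t]) +
              eS * (1 - tm$p_death_event[t])
    C_surv <- (C - eC) * (1 - tm$p_death_sarc_cvd[t]) +
              eC * (1 - tm$p_death_event[t])
    newc <- S_surv * tm$p_cvd[t]
    entrants[t] <- newc
    deaths[t] <- (H + S + C) - (H2 + S_surv + C_surv)
    state <- c(H2, S_surv - newc, C_surv + newc,
               state[.D] + deaths[t])
    occ[t + 1L, ] <- state
  }
  structure(list(arm = spec$arm, horizon = T, cohort_size = n,
                 occupancy = occ * n,
                 start_H = start_H, start_S = start_S, start_C = start_C,
                 events_sarc = ev_S, events_cvd = ev_C,
                 entrants_cvd = entrants, deaths = deaths),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Markov cohort trace, arm ", x$arm, ", ", x$horizon,
      " cycles, cohort of ", x$cohort_size, "\n", sep = "")
  alive <- sum(x$occupancy[x$horizon + 1L, c(.H, .S, .C)])
  cat(sprintf("  alive at horizon: %.1f persons; fracture events: %.1f\n",
              alive, sum(x$events_sarc + x$events_cvd) * x$cohort_size))
  invisible(x)
}

#' Discounted per-person costs and QALYs from a cohort trace
#'
#' Applies the accounting conventions of the model: utilities accrue with a
#' trapezoidal half-cycle correction (a death during a cycle contributes
#' half a cycle at the cycle's utility); a fracture-event cycle uses the
#' fracture utility of the underlying state; the annual intervention cost
#' is charged to start-of-cycle occupancy for the arm's treatment-cost
#' cycles; fracture cost is charged once per event; CVD care costs the
#' initial amount in the entry cycle and the incremental amount in each
#' subsequent cycle spent in the CVD state.  All flows in cycle `t` are
#' discounted by `(1 + discount_rate)^-t`; screening costs (cycle 0) are
#' handled upstream and not included here.
#'
#' @param trace a [run_cohort()] result.
#' @param tm the [transition_model()] the trace was generated under.
#' @param params a `sarc_params` object.
#' @param arm the arm label (determines treatment-cost cycles).
#' @return list with per-cycle discounted `cost_stream` and `qaly_stream`
#'   (per person) and scalar totals `cost` and `qaly`.
#' @export
accumulate_outcomes <- function(trace, tm, params, arm) {
  spec <- .arm_spec(arm)
  T <- trace$horizon
  t <- seq_len(T)
  disc <- (1 + params$discount_rate)^(-t)
  H <- trace$start_H; S <- trace$start_S; C <- trace$start_C
  eS <- trace$events_sarc; eC <- trace$events_cvd
  pdH <- tm$p_death_healthy; pdS <- tm$p_death_sarc
  pdC <- tm$p_death_sarc_cvd; pdE <- tm$p_death_event
  treat_on <- as.numeric(t <= spec$treat_cycles)
  cost <- params$cost_treatment_annual * treat_on * (H + S + C) +
          params$cost_cvd_incremental * C +
          params$cost_fracture * (eS + eC) +
          params$cost_cvd_initial * trace$entrants_cvd
  qaly <- params$u_healthy * H * (1 - pdH / 2) +
          params$u_sarc * (S - eS) * (1 - pdS / 2) +
          params$u_sarc_fracture * eS * (1 - pdE / 2) +
          params$u_sarc_cvd * (C - eC) * (1 - pdC / 2) +
          params$u_sarc_cvd_fracture * eC * (1 - pdE / 2)
  list(cost_stream = cost * disc, qaly_stream = qaly * disc,
       cost = sum(cost * disc), qaly = sum(qaly * disc))
}

#' Lifetime discounted outcomes of one classification arm
#'
#' @param params a `sarc_params` object.
#' @param arm one of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @return named vector `c(cost, qaly)` per person.
#' @export
evaluate_arm <- function(params, arm) {
  spec <- .arm_spec(arm)
  tm <- transition_model(params, treated = spec$treated)
  trace <- run_cohort(tm, arm, params)
  out <- accumulate_outcomes(trace, tm, params, arm)
  c(cost = out$cost, qaly = out$qaly)
}

# Outcomes of the four arms; they do not depend on the strategy, only on
# the parameter set, so strategies reuse one computation.
.arm_table <- function(params) {
  arms <- c("TP", "FN", "TN", "FP")
  out <- vapply(arms, function(a) evaluate_arm(params, a), numeric(2))
  t(out)  # rows TP/FN/TN/FP, cols cost, qaly
}

#' Expected lifetime cost and effectiveness of a screening strategy
#'
#' Mixes the four arm outcomes by the decision-tree classification
#' fractions and adds the one-off expected screening cost: true positives
#' run the treated sarcopenia arm, false negatives the untreated sarcopenia
#' arm, true negatives the healthy arm, and false positives the healthy arm
#' with one cycle of intervention cost.
#'
#' @param strategy one row of [sarc_strategies()].
#' @param params a `sarc_params` object.
#' @param arm_outcomes optional precomputed 4 x 2 arm matrix (rows TP, FN,
#'   TN, FP; columns cost, qaly) to avoid recomputation across strategies.
#' @return list with per-person `cost` (USD), `effect` (QALYs), the
#'   classification, and the arm outcome matrix.
#' @export
evaluate_strategy <- function(strategy, params, arm_outcomes = NULL) {
  cl <- classify_cohort(strategy, params$prevalence)
  if (is.null(arm_outcomes)) arm_outcomes <- .arm_table(params)
  w <- c(TP = cl$tp, FN = cl$fn, TN = cl$tn, FP = cl$fp)
  cost <- cl$expected_screening_cost +
    sum(w * arm_outcomes[c("TP", "FN", "TN", "FP"), "cost"])
  effect <- sum(w * arm_outcomes[c("TP", "FN", "TN", "FP"), "qaly"])
  list(strategy = strategy$name, cost = cost, effect = effect,
       classification = cl, arm_outcomes = arm_outcomes)
}

#' Evaluate every strategy in the roster
#'
#' @param params a `sarc_params` object.
#' @return data frame with columns `strategy`, `cost`, `effect` (per
#'   person, discounted).
#' @export
evaluate_all_strategies <- function(params) {
  strategies <- sarc_strategies(params)
  arm_outcomes <- .arm_table(params)
  rows <- lapply(seq_len(nrow(strategies)), function(i) {
    ev <- evaluate_strategy(strategies[i, ], params, arm_outcomes)
    data.frame(strategy = ev$strategy, cost = ev$cost, effect = ev$effect,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
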