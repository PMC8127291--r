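#' Individual-level microsimulation of the screening model
#'
#' Stochastic realization of the same decision tree and Markov structure as
#' the deterministic cohort engine: each simulated person's sarcopenia
#' status is a Bernoulli draw at the prevalence, the test result a
#' Bernoulli draw at the strategy's sensitivity (or one minus specificity),
#' and every cycle's fracture event, death, and CVD transition are drawn at
#' the same per-cycle probabilities, efficacy modifiers, competing-risk
#' order, and cost/utility accounting conventions as [run_cohort()] and
#' [accumulate_outcomes()] (shared through [transition_model()] and the arm
#' conventions).  Its per-arm means therefore converge on the cohort
#' engine's values, which makes it an independent stochastic check on the
#' deterministic propagation; it also serves as the package's generator of
#' synthetic individual-level data.
#'
#' @param params a `sarc_params` object.
#' @param strategy a strategy name or one row of [sarc_strategies()].
#' @param n number of individuals (>= 1).
#' @param seed integer seed for reproducibility.
#' @param keep_paths logical; keep the per-cycle state matrix (n x horizon,
#'   state at the start of each cycle, `NA` after death).
#' @return object of class `sarc_microsim` with `individuals` (one row per
#'   person: id, true status, test result, arm, death cycle, CVD entry
#'   cycle, fracture count, at-risk person-cycles, screening cost, and
#'   discounted and undiscounted trajectory cost and QALYs), the strategy
#'   name, `seed`, and optionally `paths`.
#' @export
#' @examples
#' sim <- simulate_individuals(sarc_parameters(), "EWGSOP", n = 500, seed = 1)
#' summarize_individuals(sim)
simulate_individuals <- function(params, strategy, n, seed = NULL,
                                 keep_paths = FALSE) {
  if (!is.numeric(n) || n < 1) stop("simulate_individuals: 'n' must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  strategies <- sarc_strategies(params)
  if (is.character(strategy)) strategy <- .get_strategy(strategies, strategy)
  T <- as.integer(params$horizon_cycles)
  disc <- (1 + params$discount_rate)^(-seq_len(T))

  sarcopenic <- stats::runif(n) < params$prevalence
  p_pos <- ifelse(sarcopenic, strategy$sensitivity, 1 - strategy$specificity)
  positive <- stats::runif(n) < p_pos
  arm <- ifelse(sarcopenic, ifelse(positive, "TP", "FN"),
                ifelse(positive, "FP", "TN"))
  screening_cost <- strategy$stage1_cost + positive * strategy$stage2_cost

  tmT <- transition_model(params, treated = TRUE)
  tmU <- transition_model(params, treated = FALSE)
  treated <- arm == "TP"
  treat_cycles <- ifelse(arm == "TP", Inf, ifelse(arm == "FP", 1, 0))
  state <- ifelse(sarcopenic, .S, .H)
  alive <- rep(TRUE, n)
  cost_d <- cost_u <- qaly_d <- qaly_u <- numeric(n)
  death_cycle <- cvd_entry <- rep(NA_integer_, n)
  fractures <- integer(n)
  risk_cycles <- integer(n)
  paths <- if (keep_paths) matrix(NA_integer_, n, T) else NULL

  charge <- function(i, amount, t) {
    cost_d[i] <<- cost_d[i] + amount * disc[t]
    cost_u[i] <<- cost_u[i] + amount
  }

  for (t in seq_len(T)) {
    idx <- which(alive)
    if (!length(idx)) break
    if (keep_paths) paths[cbind(idx, t)] <- state[idx]
    s <- state[idx]
    tr <- treated[idx]
    on_treat <- t <= treat_cycles[idx]
    if (any(on_treat)) charge(idx[on_treat], params$cost_treatment_annual, t)
    in_cvd <- s == .C
    if (any(in_cvd)) charge(idx[in_cvd], params$cost_cvd_incremental, t)

    at_risk <- s != .H
    risk_cycles[idx[at_risk]] <- risk_cycles[idx[at_risk]] + 1L
    p_evt <- ifelse(tr, tmT$p_event[t], tmU$p_event[t])
    evt <- at_risk & (stats::runif(length(idx)) < p_evt)
    if (any(evt)) {
      charge(idx[evt], params$cost_fracture, t)
      fractures[idx[evt]] <- fractures[idx[evt]] + 1L
    }

    pd <- numeric(length(idx))
    pd[s == .H] <- tmU$p_death_healthy[t]
    iS <- s == .S
    pd[iS] <- ifelse(tr[iS], tmT$p_death_sarc[t], tmU$p_death_sarc[t])
    pd[in_cvd] <- ifelse(tr[in_cvd], tmT$p_death_sarc_cvd[t],
                         tmU$p_death_sarc_cvd[t])
    pd[evt] <- ifelse(tr[evt], tmT$p_death_event[t], tmU$p_death_event[t])

    u <- numeric(length(idx))
    u[s == .H] <- params$u_healthy
    u[iS] <- ifelse(evt[iS], params$u_sarc_fracture, params$u_sarc)
    u[in_cvd] <- ifelse(evt[in_cvd], params$u_sarc_cvd_fracture,
                        params$u_sarc_cvd)

    die <- stats::runif(length(idx)) < pd
    frac_alive <- ifelse(die, 0.5, 1)  # death mid-cycle: half-cycle credit
    qaly_d[idx] <- qaly_d[idx] + u * frac_alive * disc[t]
    qaly_u[idx] <- qaly_u[idx] + u * frac_alive

    to_cvd <- !die & iS &
      (stats::runif(length(idx)) < ifelse(tr, tmT$p_cvd[t], tmU$p_cvd[t]))
    if (any(to_cvd)) {
      state[idx[to_cvd]] <- .C
      cvd_entry[idx[to_cvd]] <- t
      charge(idx[to_cvd], params$cost_cvd_initial, t)
    }
    if (any(die)) {
      alive[idx[die]] <- FALSE
      death_cycle[idx[die]] <- t
      state[idx[die]] <- .D
    }
  }

  individuals <- data.frame(
    id = seq_len(n),
    true_status = ifelse(sarcopenic, "sarcopenic", "healthy"),
    test_result = ifelse(positive, "positive", "negative"),
    arm = arm,
    death_cycle = death_cycle,
    cvd_entry_cycle = cvd_entry,
    fractures = fractures,
    risk_cycles = risk_cycles,
    screening_cost = screening_cost,
    cost = cost_d, qaly = qaly_d,
    cost_undiscounted = cost_u, qaly_undiscounted = qaly_u,
    stringsAsFactors = FALSE)
  structure(list(individuals = individuals, strategy = strategy$name,
                 seed = seed, horizon = T, paths = paths),
            class = "sarc_microsim")
}

#' @export
print.sarc_microsim <- function(x, ...) {
  ind <- x$individuals
  cat("Microsimulation of strategy ", x$strategy, ": ", nrow(ind),
      " individuals, ", x$horizon, " cycles\n", sep = "")
  cat(sprintf("  mean discounted cost $%.2f (incl. screening), mean QALYs %.3f\n",
              mean(ind$cost + ind$screening_cost), mean(ind$qaly)))
  invisible(x)
}

#' Summarize simulated individuals
#'
#' Per-arm and overall means with standard errors for discounted trajectory
#' cost and QALYs, plus the empirical fracture-event rate per at-risk
#' person-cycle.  The overall row includes the screening cost, so its mean
#' cost is directly comparable with [evaluate_strategy()].
#'
#' @param sim a `sarc_microsim` object (or its `individuals` data frame).
#' @return data frame: one row per arm plus an `ALL` row, with `n`,
#'   `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`, `fracture_rate`.
#' @export
summarize_individuals <- function(sim) {
  ind <- if (inherits(sim, "sarc_microsim")) sim$individuals else sim
  if (is.null(ind) || !nrow(ind))
    stop("summarize_individuals: no individual records to summarize")
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  one <- function(label, cost, qaly, frac, risk) {
    data.frame(arm = label, n = length(cost),
               mean_cost = mean(cost), se_cost = se(cost),
               mean_qaly = mean(qaly), se_qaly = se(qaly),
               fracture_rate = if (sum(risk) > 0) sum(frac) / sum(risk)
                               else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(split(seq_len(nrow(ind)), ind$arm), function(i) {
    one(ind$arm[i[1]], ind$cost[i], ind$qaly[i],
        ind$fractures[i], ind$risk_cycles[i])
  })
  total <- one("ALL", ind$cost + ind$screening_cost, ind$qaly,
               ind$fractures, ind$risk_cycles)
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  out
}

#' Long-format per-cycle state paths
#'
#' @param sim a `sarc_microsim` object created with `keep_paths = TRUE`.
#' @return data frame (id, cycle, state) for alive person-cycles.
#' @export
microsim_paths <- function(sim) {
  if (is.null(sim$paths))
    stop("microsim_paths: simulation was run with keep_paths = FALSE")
  idx <- which(!is.na(sim$paths), arr.ind = TRUE)
  data.frame(id = idx[, 1], cycle = idx[, 2],
             state = .STATES[sim$paths[idx]], stringsAsFactors = FALSE)
}
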