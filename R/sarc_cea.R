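#' Fit the sarcopenia screening cost-effectiveness model
#'
#' Runs the full base-case evaluation: the decision tree partitions a
#' cohort of older adults by true sarcopenia status and test result for
#' each screening strategy (EWGSOP, SarSA-Mod, MSRA, SARC-F, and no
#' screening), each classification arm is propagated through the Markov
#' model over the lifetime horizon, and per-strategy discounted costs and
#' QALYs are combined into incremental cost-effectiveness tables (both a
#' common-reference table and the efficiency frontier) and net monetary
#' benefits at the willingness-to-pay threshold.
#'
#' @param params a `sarc_params` object; defaults to the base-case inputs.
#' @param reference comparator strategy for the reference-mode ICER table.
#' @param wtp willingness-to-pay threshold (USD/QALY); defaults to
#'   `params$wtp`.
#' @return an object of class `sarc_cea` with components `params`,
#'   `strategies`, `classification`, `arm_outcomes`, `results` (per-strategy
#'   cost and effect), `table_reference`, `table_frontier`, `frontier`, and
#'   `wtp`.
#' @seealso [simulate.sarc_cea()] for probabilistic sensitivity analysis,
#'   [one_way_dsa()] for tornado analysis, [simulate_individuals()] for the
#'   microsimulation check.
#' @export
#' @examples
#' fit <- sarc_cea()
#' fit
#' summary(fit)
sarc_cea <- function(params = sarc_parameters(), reference = "NoScreening",
                     wtp = params$wtp) {
  validate_parameters(params)
  strategies <- sarc_strategies(params)
  arm_outcomes <- .arm_table(params)
  results <- evaluate_all_strategies(params)
  structure(list(
    params = params,
    strategies = strategies,
    classification = classification_table(params),
    arm_outcomes = arm_outcomes,
    results = results,
    table_reference = icer_table(results, reference = reference, wtp = wtp),
    table_frontier = icer_table(results, reference = "pairwise-frontier",
                                wtp = wtp),
    frontier = cea_frontier(results),
    reference = reference,
    wtp = wtp
  ), class = "sarc_cea")
}

#' @export
print.sarc_cea <- function(x, ...) {
  cat("Sarcopenia screening cost-effectiveness model\n")
  cat(sprintf("  %d strategies | horizon %d years | discount %.1f%% | WTP $%s/QALY\n",
              nrow(x$results), as.integer(x$params$horizon_cycles),
              100 * x$params$discount_rate,
              format(x$wtp, big.mark = ",")))
  print(x$table_reference)
  front <- x$frontier$frontier$strategy
  cat("Efficiency frontier:", paste(front, collapse = " -> "), "\n")
  if (nrow(x$frontier$removed))
    cat("Removed:",
        paste(sprintf("%s (%s)", x$frontier$removed$strategy,
                      x$frontier$removed$reason), collapse = ", "), "\n")
  best <- x$results$strategy[which.max(
    net_monetary_benefit(x$results$cost, x$results$effect, x$wtp))]
  cat("Highest net monetary benefit at threshold:", best, "\n")
  invisible(x)
}

#' @export
summary.sarc_cea <- function(object, ...) {
  structure(list(fit = object), class = "summary.sarc_cea")
}

#' @export
print.summary.sarc_cea <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nDecision-tree classification (cohort fractions):\n")
  cl <- fit$classification
  cl[, 2:7] <- round(cl[, 2:7], 4)
  print.data.frame(cl, row.names = FALSE)
  cat("\nPer-arm discounted outcomes (per person):\n")
  print(round(fit$arm_outcomes, 3))
  cat("\nSequential frontier ICERs:\n")
  print(fit$table_frontier)
  invisible(x)
}

#' @export
coef.sarc_cea <- function(object, ...) {
  meta <- attr(object$params, "meta")
  vapply(meta$name, function(nm) object$params[[nm]][1], numeric(1))
}

#' Per-strategy predictions from a fitted screening model
#'
#' @param object a `sarc_cea` fit.
#' @param params optional new `sarc_params` object to re-evaluate under.
#' @param wtp optional new willingness-to-pay threshold for the NMB column.
#' @param ... unused.
#' @return data frame with `strategy`, `cost`, `effect`, `nmb`.
#' @export
predict.sarc_cea <- function(object, params = NULL, wtp = NULL, ...) {
  res <- if (is.null(params)) object$results else evaluate_all_strategies(params)
  lambda <- if (is.null(wtp)) object$wtp else wtp
  res$nmb <- net_monetary_benefit(res$cost, res$effect, lambda)
  res
}

#' Cost-effectiveness plane of a fitted screening model
#'
#' Plots each strategy on the (effectiveness, cost) plane and draws the
#' efficiency frontier through the nondominated strategies.
#'
#' @param x a `sarc_cea` fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.sarc_cea <- function(x, ...) {
  res <- x$results
  front <- x$frontier$frontier
  graphics::plot(res$effect, res$cost, pch = 19,
                 xlab = "Effectiveness (QALYs)", ylab = "Cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::lines(front$effect, front$cost, lty = 2)
  graphics::text(res$effect, res$cost, labels = res$strategy,
                 pos = 3, cex = 0.8, xpd = NA)
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted screening model
#'
#' `simulate()` on a `sarc_cea` fit draws `nsim` joint parameter sets from
#' the moment-matched uncertainty distributions and re-evaluates every
#' strategy per draw; this is the package's PSA entry point (see
#' [run_psa()] for the function interface).
#'
#' @param object a `sarc_cea` fit.
#' @param nsim number of Monte Carlo replications (default 1000).
#' @param seed integer seed for reproducibility.
#' @param ... unused.
#' @return a `sarc_psa` object.
#' @export
simulate.sarc_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  run_psa(object$params, n_iter = nsim, seed = seed, wtp = object$wtp)
}
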