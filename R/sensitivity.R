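# Domain clipping for DSA bounds: probabilities and utilities stay in
# [0, 1], costs and rates stay non-negative.
.clip_to_domain <- function(value, kind, name) {
  lo <- 0
  hi <- if (kind %in% c("probability", "utility")) 1 else Inf
  if (value < lo || value > hi) {
    warning("DSA bound for '", name, "' clipped to parameter domain")
    value <- min(max(value, lo), hi)
  }
  value
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full model with each uncertain parameter set to its low
#' and high bound while all others stay at base values.  Bounds default to
#' the printed confidence interval where one exists, otherwise base plus or
#' minus one standard deviation (clipped to the parameter's domain).  Two
#' outcome metrics are available: `"nmb_gap"`, the net monetary benefit of
#' the strategy of interest minus the best alternative's at the
#' willingness-to-pay threshold, and `"icer"`, the strategy's ICER against
#' the reference.
#'
#' @param params a `sarc_params` object.
#' @param parameters character vector of parameters to vary; defaults to
#'   every non-structural parameter with nonzero uncertainty.
#' @param outcome `"nmb_gap"` or `"icer"`.
#' @param strategy strategy whose outcome is tracked.
#' @param reference comparator for the `"icer"` outcome.
#' @param wtp willingness-to-pay threshold for the `"nmb_gap"` outcome.
#' @param ranges optional named list of `c(low, high)` overrides.
#' @return a `sarc_dsa` data frame (parameter, low, high, outcome_low,
#'   outcome_high, width) sorted by descending bar width, with the
#'   base-case outcome as attribute `base_outcome`.
#' @export
one_way_dsa <- function(params, parameters = NULL,
                        outcome = c("nmb_gap", "icer"),
                        strategy = "EWGSOP", reference = "NoScreening",
                        wtp = params$wtp, ranges = NULL) {
  outcome <- match.arg(outcome)
  meta <- attr(params, "meta")
  if (is.null(parameters)) {
    parameters <- meta$name[meta$kind != "structural" & meta$sd_used > 0]
    if (length(params$p_death_healthy) > 1L)
      parameters <- setdiff(parameters, "p_death_healthy")
  }
  eval_outcome <- function(p) {
    res <- evaluate_all_strategies(p)
    if (outcome == "nmb_gap") {
      nmb <- net_monetary_benefit(res$cost, res$effect, wtp)
      i <- match(strategy, res$strategy)
      nmb[i] - max(nmb[-i])
    } else {
      i <- match(strategy, res$strategy)
      j <- match(reference, res$strategy)
      (res$cost[i] - res$cost[j]) / (res$effect[i] - res$effect[j])
    }
  }
  base_outcome <- eval_outcome(params)
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, meta$name)
    if (is.na(i)) stop("one_way_dsa: unknown parameter '", nm, "'")
    if (!is.null(ranges[[nm]])) {
      lo <- ranges[[nm]][1]; hi <- ranges[[nm]][2]
    } else if (!is.na(meta$ci_low[i]) && !is.na(meta$ci_high[i])) {
      lo <- meta$ci_low[i]; hi <- meta$ci_high[i]
    } else {
      lo <- meta$base[i] - meta$sd_used[i]
      hi <- meta$base[i] + meta$sd_used[i]
    }
    lo <- .clip_to_domain(lo, meta$kind[i], nm)
    hi <- .clip_to_domain(hi, meta$kind[i], nm)
    p_lo <- params; p_lo[[nm]] <- lo
    p_hi <- params; p_hi[[nm]] <- hi
    data.frame(parameter = nm, low = lo, high = hi,
               outcome_low = eval_outcome(p_lo),
               outcome_high = eval_outcome(p_hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$outcome_high - out$outcome_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sarc_dsa", "data.frame")
  attr(out, "base_outcome") <- base_outcome
  attr(out, "outcome") <- outcome
  out
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param x a `sarc_dsa` object.
#' @param n_top number of widest bars to show.
#' @param ... further arguments passed to [graphics::barplot()].
#' @export
plot.sarc_dsa <- function(x, n_top = min(10L, nrow(x)), ...) {
  y <- x[seq_len(n_top), , drop = FALSE]
  y <- y[rev(seq_len(nrow(y))), ]
  base <- attr(x, "base_outcome")
  lo <- pmin(y$outcome_low, y$outcome_high) - base
  hi <- pmax(y$outcome_low, y$outcome_high) - base
  old <- graphics::par(mar = c(4, 11, 3, 1)); on.exit(graphics::par(old))
  bp <- graphics::barplot(hi, horiz = TRUE, names.arg = y$parameter,
                          las = 1, xlim = range(c(lo, hi, 0)) * 1.1,
                          col = "steelblue",
                          main = "One-way sensitivity (tornado)",
                          xlab = paste0("Change in ", attr(x, "outcome"),
                                        " from base case"), ...)
  graphics::barplot(lo, horiz = TRUE, add = TRUE, col = "indianred",
                    axes = FALSE)
  graphics::abline(v = 0)
  invisible(bp)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo evaluation of parameter uncertainty: each iteration draws
#' one joint parameter set from the moment-matched marginal distributions
#' (independently across parameters) and evaluates the lifetime cost and
#' effectiveness of every strategy.  Draws that fail model construction
#' (a transition probability outside \[0, 1\]) are rejected and resampled,
#' preserving the stated marginals; the rejection count is reported.
#'
#' @param params base `sarc_params` object.
#' @param n_iter number of sampling replications (default 1000).
#' @param seed integer seed; the whole run is reproducible given the seed.
#' @param wtp willingness-to-pay threshold carried into reporting.
#' @return object of class `sarc_psa`: matrices `cost` and `effect`
#'   (`n_iter` rows, one column per strategy), the sampled parameter
#'   `draws` data frame, `rejections`, `n_iter`, `seed`, `wtp`.
#' @export
run_psa <- function(params, n_iter = 1000, seed = NULL, wtp = params$wtp) {
  if (!is.numeric(n_iter) || n_iter < 1)
    stop("run_psa: 'n_iter' must be >= 1")
  n_iter <- as.integer(n_iter)
  if (!is.null(seed)) set.seed(seed)
  strategies <- sarc_strategies(params)$name
  meta <- attr(params, "meta")
  sampled_names <- meta$name[meta$family != "fixed" & meta$sd_used > 0]
  cost <- effect <- matrix(NA_real_, n_iter, length(strategies),
                           dimnames = list(NULL, strategies))
  draws <- matrix(NA_real_, n_iter, length(sampled_names),
                  dimnames = list(NULL, sampled_names))
  rejections <- 0L
  for (it in seq_len(n_iter)) {
    for (attempt in seq_len(100L)) {
      p <- sample_parameter_set(params)
      res <- tryCatch(evaluate_all_strategies(p), error = function(e) NULL)
      if (!is.null(res)) break
      rejections <- rejections + 1L
    }
    if (is.null(res))
      stop("run_psa: could not draw a feasible parameter set in 100 attempts")
    draws[it, ] <- vapply(sampled_names, function(nm) p[[nm]][1], numeric(1))
    m <- match(strategies, res$strategy)
    cost[it, ] <- res$cost[m]
    effect[it, ] <- res$effect[m]
  }
  structure(list(cost = cost, effect = effect,
                 draws = as.data.frame(draws), n_iter = n_iter,
                 seed = seed, rejections = rejections, wtp = wtp,
                 params = params),
            class = "sarc_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value in `lambda_grid`, the probability that
#' a strategy is optimal is the fraction of PSA iterations in which it has
#' the strictly highest net monetary benefit; exact ties split the
#' iteration's mass equally among the tied strategies, so the
#' probabilities sum to one at every threshold.
#'
#' @param psa a `sarc_psa` object.
#' @param lambda_grid willingness-to-pay grid (USD/QALY); defaults to 0 up
#'   to three times the threshold stored in the PSA, in 101 points.
#' @return matrix (`length(lambda_grid)` x strategies) of probabilities,
#'   with the grid as attribute `lambda` and row names.
#' @export
ceac <- function(psa, lambda_grid = NULL) {
  if (is.null(lambda_grid))
    lambda_grid <- seq(0, 3 * psa$wtp, length.out = 101L)
  if (!length(lambda_grid)) stop("ceac: 'lambda_grid' must be non-empty")
  n <- nrow(psa$cost)
  k <- ncol(psa$cost)
  out <- matrix(0, length(lambda_grid), k,
                dimnames = list(signif(lambda_grid, 8), colnames(psa$cost)))
  for (g in seq_along(lambda_grid)) {
    nmb <- lambda_grid[g] * psa$effect - psa$cost
    best <- nmb == .row_maxs(nmb)
    out[g, ] <- colSums(best / rowSums(best)) / n
  }
  attr(out, "lambda") <- lambda_grid
  out
}

# Row maxima without extra dependencies.
.row_maxs <- function(m) do.call(pmax, as.data.frame(m))

#' Strategy-selection probabilities at a single threshold
#'
#' The cost-effectiveness acceptability curve evaluated at one
#' willingness-to-pay value: the probability, over the PSA draws, that each
#' strategy has the highest net monetary benefit.
#'
#' @param psa a `sarc_psa` object.
#' @param wtp willingness-to-pay threshold (USD/QALY); defaults to the one
#'   stored in the PSA.
#' @return named probability vector summing to one.
#' @export
selection_probabilities <- function(psa, wtp = psa$wtp) {
  drop(ceac(psa, lambda_grid = wtp))
}

#' @export
print.sarc_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", x$n_iter,
      " replications", if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"),
      "\n", sep = "")
  if (x$rejections > 0)
    cat("  rejected and resampled draws:", x$rejections, "\n")
  p <- selection_probabilities(x)
  cat(sprintf("  selection probabilities at WTP $%s/QALY:\n",
              format(x$wtp, big.mark = ",")))
  print(round(p, 3))
  invisible(x)
}

#' Plot a probabilistic sensitivity analysis
#'
#' `type = "ceac"` draws the cost-effectiveness acceptability curves;
#' `type = "plane"` scatters the incremental (effect, cost) draws of each
#' strategy against the comparator.
#'
#' @param x a `sarc_psa` object.
#' @param type `"ceac"` or `"plane"`.
#' @param reference comparator strategy for the incremental plane.
#' @param ... further graphical arguments.
#' @export
plot.sarc_psa <- function(x, type = c("ceac", "plane"),
                          reference = "NoScreening", ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    cc <- ceac(x)
    lambda <- attr(cc, "lambda")
    graphics::matplot(lambda, cc, type = "l", lty = 1, lwd = 2,
                      xlab = "Willingness to pay (USD/QALY)",
                      ylab = "Probability cost-effective",
                      main = "Cost-effectiveness acceptability curves",
                      ylim = c(0, 1), ...)
    graphics::abline(v = x$wtp, lty = 3)
    graphics::legend("right", legend = colnames(cc), col = seq_len(ncol(cc)),
                     lty = 1, lwd = 2, bty = "n", cex = 0.8)
  } else {
    j <- match(reference, colnames(x$cost))
    if (is.na(j)) stop("plot.sarc_psa: unknown reference '", reference, "'")
    de <- x$effect[, -j, drop = FALSE] - x$effect[, j]
    dc <- x$cost[, -j, drop = FALSE] - x$cost[, j]
    graphics::matplot(de, dc, pch = 20, cex = 0.5,
                      xlab = paste("Incremental QALYs vs", reference),
                      ylab = paste("Incremental cost (USD) vs", reference),
                      main = "Incremental cost-effectiveness scatter", ...)
    graphics::abline(h = 0, v = 0, lty = 3)
    graphics::abline(a = 0, b = x$wtp, lty = 2)
    graphics::legend("topleft", legend = colnames(de),
                     col = seq_len(ncol(de)), pch = 20, bty = "n", cex = 0.8)
  }
  invisible(x)
}
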