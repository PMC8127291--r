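#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`: the monetary value of a strategy's health
#' gain at willingness-to-pay `wtp`, net of its cost.  Ranking strategies by
#' NMB at a threshold is equivalent to the ICER decision rule.
#'
#' @param cost cost in USD (vectorized).
#' @param effect effectiveness in QALYs.
#' @param wtp willingness-to-pay threshold in USD/QALY.
#' @return net monetary benefit in USD.
#' @export
#' @examples
#' net_monetary_benefit(3518.75, 8.50, 5520.311)
net_monetary_benefit <- function(cost, effect, wtp) {
  stopifnot(is.finite(wtp))
  wtp * effect - cost
}

# Weak-dominance pass: a strategy is dominated if some other strategy is no
# more costly and no less effective, with at least one strict inequality.
# Equal (cost, effect) pairs are ties: the first listed is kept.
.dominated_weak <- function(cost, effect) {
  n <- length(cost)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (j == i) return(FALSE)
      leq_cost <- cost[j] <= cost[i]
      geq_eff <- effect[j] >= effect[i]
      strict <- cost[j] < cost[i] || effect[j] > effect[i]
      tie <- cost[j] == cost[i] && effect[j] == effect[i]
      (leq_cost && geq_eff && strict) || (tie && j < i)
    }, logical(1)))
  }, logical(1))
}

#' Cost-effectiveness efficiency frontier
#'
#' Identifies the nondominated strategies: first strategies that are weakly
#' dominated (another option costs no more and is at least as effective) are
#' removed, then extendedly dominated ones (bypassed by a convex combination
#' of a cheaper and a pricier strategy with a lower blended ICER, i.e. a
#' strategy whose incoming sequential ICER strictly exceeds its outgoing
#' one).  The surviving set is the lower-right convex hull of the
#' (effect, cost) cloud.  Collinear points (equal sequential ICERs) are
#' retained: they are not *strictly* extendedly dominated.
#'
#' @param results data frame with columns `strategy`, `cost`, `effect`.
#' @return list with `frontier` (kept rows, ordered by ascending cost, with
#'   sequential `icer`) and `removed` (data frame of strategy and removal
#'   reason: `"dominated"` or `"extendedly_dominated"`).
#' @export
#' @examples
#' res <- data.frame(strategy = c("A", "B", "C"),
#'                   cost = c(0, 10, 12), effect = c(0, 1, 2))
#' cea_frontier(res)$frontier$strategy  # "A", "C": B extendedly dominated
cea_frontier <- function(results) {
  stopifnot(nrow(results) >= 1,
            all(c("strategy", "cost", "effect") %in% names(results)))
  res <- results[order(results$cost, -results$effect), , drop = FALSE]
  removed <- data.frame(strategy = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  dom <- .dominated_weak(res$cost, res$effect)
  if (any(dom))
    removed <- rbind(removed, data.frame(strategy = res$strategy[dom],
                                         reason = "dominated",
                                         stringsAsFactors = FALSE))
  keep <- res[!dom, , drop = FALSE]
  repeat {
    if (nrow(keep) < 3L) break
    icer <- diff(keep$cost) / diff(keep$effect)
    # interior strategy k has incoming icer[k-1] and outgoing icer[k]
    ext <- which(icer[-length(icer)] > icer[-1L]) + 1L
    if (!length(ext)) break
    drop_i <- ext[1L]
    removed <- rbind(removed,
                     data.frame(strategy = keep$strategy[drop_i],
                                reason = "extendedly_dominated",
                                stringsAsFactors = FALSE))
    keep <- keep[-drop_i, , drop = FALSE]
  }
  icer <- c(NA_real_, diff(keep$cost) / diff(keep$effect))
  keep$icer <- icer
  rownames(keep) <- NULL
  list(frontier = keep, removed = removed)
}

#' Incremental cost-effectiveness table
#'
#' Two conventions are supported.  In `"reference"` mode every strategy's
#' incremental cost, incremental effect, and ICER are computed against a
#' single comparator (the usual presentation when no-screening is the
#' baseline).  In `"frontier"` mode dominated and extendedly dominated
#' strategies are removed and ICERs are sequential along the efficiency
#' frontier.  Both modes report the dominance status of every strategy and
#' its net monetary benefit at `wtp`.
#'
#' @param results data frame with columns `strategy`, `cost`, `effect`.
#' @param reference comparator strategy name, or `"pairwise-frontier"` for
#'   frontier mode.
#' @param wtp willingness-to-pay threshold (USD/QALY) for the NMB column.
#' @return a `cea_table` data frame sorted by ascending cost with columns
#'   `strategy`, `cost`, `incr_cost`, `effect`, `incr_effect`, `icer`,
#'   `dominance`, `nmb`.  A zero incremental effect with positive
#'   incremental cost leaves `icer` as `NA` (flagged dominated) rather than
#'   dividing by zero.
#' @export
icer_table <- function(results, reference = "NoScreening", wtp) {
  stopifnot(nrow(results) >= 2,
            all(is.finite(results$cost)), all(is.finite(results$effect)))
  res <- results[order(results$cost, -results$effect), , drop = FALSE]
  rownames(res) <- NULL
  fr <- cea_frontier(res)
  status <- rep("nondominated", nrow(res))
  m <- match(res$strategy, fr$removed$strategy)
  status[!is.na(m)] <- fr$removed$reason[m[!is.na(m)]]
  if (identical(reference, "pairwise-frontier")) {
    on_front <- match(res$strategy, fr$frontier$strategy)
    icer <- fr$frontier$icer[on_front]
    prev <- c(NA, fr$frontier$strategy[-nrow(fr$frontier)])[on_front]
    pi <- match(prev, res$strategy)
    incr_cost <- res$cost - res$cost[pi]
    incr_effect <- res$effect - res$effect[pi]
  } else {
    ri <- match(reference, res$strategy)
    if (is.na(ri)) stop("icer_table: reference strategy '", reference,
                        "' not among results")
    incr_cost <- res$cost - res$cost[ri]
    incr_effect <- res$effect - res$effect[ri]
    icer <- ifelse(incr_effect != 0, incr_cost / incr_effect, NA_real_)
    icer[ri] <- NA_real_
    tie <- incr_effect == 0 & incr_cost == 0 & seq_len(nrow(res)) != ri
    status[incr_effect == 0 & incr_cost > 0] <- "dominated"
    status[tie] <- "tie"
  }
  out <- data.frame(strategy = res$strategy, cost = res$cost,
                    incr_cost = incr_cost, effect = res$effect,
                    incr_effect = incr_effect, icer = icer,
                    dominance = status,
                    nmb = net_monetary_benefit(res$cost, res$effect, wtp),
                    stringsAsFactors = FALSE)
  class(out) <- c("cea_table", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "wtp") <- wtp
  out
}

#' @export
print.cea_table <- function(x, ...) {
  mode <- if (identical(attr(x, "reference"), "pairwise-frontier"))
    "sequential frontier ICERs" else paste0("ICER vs ", attr(x, "reference"))
  cat("Cost-effectiveness table (", mode, ", WTP $",
      format(attr(x, "wtp"), big.mark = ","), "/QALY)\n", sep = "")
  y <- as.data.frame(x)
  y$cost <- round(y$cost, 2); y$incr_cost <- round(y$incr_cost, 2)
  y$effect <- round(y$effect, 3); y$incr_effect <- round(y$incr_effect, 3)
  y$icer <- round(y$icer, 2); y$nmb <- round(y$nmb, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
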