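#' Screening strategy definitions
#'
#' Builds the roster of compared strategies from a parameter set.  Each
#' strategy is reduced to its test operating characteristics and staged
#' costs: a stage-1 cost paid by everyone screened and a stage-2 cost paid
#' by screen-positives (confirmatory DXA for the two-stage EWGSOP algorithm;
#' the supplementary assessment of high-risk individuals for SARC-F; zero
#' for the single-stage SarSA-Mod and MSRA questionnaires).  `NoScreening`
#' is the null strategy: sensitivity 0, specificity 1, no costs — nobody is
#' labelled positive and nobody pays.
#'
#' @param params a `sarc_params` object.
#' @return data frame with columns `name`, `sensitivity`, `specificity`,
#'   `stage1_cost`, `stage2_cost`, one row per strategy.
#' @export
#' @examples
#' sarc_strategies(sarc_parameters())
sarc_strategies <- function(params) {
  data.frame(
    name = c("EWGSOP", "SarSA-Mod", "MSRA", "SARC-F", "NoScreening"),
    sensitivity = c(params$sens_ewgsop, params$sens_sarsamod,
                    params$sens_msra, params$sens_sarcf, 0),
    specificity = c(params$spec_ewgsop, params$spec_sarsamod,
                    params$spec_msra, params$spec_sarcf, 1),
    stage1_cost = c(params$cost_ewgsop_stage1, params$cost_sarsamod,
                    params$cost_msra, params$cost_sarcf, 0),
    stage2_cost = c(params$cost_ewgsop_stage2, 0, 0,
                    params$cost_sarcf_highrisk, 0),
    stringsAsFactors = FALSE
  )
}

.get_strategy <- function(strategies, name) {
  i <- match(name, strategies$name)
  if (is.na(i)) stop("unknown strategy '", name, "'")
  strategies[i, , drop = FALSE]
}

#' Partition a screened cohort by true status and test result
#'
#' The decision tree splits the population by sarcopenia prevalence, then by
#' the test outcome, into true positives, false negatives, false positives
#' and true negatives.
#'
#' @param strategy one row of [sarc_strategies()] (or any list with
#'   `sensitivity`, `specificity`, `stage1_cost`, `stage2_cost`).
#' @param prevalence sarcopenia prevalence in \[0, 1\].
#' @return named list with cohort fractions `tp`, `fn`, `fp`, `tn`, the
#'   overall `positive_rate`, and `expected_screening_cost` per person.
#' @export
#' @examples
#' s <- sarc_strategies(sarc_parameters())
#' classify_cohort(s[s$name == "EWGSOP", ], prevalence = 0.245)
classify_cohort <- function(strategy, prevalence) {
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("classify_cohort: 'prevalence' must lie in [0, 1]")
  sens <- strategy$sensitivity
  spec <- strategy$specificity
  tp <- prevalence * sens
  fn <- prevalence * (1 - sens)
  fp <- (1 - prevalence) * (1 - spec)
  tn <- (1 - prevalence) * spec
  res <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              positive_rate = tp + fp)
  res$expected_screening_cost <- screening_cost(strategy, res)
  res
}

#' Expected per-person screening cost of a strategy
#'
#' Stage-1 cost is paid by everyone screened; stage-2 cost only by
#' screen-positives.  Screening happens once, before the first model cycle,
#' and is therefore undiscounted.
#'
#' @param strategy strategy definition (see [classify_cohort()]).
#' @param classification result of [classify_cohort()] for this strategy.
#' @return expected screening cost in USD per person.
#' @export
screening_cost <- function(strategy, classification) {
  strategy$stage1_cost + classification$positive_rate * strategy$stage2_cost
}

#' Classification table for all strategies
#'
#' @param params a `sarc_params` object.
#' @return data frame: one row per strategy with tp/fn/fp/tn fractions,
#'   positive rate and expected per-person screening cost.
#' @export
classification_table <- function(params) {
  strategies <- sarc_strategies(params)
  rows <- lapply(seq_len(nrow(strategies)), function(i) {
    cl <- classify_cohort(strategies[i, ], params$prevalence)
    data.frame(strategy = strategies$name[i], tp = cl$tp, fn = cl$fn,
               fp = cl$fp, tn = cl$tn, positive_rate = cl$positive_rate,
               screening_cost = cl$expected_screening_cost,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
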