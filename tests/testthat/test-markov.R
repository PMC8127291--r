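test_that("transition layer combines falls, fractures, efficacy and excess mortality", {
  p <- const_params()
  un <- transition_model(p, treated = FALSE)
  tr <- transition_model(p, treated = TRUE)

  expect_equal(un$p_event[1], 0.273 * 0.40)       # 0.1092
  expect_equal(tr$p_event[1], 0.273 * 0.6 * 0.40) # treated fall prob 0.1638
  expect_equal(un$p_cvd[1], 0.27)
  expect_equal(tr$p_cvd[1], 0.27 * 0.6)
  expect_equal(un$p_death_sarc[1], 0.132)
  # treated mortality scales only the excess above healthy mortality
  expect_equal(tr$p_death_sarc[1], 0.09 + 0.6 * (0.132 - 0.09))
  expect_equal(tr$p_death_sarc_cvd[1], 0.09 + 0.6 * (0.198 - 0.09))

  # full efficacy removes all excess risk: treated death = healthy death
  pf <- const_params(efficacy = 1)
  trf <- transition_model(pf, treated = TRUE)
  expect_equal(trf$p_death_sarc, trf$p_death_healthy)
  expect_equal(trf$p_cvd[1], 0)
  expect_equal(trf$p_event[1], 0)

  expect_error(transition_model(const_params(p_fall = 1, p_fracture_given_fall = 1,
                                             p_death_fracture = 0)),
               NA)  # boundary probabilities are admissible
})

test_that("degenerate cohorts reproduce hand-computed QALY totals", {
  # everyone dies in cycle 1: half-cycle credit at the sarcopenia utility
  p1 <- const_params(p_death_sarc = 1, p_fall = 0, p_cvd = 0,
                     discount_rate = 0)
  expect_equal(unname(evaluate_arm(p1, "FN")["qaly"]), 0.68 * 0.5)

  # immortal healthy cohort: utility times horizon
  p2 <- const_params(p_death_healthy = 0, discount_rate = 0)
  expect_equal(unname(evaluate_arm(p2, "TN")["qaly"]), 0.76 * 25)

  # all-dead beyond the first cycle accrues nothing further
  tr1 <- run_cohort(transition_model(p1), "FN", p1)
  expect_equal(unname(tr1$occupancy[nrow(tr1$occupancy), "DEAD"]),
               p1$cohort_size)
})

test_that("constant-hazard no-event survival matches the closed-form geometric sum", {
  p <- const_params(discount_rate = 0.05)
  # healthy arm is the no-event constant-hazard limit: s = 1 - 0.09
  got <- unname(evaluate_arm(p, "TN")["qaly"])
  s <- 1 - 0.09; u <- 0.76; d <- 0.05; T <- 25
  t <- seq_len(T)
  closed_form <- u * sum((s^(t - 1) + s^t) / 2 * (1 + d)^(-t))
  expect_equal(got, closed_form, tolerance = 1e-10)
})

test_that("cost accounting follows the arm conventions", {
  p <- const_params(discount_rate = 0)
  # false positives pay exactly one intervention cycle more than true negatives
  fp <- evaluate_arm(p, "FP"); tn <- evaluate_arm(p, "TN")
  expect_equal(unname(fp["cost"] - tn["cost"]), 1119.048, tolerance = 1e-9)
  expect_equal(unname(fp["qaly"] - tn["qaly"]), 0)
  # discounted variant: the single cycle-1 charge carries one discount factor
  pd <- const_params(discount_rate = 0.05)
  fp_d <- evaluate_arm(pd, "FP"); tn_d <- evaluate_arm(pd, "TN")
  expect_equal(unname(fp_d["cost"] - tn_d["cost"]), 1119.048 / 1.05,
               tolerance = 1e-9)

  # CVD tunnel: entry cost once, incremental cost each later CVD cycle
  pc <- const_params(horizon_cycles = 3, p_cvd = 1, p_fall = 0,
                     p_death_sarc = 0, p_death_sarc_cvd = 0,
                     p_death_healthy = 0, discount_rate = 0,
                     cost_treatment_annual = 0)
  out <- evaluate_arm(pc, "FN")
  expect_equal(unname(out["cost"]), 4149.286 + 2 * 1904.762, tolerance = 1e-9)
  expect_equal(unname(out["qaly"]), 0.68 + 2 * 0.56, tolerance = 1e-9)
})

test_that("occupancy mass is conserved and death is absorbing in every arm", {
  for (make in list(base_params, const_params)) {
    p <- make()
    for (arm in c("TP", "FN", "TN", "FP")) {
      tm <- transition_model(p, treated = (arm == "TP"))
      tr <- run_cohort(tm, arm, p)
      expect_equal(unname(rowSums(tr$occupancy)),
                   rep(p$cohort_size, p$horizon_cycles + 1),
                   tolerance = 1e-9)
      expect_true(all(diff(tr$occupancy[, "DEAD"]) >= -1e-12))
      expect_true(all(tr$occupancy >= -1e-12))
    }
  }
})

test_that("outcomes respond monotonically to mortality, efficacy and discounting", {
  q_at <- function(pd) unname(evaluate_arm(const_params(p_death_sarc = pd),
                                           "FN")["qaly"])
  grid <- seq(0.05, 0.9, by = 0.2)
  expect_true(all(diff(vapply(grid, q_at, numeric(1))) < 0))

  eff_at <- function(e) {
    res <- evaluate_all_strategies(base_params(efficacy = e))
    res$effect[res$strategy == "EWGSOP"]
  }
  expect_true(all(diff(vapply(c(0, 0.25, 0.5, 0.75, 1), eff_at,
                              numeric(1))) > 0))

  totals <- function(d) {
    p <- base_params(discount_rate = d)
    sapply(c("TP", "FN", "TN", "FP"), function(a) evaluate_arm(p, a))
  }
  t0 <- totals(0); t05 <- totals(0.05); t12 <- totals(0.12)
  expect_true(all(t0 >= t05 - 1e-12))
  expect_true(all(t05 >= t12 - 1e-12))
})

test_that("strategy-level effectiveness follows test sensitivity and treatment benefit", {
  p <- base_params()
  res <- evaluate_all_strategies(p)
  eff <- setNames(res$effect, res$strategy)
  # detection-driven ordering of lifetime QALYs
  expect_true(eff["EWGSOP"] >= eff["SarSA-Mod"])
  expect_true(abs(eff["SarSA-Mod"] - eff["MSRA"]) < 0.01)
  expect_true(eff["MSRA"] >= eff["SARC-F"])
  expect_true(eff["SARC-F"] >= eff["NoScreening"])
  expect_true(eff["EWGSOP"] > eff["NoScreening"])

  cost <- setNames(res$cost, res$strategy)
  expect_true(cost["NoScreening"] < cost["SARC-F"])
  expect_true(cost["SARC-F"] < cost["SarSA-Mod"])
  expect_true(cost["SarSA-Mod"] < cost["MSRA"])
  expect_true(cost["MSRA"] < cost["EWGSOP"])

  # a perfect costless test with zero efficacy changes nothing vs no screening
  p0 <- base_params(efficacy = 0, cost_treatment_annual = 0)
  perfect <- data.frame(name = "Perfect", sensitivity = 1, specificity = 1,
                        stage1_cost = 0, stage2_cost = 0,
                        stringsAsFactors = FALSE)
  noscr <- sarc_strategies(p0)
  ev_p <- evaluate_strategy(perfect, p0)
  ev_n <- evaluate_strategy(noscr[noscr$name == "NoScreening", ], p0)
  expect_equal(ev_p$cost, ev_n$cost, tolerance = 1e-10)
  expect_equal(ev_p$effect, ev_n$effect, tolerance = 1e-10)
})

test_that("the fitted model object exposes the standard methods coherently", {
  fit <- sarc_cea(const_params())
  expect_s3_class(fit, "sarc_cea")
  expect_equal(nrow(fit$results), 5L)
  expect_named(coef(fit)["prevalence"], "prevalence")
  pr <- predict(fit)
  expect_equal(pr$nmb, fit$wtp * pr$effect - pr$cost, tolerance = 1e-12)
  expect_output(print(fit), "Efficiency frontier")
  expect_output(print(summary(fit)), "Per-arm discounted outcomes")
  # predict under modified parameters re-evaluates the model
  pr2 <- predict(fit, params = const_params(efficacy = 0.8))
  expect_true(pr2$effect[pr2$strategy == "EWGSOP"] >
              pr$effect[pr$strategy == "EWGSOP"])
})
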