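test_that("tornado bars equal two independent full-model evaluations", {
  p <- const_params()
  dsa <- one_way_dsa(p, parameters = c("prevalence", "discount_rate"),
                     ranges = list(prevalence = c(0.165, 0.325)))
  row <- dsa[dsa$parameter == "prevalence", ]
  expect_equal(row$low, 0.165)
  expect_equal(row$high, 0.325)

  # oracle: recompute the outcome by two direct model calls
  oracle <- function(prev) {
    res <- evaluate_all_strategies(const_params(prevalence = prev))
    nmb <- net_monetary_benefit(res$cost, res$effect, p$wtp)
    i <- match("EWGSOP", res$strategy)
    nmb[i] - max(nmb[-i])
  }
  expect_equal(row$outcome_low, oracle(0.165), tolerance = 1e-10)
  expect_equal(row$outcome_high, oracle(0.325), tolerance = 1e-10)
  expect_equal(row$width, abs(oracle(0.325) - oracle(0.165)),
               tolerance = 1e-10)

  # bars are sorted by descending width
  full <- one_way_dsa(p)
  expect_true(all(diff(full$width) <= 1e-12))
})

test_that("tornado handles degenerate and clipped ranges", {
  p <- const_params()
  z <- one_way_dsa(p, parameters = "p_fall",
                   ranges = list(p_fall = c(0.273, 0.273)))
  expect_equal(z$width, 0)
  expect_warning(
    one_way_dsa(p, parameters = "u_healthy",
                ranges = list(u_healthy = c(0.9, 1.4))),
    "clipped")
})

test_that("discount-rate bounds span the printed interval and richer futures score higher", {
  p <- const_params()
  dsa <- one_way_dsa(p, parameters = "discount_rate")
  expect_equal(dsa$low, 0.03)
  expect_equal(dsa$high, 0.12)
  eff <- function(d) {
    res <- evaluate_all_strategies(const_params(discount_rate = d))
    res$effect[res$strategy == "EWGSOP"]
  }
  expect_gt(eff(0.03), eff(0.12))
})

test_that("PSA is reproducible under a fixed seed and degenerates to the base case", {
  p <- const_params()
  a <- run_psa(p, n_iter = 30, seed = 7)
  b <- run_psa(p, n_iter = 30, seed = 7)
  expect_identical(a$cost, b$cost)
  expect_identical(a$effect, b$effect)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(p, n_iter = 30, seed = 8)
  expect_false(identical(a$cost, c2$cost))
  expect_equal(a$rejections, 0L)

  # degenerate limit: zero spread reproduces the base case in every draw
  p0 <- p
  meta <- attr(p0, "meta"); meta$sd_used[] <- 0
  attr(p0, "meta") <- meta
  d <- run_psa(p0, n_iter = 3, seed = 1)
  base <- evaluate_all_strategies(p)
  for (it in 1:3) {
    expect_equal(unname(d$cost[it, ]), base$cost, tolerance = 1e-12)
    expect_equal(unname(d$effect[it, ]), base$effect, tolerance = 1e-12)
  }
  sel <- selection_probabilities(d)
  nmb <- net_monetary_benefit(base$cost, base$effect, p$wtp)
  expect_equal(unname(sel[base$strategy[which.max(nmb)]]), 1)
})

test_that("CEAC is a proper probability partition with the correct threshold limits", {
  psa <- run_psa(const_params(), n_iter = 120, seed = 21)
  cc <- ceac(psa)
  expect_true(all(cc >= 0 & cc <= 1))
  expect_equal(unname(rowSums(cc)), rep(1, nrow(cc)), tolerance = 1e-12)

  # lambda = 0: NMB = -cost, so the cheapest strategy always wins
  at0 <- drop(ceac(psa, lambda_grid = 0))
  cheapest <- colnames(psa$cost)[apply(psa$cost, 1, which.min)]
  expect_equal(unname(at0["NoScreening"]), mean(cheapest == "NoScreening"))
  expect_gt(at0[["NoScreening"]], 0.99)

  # lambda -> infinity: the most effective strategy wins (EWGSOP detects all)
  atInf <- drop(ceac(psa, lambda_grid = 1e9))
  expect_gt(atInf[["EWGSOP"]], 0.99)

  expect_error(ceac(psa, lambda_grid = numeric(0)), "non-empty")
})

test_that("selection probabilities are the CEAC at one threshold and split exact ties", {
  psa <- run_psa(const_params(), n_iter = 60, seed = 3)
  sel <- selection_probabilities(psa)
  cc <- ceac(psa, lambda_grid = psa$wtp)
  expect_equal(unname(sel), unname(drop(cc)), tolerance = 1e-15)
  expect_equal(sum(sel), 1, tolerance = 1e-12)

  # two indistinguishable strategies share their winning mass equally
  fake <- structure(list(
    cost = cbind(A = c(1, 1), B = c(1, 1), C = c(5, 0.5)),
    effect = cbind(A = c(1, 1), B = c(1, 1), C = c(1, 1)),
    n_iter = 2L, seed = NULL, rejections = 0L, wtp = 10), class = "sarc_psa")
  s <- selection_probabilities(fake)
  expect_equal(unname(s["A"]), unname(s["B"]))
  expect_equal(unname(s["A"] + s["B"] + s["C"]), 1)
  expect_equal(unname(s["C"]), 0.5)  # C wins iteration 2 outright
})

test_that("PSA mean outcomes agree with an independent replication at another seed", {
  p <- const_params()
  psa <- run_psa(p, n_iter = 400, seed = 5)
  oracle <- run_psa(p, n_iter = 400, seed = 1005)
  for (s in colnames(psa$cost)) {
    se <- sd(psa$cost[, s]) / sqrt(nrow(psa$cost))
    se_o <- sd(oracle$cost[, s]) / sqrt(nrow(oracle$cost))
    z <- (mean(psa$cost[, s]) - mean(oracle$cost[, s])) /
      sqrt(se^2 + se_o^2)
    expect_lt(abs(z), 4)
  }
})
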