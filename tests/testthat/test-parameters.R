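test_that("base parameter set reproduces the canonical inputs and validation names offenders", {
  p <- base_params()
  expect_equal(p$prevalence, 0.245)
  expect_equal(p$discount_rate, 0.05)
  expect_equal(p$wtp, 5520.311)
  expect_equal(p$cost_treatment_annual, 1119.048)
  expect_equal(as.integer(p$horizon_cycles), 25L)
  expect_equal(p$sens_ewgsop, 1)

  expect_error(sarc_parameters(u_sarc = 1.2), "u_sarc")
  expect_error(sarc_parameters(cost_dxa = -1), "cost_dxa")
  expect_error(sarc_parameters(nonexistent = 1), "unknown parameter")
  expect_error(sarc_parameters(u_sarc_cvd_fracture = 0.6), "u_sarc_cvd_fracture")

  # EWGSOP sensitivity of exactly 1 admits no Beta distribution: held fixed
  meta <- attr(p, "meta")
  expect_identical(meta$family[meta$name == "sens_ewgsop"], "fixed")
  expect_equal(meta$sd_used[meta$name == "sens_ewgsop"], 0)
})

test_that("default-SD rule is a fraction of the mean, restricted to the 10-15% band", {
  expect_equal(default_sd(1119.048, 0.125), 139.881)
  expect_equal(default_sd(0), 0)
  expect_equal(default_sd(0.27, 0.10), 0.027)
  expect_error(default_sd(1, 0.2), "fraction")
  expect_error(default_sd(1, 0.05), "fraction")

  # CI-to-SD fallback uses the normal approximation (width / (2 * 1.96))
  meta <- attr(base_params(), "meta")
  expect_equal(meta$sd_used[meta$name == "sens_sarsamod"],
               (0.842 - 0.767) / (2 * 1.96))
  # no printed uncertainty at all -> default rule at the 12.5% midpoint
  expect_equal(meta$sd_used[meta$name == "u_healthy"], 0.125 * 0.76)
  expect_true("u_healthy" %in% attr(base_params(), "defaults_applied"))
})

test_that("moment-matched Beta/Gamma fits reproduce their target moments", {
  # hand-checkable cases
  expect_equal(unname(fit_beta_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  ab <- fit_beta_moments(0.245, 0.08)
  expect_equal(unname(ab), c(6.836074, 21.066270), tolerance = 1e-6)
  gs <- fit_gamma_moments(1119.048, 119.047)
  expect_equal(unname(gs), c(88.360979, 12.664504), tolerance = 1e-6)
  gs2 <- fit_gamma_moments(3599.048, 695.074)
  expect_equal(unname(gs2), c(26.811011, 134.237683), tolerance = 1e-6)
  expect_equal(unname(fit_gamma_moments(5, 5)["shape"]), 1)

  expect_error(fit_beta_moments(0.5, 0.6), "infeasible")
  expect_error(fit_beta_moments(1, 0.1), "mean")
  expect_error(fit_gamma_moments(-1, 1), "mean")

  # property: analytic moments of the fitted law equal the inputs to 1e-9
  set.seed(4)
  for (i in 1:50) {
    m <- runif(1, 0.02, 0.98)
    s <- runif(1, 0.01, 0.95) * sqrt(m * (1 - m))
    ab <- fit_beta_moments(m, s)
    a <- ab[["shape1"]]; b <- ab[["shape2"]]
    expect_equal(a / (a + b), m, tolerance = 1e-9)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), s, tolerance = 1e-9)
    mg <- runif(1, 0.1, 5000); sg <- runif(1, 0.01, 2) * mg
    gs <- fit_gamma_moments(mg, sg)
    expect_equal(gs[["shape"]] * gs[["scale"]], mg, tolerance = 1e-9)
    expect_equal(sqrt(gs[["shape"]]) * gs[["scale"]], sg, tolerance = 1e-9)
  }

  # Monte Carlo confirmation that draws realize the target moments
  set.seed(52)
  ab <- fit_beta_moments(0.245, 0.08)
  x <- rbeta(1e5, ab[["shape1"]], ab[["shape2"]])
  expect_lt(abs(mean(x) - 0.245), 3 * 0.08 / sqrt(1e5))
  expect_equal(sd(x), 0.08, tolerance = 0.02)
})

test_that("joint sampling is seed-deterministic and respects supports", {
  p <- base_params()
  d1 <- sample_parameter_set(p, seed = 42)
  d2 <- sample_parameter_set(p, seed = 42)
  expect_identical(unclass(d1), unclass(d2))

  meta <- attr(p, "meta")
  set.seed(9)
  n <- 1500
  draws <- t(replicate(n, {
    s <- sample_parameter_set(p)
    vapply(meta$name, function(nm) s[[nm]][1], numeric(1))
  }))
  unit_cols <- meta$name[meta$kind %in% c("probability", "utility")]
  expect_true(all(draws[, unit_cols] >= 0 & draws[, unit_cols] <= 1))
  expect_true(all(draws[, meta$name[meta$kind == "cost"]] >= 0))
  # fixed-family parameters never move
  expect_true(all(draws[, "sens_ewgsop"] == 1))
  expect_true(all(draws[, "wtp"] == 5520.311))
  expect_lt(abs(mean(draws[, "prevalence"]) - 0.245), 3 * 0.08 / sqrt(n))
})

test_that("configuration files round-trip the parameter set exactly", {
  p <- base_params()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    q <- read_parameters(f)
    expect_equal(unclass(q)[names(p)], unclass(p)[names(p)], tolerance = 1e-12)
    expect_equal(attr(q, "meta")$sd_used, attr(p, "meta")$sd_used,
                 tolerance = 1e-12)
    unlink(f)
  }
  # the shipped canonical configuration equals the in-code defaults
  canon <- system.file("extdata", "default_parameters.yaml",
                       package = "sarcscreen")
  expect_true(nzchar(canon))
  q <- read_parameters(canon)
  expect_equal(unclass(q)[names(p)], unclass(p)[names(p)], tolerance = 1e-9)

  f <- tempfile(fileext = ".yaml")
  writeLines("parameters:\n  not_a_parameter: 3", f)
  expect_error(read_parameters(f), "unknown parameter")
  writeLines("parameters:\n  u_sarc: 1.2", f)
  expect_error(read_parameters(f), "u_sarc")
  unlink(f)
})

test_that("synthetic life table rises with age and matches its target life expectancy", {
  q <- synthetic_life_table(horizon = 60)
  expect_true(all(q > 0 & q < 1))
  expect_true(all(diff(q) > 0))
  # independent survival bookkeeping: trapezoidal person-years over the
  # full schedule reproduce the 25-year expectancy at entry
  s <- cumprod(1 - q)
  le <- sum((c(1, s[-length(s)]) + s) / 2)
  expect_equal(le, 25, tolerance = 1e-6)
  # default parameter set uses the schedule over the model horizon
  p <- base_params()
  expect_length(p$p_death_healthy, 25L)
  expect_equal(p$p_death_healthy, synthetic_life_table(25))
  expect_identical(const_params()$p_death_healthy, 0.09)
})
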