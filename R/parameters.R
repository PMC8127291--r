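#' @importFrom stats simulate coef predict
NULL

# Registry of model inputs: base value, printed uncertainty (SD or 95% CI),
# distribution family used in probabilistic sensitivity analysis, and the
# quantity kind (drives validation).  Monetary values are 2019 USD converted
# at the fixed official rate of 42,000 Rial per USD; probabilities are
# per annual cycle unless noted.
.param_registry <- function() {
  r <- function(name, base, sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                family, kind) {
    data.frame(name = name, base = base, sd = sd, ci_low = ci_low,
               ci_high = ci_high, family = family, kind = kind,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r("prevalence",            0.245, sd = 0.08,                    family = "beta",  kind = "probability"),
    r("discount_rate",         0.05,  ci_low = 0.03, ci_high = 0.12, family = "beta", kind = "rate"),
    r("sens_ewgsop",           1.000,                               family = "fixed", kind = "probability"),
    r("sens_sarsamod",         0.806, ci_low = 0.767, ci_high = 0.842, family = "beta", kind = "probability"),
    r("sens_msra",             0.804, sd = 0.08,                    family = "beta",  kind = "probability"),
    r("sens_sarcf",            0.168, ci_low = 0.135, ci_high = 0.206, family = "beta", kind = "probability"),
    r("spec_ewgsop",           0.84,  ci_low = 0.816, ci_high = 0.862, family = "beta", kind = "probability"),
    r("spec_sarsamod",         0.788, ci_low = 0.750, ci_high = 0.803, family = "beta", kind = "probability"),
    r("spec_msra",             0.604, ci_low = 0.543, ci_high = 0.664, family = "beta", kind = "probability"),
    r("spec_sarcf",            0.866, ci_low = 0.843, ci_high = 0.886, family = "beta", kind = "probability"),
    r("p_death_healthy",       0.09,                                family = "beta",  kind = "probability"),
    r("p_death_sarc",          0.132, sd = 0.013,                   family = "beta",  kind = "probability"),
    r("p_death_sarc_cvd",      0.198, sd = 0.03,                    family = "beta",  kind = "probability"),
    r("p_death_fracture",      0.171, sd = 0.02,                    family = "beta",  kind = "probability"),
    r("p_fall",                0.273, sd = 0.03,                    family = "beta",  kind = "probability"),
    r("p_fracture_given_fall", 0.40,  sd = 0.05,                    family = "beta",  kind = "probability"),
    r("p_cvd",                 0.27,  sd = 0.03,                    family = "beta",  kind = "probability"),
    r("cost_treatment_annual", 1119.048, sd = 119.047,              family = "gamma", kind = "cost"),
    r("cost_gait",             0.714,                               family = "gamma", kind = "cost"),
    r("cost_handgrip",         1.309,                               family = "gamma", kind = "cost"),
    r("cost_dxa",              42.857,                              family = "gamma", kind = "cost"),
    r("cost_msra",             0.714,                               family = "gamma", kind = "cost"),
    r("cost_sarcf",            0.714,                               family = "gamma", kind = "cost"),
    r("cost_sarcf_highrisk",   44.880,                              family = "gamma", kind = "cost"),
    r("cost_sarsamod",         1.785,                               family = "gamma", kind = "cost"),
    r("cost_ewgsop_stage1",    2.023,                               family = "gamma", kind = "cost"),
    r("cost_ewgsop_stage2",    42.857,                              family = "gamma", kind = "cost"),
    r("cost_fracture",         3599.048, sd = 695.074,              family = "gamma", kind = "cost"),
    r("cost_cvd_initial",      4149.286,                            family = "gamma", kind = "cost"),
    r("cost_cvd_incremental",  1904.762, sd = 190.476,              family = "gamma", kind = "cost"),
    r("u_healthy",             0.76,                                family = "beta",  kind = "utility"),
    r("u_sarc",                0.68,                                family = "beta",  kind = "utility"),
    r("u_sarc_fracture",       0.51,                                family = "beta",  kind = "utility"),
    r("u_sarc_cvd",            0.56,                                family = "beta",  kind = "utility"),
    r("u_sarc_cvd_fracture",   0.42,                                family = "beta",  kind = "utility"),
    r("efficacy",              0.40,  sd = 0.15,                    family = "beta",  kind = "probability"),
    r("horizon_cycles",        25,                                  family = "fixed", kind = "structural"),
    r("cycle_length",          1,                                   family = "fixed", kind = "structural"),
    r("cohort_size",           1000,                                family = "fixed", kind = "structural"),
    r("wtp",                   5520.311,                            family = "fixed", kind = "structural")
  ))
}

#' Default standard-deviation rule for parameters with no printed uncertainty
#'
#' When a model input has a distribution assigned but no reported standard
#' deviation or confidence interval, its SD is taken as a fixed fraction of
#' the mean (10--15% band, default 12.5%).
#'
#' @param base parameter mean (any finite real).
#' @param fraction fraction of the mean used as SD; must lie in \[0.10, 0.15\].
#' @return `fraction * abs(base)`.
#' @export
default_sd <- function(base, fraction = 0.125) {
  if (!is.finite(base)) stop("default_sd: 'base' must be finite")
  if (!is.numeric(fraction) || fraction < 0.10 || fraction > 0.15)
    stop("default_sd: 'fraction' must lie in [0.10, 0.15], got ", fraction)
  fraction * abs(base)
}

# SD actually used in PSA/DSA for one registry row:
# printed SD > normal-approximation CI width > default fraction of the mean.
.resolve_sd <- function(meta, sd_fraction = 0.125) {
  sd <- meta$sd
  from_ci <- !is.na(meta$ci_low) & !is.na(meta$ci_high) & is.na(sd)
  sd[from_ci] <- (meta$ci_high[from_ci] - meta$ci_low[from_ci]) / (2 * 1.96)
  defaulted <- is.na(sd) & meta$family != "fixed"
  sd[defaulted] <- vapply(meta$base[defaulted], default_sd,
                          numeric(1), fraction = sd_fraction)
  sd[meta$family == "fixed"] <- 0
  list(sd = sd, defaulted = meta$name[defaulted])
}

#' Synthetic age-indexed mortality vector (Gompertz life table)
#'
#' The model's healthy-arm mortality is age-specific: a cohort entering at
#' age 60 faces an annual death probability that rises with age.  The
#' national life table the model is anchored to is summarised here by a
#' synthetic Gompertz schedule: hazard `a * exp(slope * (t - 0.5))` in
#' model year `t`, with the level `a` calibrated so that remaining life
#' expectancy at entry equals `life_expectancy` years (the model's stated
#' 25-year expectancy at age 60).  The slope 0.09/year is the standard
#' adult mortality-doubling rate (doubling time about 8 years).  This is a
#' synthetic stand-in constructed from those two constraints, not a copied
#' national table.
#'
#' @param horizon number of annual cycles to return (default 25).
#' @param life_expectancy target remaining life expectancy at entry, years.
#' @param slope Gompertz log-hazard slope per year.
#' @return numeric vector of length `horizon`: annual death probabilities.
#' @export
#' @examples
#' q <- synthetic_life_table()
#' round(q[c(1, 13, 25)], 4)
synthetic_life_table <- function(horizon = 25, life_expectancy = 25,
                                 slope = 0.09) {
  stopifnot(horizon >= 1, life_expectancy > 1, slope > 0)
  n_full <- 60L  # follow the schedule well past the horizon for the LE calc
  le_at <- function(a) {
    q <- 1 - exp(-a * exp(slope * (seq_len(n_full) - 0.5)))
    s <- cumprod(1 - q)
    sum((c(1, s[-n_full]) + s) / 2)
  }
  a <- stats::uniroot(function(a) le_at(a) - life_expectancy,
                      interval = c(1e-8, 0.5), tol = 1e-12)$root
  q <- 1 - exp(-a * exp(slope * (seq_len(horizon) - 0.5)))
  pmin(q, 1)
}

#' Construct the model parameter set
#'
#' Builds the full input set of the screening cost-effectiveness model:
#' sarcopenia prevalence, per-strategy test sensitivity/specificity, annual
#' transition probabilities, costs (2019 USD), health-state utilities,
#' intervention efficacy, discount rate, and the structural settings (25
#' one-year cycles, cohort of 1000, willingness-to-pay threshold of one GDP
#' per capita, $5520.311/QALY).  Any value may be overridden by name.
#'
#' Healthy-arm mortality has two modes.  The default, `"life_table"`, uses
#' the age-indexed synthetic schedule of [synthetic_life_table()], which is
#' consistent with the model's stated 25-year life expectancy at age 60; it
#' is held fixed in probabilistic sampling.  `"constant"` uses the flat
#' per-cycle summary probability 0.09.  An explicit `p_death_healthy`
#' override (scalar or vector of length `horizon_cycles`) takes precedence
#' over the mode.
#'
#' @param ... named overrides of registry values, e.g. `prevalence = 0.3`.
#' @param mortality healthy-arm mortality mode, `"life_table"` (default) or
#'   `"constant"`; ignored when `p_death_healthy` is supplied directly.
#' @param sd_fraction default-SD fraction for parameters whose uncertainty is
#'   not printed; must lie in \[0.10, 0.15\].
#' @return an object of class `sarc_params`: a named list of values with a
#'   `meta` attribute (data frame of base, sd, family, kind per parameter)
#'   and a `defaults_applied` attribute naming parameters whose SD came from
#'   the default rule.
#' @seealso [read_parameters()], [sample_parameter_set()]
#' @export
#' @examples
#' p <- sarc_parameters()
#' p$prevalence
#' attr(p, "meta")[1:3, ]
sarc_parameters <- function(..., mortality = c("life_table", "constant"),
                            sd_fraction = 0.125) {
  mortality <- match.arg(mortality)
  meta <- .param_registry()
  values <- as.list(stats::setNames(meta$base, meta$name))
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("sarc_parameters: overrides must be named")
    unknown <- setdiff(names(overrides), meta$name)
    if (length(unknown))
      stop("sarc_parameters: unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    values[names(overrides)] <- overrides
  }
  if (!"p_death_healthy" %in% names(overrides) && mortality == "life_table")
    values$p_death_healthy <-
      synthetic_life_table(horizon = as.integer(values$horizon_cycles))
  res <- .resolve_sd(meta, sd_fraction)
  meta$sd_used <- res$sd
  # an age-indexed mortality vector is structural: no scalar uncertainty
  if (length(values$p_death_healthy) > 1L)
    meta$sd_used[meta$name == "p_death_healthy"] <- 0
  out <- structure(values, class = "sarc_params", meta = meta,
                   defaults_applied = res$defaulted,
                   sd_fraction = sd_fraction)
  validate_parameters(out)
  out
}

#' Validate a parameter set
#'
#' Checks presence of every required input, probability and utility ranges,
#' non-negative costs, the utility ordering (the fracture-plus-CVD state is
#' no better than either single morbidity), and a horizon of at least one
#' cycle.  Errors name the offending parameter.
#'
#' @param params a `sarc_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  meta <- attr(params, "meta")
  missing <- setdiff(meta$name, names(params))
  if (length(missing))
    stop("parameter set missing required key(s): ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    v <- params[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("parameter '", nm, "' must be finite numeric")
    if (nm != "p_death_healthy" && length(v) != 1L)
      stop("parameter '", nm, "' must be a scalar")
    kind <- meta$kind[i]
    if (kind %in% c("probability", "utility") && any(v < 0 | v > 1))
      stop("parameter '", nm, "' out of range: must lie in [0, 1], got ",
           paste(signif(v, 6), collapse = ", "))
    if (kind == "cost" && any(v < 0))
      stop("parameter '", nm, "' out of range: costs must be >= 0")
    if (kind == "rate" && any(v < 0))
      stop("parameter '", nm, "' out of range: rates must be >= 0")
  }
  if (params$u_sarc_cvd_fracture >
      min(params$u_sarc_cvd, params$u_sarc_fracture) + 1e-12)
    stop("parameter 'u_sarc_cvd_fracture' out of range: must not exceed ",
         "min(u_sarc_cvd, u_sarc_fracture)")
  if (params$u_healthy < params$u_sarc - 1e-12)
    stop("parameter 'u_healthy' out of range: must be >= u_sarc")
  if (params$horizon_cycles < 1)
    stop("parameter 'horizon_cycles' out of range: must be >= 1")
  pdh <- params$p_death_healthy
  if (length(pdh) != 1L && length(pdh) != params$horizon_cycles)
    stop("parameter 'p_death_healthy' must be scalar or length horizon_cycles")
  invisible(params)
}

#' @export
print.sarc_params <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("Sarcopenia screening model parameters (", nrow(meta), " inputs)\n",
      sep = "")
  cat(sprintf("  prevalence %.3f | discount %.3g | horizon %d cycles | WTP $%.3f/QALY\n",
              x$prevalence, x$discount_rate, as.integer(x$horizon_cycles),
              x$wtp))
  da <- attr(x, "defaults_applied")
  if (length(da))
    cat("  default-SD rule (", attr(x, "sd_fraction") * 100,
        "% of mean) applied to: ", paste(da, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sarc_params <- function(x, ...) {
  meta <- attr(x, "meta")
  meta$value <- vapply(meta$name, function(nm) x[[nm]][1], numeric(1))
  meta
}

#' Read a parameter configuration file
#'
#' Accepts YAML or JSON (by file extension).  Two layouts are supported: a
#' flat map `name: value`, or a rich map `name: {base, sd, ci_low, ci_high,
#' family}` overriding the registry's uncertainty specification.  Unknown
#' keys and out-of-range values raise named errors; parameters whose SD is
#' neither printed nor derivable from a CI fall back to the default-SD rule
#' and are reported in the `defaults_applied` attribute.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` document.
#' @param sd_fraction passed to [sarc_parameters()].
#' @return a validated `sarc_params` object.
#' @export
read_parameters <- function(file, sd_fraction = 0.125) {
  if (!file.exists(file)) stop("read_parameters: no such file: ", file)
  ext <- tolower(tools::file_ext(file))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(file),
    json = jsonlite::read_json(file, simplifyVector = TRUE),
    stop("read_parameters: unsupported extension '", ext, "'"))
  if (!is.null(doc$parameters)) doc <- doc$parameters
  if (!length(doc) || is.null(names(doc)))
    stop("read_parameters: document has no named parameter entries")
  meta <- .param_registry()
  unknown <- setdiff(names(doc), meta$name)
  if (length(unknown))
    stop("read_parameters: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  values <- list()
  for (nm in names(doc)) {
    entry <- doc[[nm]]
    if (is.list(entry)) {
      i <- match(nm, meta$name)
      if (is.null(entry$base)) stop("read_parameters: '", nm, "' lacks 'base'")
      values[[nm]] <- as.numeric(entry$base)
      if (!is.null(entry$sd))      meta$sd[i]      <- as.numeric(entry$sd)
      if (!is.null(entry$ci_low))  meta$ci_low[i]  <- as.numeric(entry$ci_low)
      if (!is.null(entry$ci_high)) meta$ci_high[i] <- as.numeric(entry$ci_high)
      if (!is.null(entry$family))  meta$family[i]  <- as.character(entry$family)
      meta$base[i] <- as.numeric(entry$base)[1]
    } else {
      values[[nm]] <- as.numeric(entry)
      meta$base[match(nm, meta$name)] <- as.numeric(entry)[1]
    }
  }
  full <- as.list(stats::setNames(meta$base, meta$name))
  full[names(values)] <- values
  bad_fam <- setdiff(unique(meta$family), c("beta", "gamma", "fixed"))
  if (length(bad_fam))
    stop("read_parameters: unknown distribution family: ",
         paste(bad_fam, collapse = ", "))
  res <- .resolve_sd(meta, sd_fraction)
  meta$sd_used <- res$sd
  if (length(full$p_death_healthy) > 1L)
    meta$sd_used[meta$name == "p_death_healthy"] <- 0
  out <- structure(full, class = "sarc_params", meta = meta,
                   defaults_applied = res$defaulted,
                   sd_fraction = sd_fraction)
  validate_parameters(out)
  out
}

#' Write a parameter set to a configuration file
#'
#' Serializes a `sarc_params` object in the rich layout understood by
#' [read_parameters()], so that read-after-write reproduces the parameter
#' set exactly.
#'
#' @param params a `sarc_params` object.
#' @param file destination path ending in `.yaml`, `.yml` or `.json`.
#' @return `file`, invisibly.
#' @export
write_parameters <- function(params, file) {
  meta <- attr(params, "meta")
  doc <- list()
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    entry <- list(base = unname(params[[nm]]), family = meta$family[i])
    if (!is.na(meta$sd[i]))      entry$sd      <- meta$sd[i]
    if (!is.na(meta$ci_low[i]))  entry$ci_low  <- meta$ci_low[i]
    if (!is.na(meta$ci_high[i])) entry$ci_high <- meta$ci_high[i]
    doc[[nm]] <- entry
  }
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    yaml = , yml = yaml::write_yaml(list(parameters = doc), file,
                                    precision = 15L),
    json = jsonlite::write_json(list(parameters = doc), file,
                                auto_unbox = TRUE, digits = NA),
    stop("write_parameters: unsupported extension '", ext, "'"))
  invisible(file)
}

#' Beta distribution from mean and standard deviation (method of moments)
#'
#' @param mean target mean, strictly inside (0, 1).
#' @param sd target standard deviation; must satisfy `sd^2 < mean * (1-mean)`.
#' @return named vector `c(shape1, shape2)`.
#' @export
#' @examples
#' fit_beta_moments(0.245, 0.08)
fit_beta_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("fit_beta_moments: 'mean' must lie strictly in (0, 1)")
  if (!is.finite(sd) || sd <= 0)
    stop("fit_beta_moments: 'sd' must be > 0")
  v <- mean * (1 - mean)
  if (sd^2 >= v)
    stop("fit_beta_moments: infeasible moments, need sd^2 < mean*(1-mean) = ",
         signif(v, 6))
  kappa <- v / sd^2 - 1
  c(shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

#' Gamma distribution from mean and standard deviation (method of moments)
#'
#' @param mean target mean, > 0.
#' @param sd target standard deviation, > 0.
#' @return named vector `c(shape, scale)`.
#' @export
#' @examples
#' fit_gamma_moments(1119.048, 119.047)
fit_gamma_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    stop("fit_gamma_moments: 'mean' must be > 0")
  if (!is.finite(sd) || sd <= 0)
    stop("fit_gamma_moments: 'sd' must be > 0")
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Each uncertain parameter is drawn independently from its moment-matched
#' marginal: Beta for probabilities, utilities and the discount rate, Gamma
#' for costs; `fixed`-family parameters (and a vector `p_death_healthy`) are
#' left at their base values.  Draws use R's global RNG stream; pass `seed`
#' for a self-contained reproducible draw.
#'
#' @param params base `sarc_params` object.
#' @param seed optional integer seed applied before drawing.
#' @return a `sarc_params` object holding one joint draw.
#' @export
sample_parameter_set <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- attr(params, "meta")
  out <- params
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    fam <- meta$family[i]
    if (fam == "fixed") next
    if (nm == "p_death_healthy" && length(params[[nm]]) > 1L) next
    base <- unname(params[[nm]])
    sd <- meta$sd_used[i]
    if (sd <= 0) next
    out[[nm]] <- if (fam == "beta") {
      ab <- fit_beta_moments(base, sd)
      stats::rbeta(1, ab[["shape1"]], ab[["shape2"]])
    } else {
      gs <- fit_gamma_moments(base, sd)
      stats::rgamma(1, shape = gs[["shape"]], scale = gs[["scale"]])
    }
  }
  out
}
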