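## Ratio endpoints (RBE, OER) and percent reductions, with first-order
## error propagation on the Monte Carlo standard errors.

ratio_with_se <- function(num, den, what) {
  num <- as_value_se(num); den <- as_value_se(den)
  if (den[["value"]] <= 0) stopf("%s reference yield must be positive", what)
  r <- num[["value"]] / den[["value"]]
  rel <- sqrt((num[["se"]] / num[["value"]])^2 + (den[["se"]] / den[["value"]])^2)
  c(value = r, se = if (num[["value"]] > 0) r * rel else 0)
}

as_value_se <- function(x) {
  if (inherits(x, "damage_yields")) x <- yield_entry(x, "total_DSB")
  if (is.numeric(x) && length(x) == 1L) x <- c(value = x, se = 0)
  if (!is.numeric(x) || is.null(names(x)) || !all(c("value", "se") %in% names(x)))
    stopf("expected a damage_yields object, a c(value, se) pair, or a bare number")
  x[c("value", "se")]
}

#' Relative biological effectiveness (RBE) for a damage class
#'
#' Ratio of the class yield of a test radiation to the gamma-ray reference
#' yield.  Inputs are `c(value, se)` pairs (see [yield_entry()]), bare
#' numbers, or `damage_yields` objects (total DSB is then used, the
#' conventional endpoint).  Standard errors propagate in quadrature on the
#' relative scale.
#'
#' @param sigma_r test-radiation yield.
#' @param sigma_gamma reference yield (> 0).
#' @return Named numeric `c(value, se)`.
#' @export
#' @examples
#' rbe(c(value = 24.0, se = 0.1), c(value = 8.29, se = 0.01))
rbe <- function(sigma_r, sigma_gamma) ratio_with_se(sigma_r, sigma_gamma, "RBE")

#' Oxygen enhancement ratio (OER) for a damage class
#'
#' Ratio of a class yield under the aerobic reference tension to the
#' yield under hypoxia (conventionally 21% vs 0.001% O2).  Callable for
#' any damage class, e.g. the SSB class as well as the DSB class.
#'
#' @param yield_aerobic aerobic yield.
#' @param yield_hypoxic hypoxic yield (> 0).
#' @return Named numeric `c(value, se)`.
#' @export
oer <- function(yield_aerobic, yield_hypoxic) ratio_with_se(yield_aerobic, yield_hypoxic, "OER")

#' Percent reduction relative to a baseline
#'
#' @param baseline baseline value (> 0).
#' @param modified modified value.
#' @return `100 * (1 - modified / baseline)` (vectorised over `modified`).
#' @export
#' @examples
#' percent_reduction(8.29, 4.36)  # ~ 47.4
percent_reduction <- function(baseline, modified) {
  if (any(baseline <= 0)) stopf("'baseline' must be positive")
  100 * (1 - modified / baseline)
}

#' RBE-vs-DMSO sweep
#'
#' Computes the full damage-yield table and the DSB-class RBE against a
#' gamma-ray reference along a DMSO concentration grid.  The test quality
#' and the reference share the untreated baseline population convention:
#' both are thinned from their own baselines with their own scavenger
#' parameter sets, and the RBE at each concentration is the ratio of the
#' resulting total-DSB yields.
#'
#' @param quality test [radiation_quality()] (or [damage_model()]).
#' @param reference gamma-ray reference [radiation_quality()] (or model).
#' @param dmso_grid DMSO concentrations in mol/L.
#' @param config a [simulation_config()].
#' @param o2_percent oxygen tension for the whole sweep.
#' @return Long data frame: `quality`, `class`, `dmso_M`, `yield`, `se`,
#'   plus `rbe` and `rbe_se` on the `total_DSB` rows of the test quality.
#' @export
dmso_sweep <- function(quality, reference, dmso_grid = seq(0, 2, by = 0.25),
                       config = simulation_config(n_clusters = 5e5),
                       o2_percent = 21) {
  if (inherits(quality, "damage_model")) quality <- quality$quality
  if (inherits(reference, "damage_model")) reference <- reference$quality
  pop_t <- generate_clusters(quality, config)
  pop_r <- generate_clusters(reference, config,
                             seed = derive_seed(config$seed, "reference"))
  rows <- list()
  for (c_dmso in dmso_grid) {
    env <- environment_condition(c_dmso, o2_percent)
    yt <- tally_yields(maybe_thin(pop_t, combined_survival(env, quality), config$seed), config)
    yr <- tally_yields(maybe_thin(pop_r, combined_survival(env, reference), config$seed), config)
    r <- rbe(yt, yr)
    d <- as.data.frame(yt)
    d <- data.frame(quality = quality$name, class = d$class, dmso_M = c_dmso,
                    yield = d$yield, se = d$se, rbe = NA_real_, rbe_se = NA_real_)
    d$rbe[d$class == "total_DSB"] <- r[["value"]]
    d$rbe_se[d$class == "total_DSB"] <- r[["se"]]
    rows[[length(rows) + 1L]] <- d
  }
  do.call(rbind, rows)
}

#' OER-vs-oxygen sweep
#'
#' Damage yields and DSB-class OER along an oxygen-tension grid (the OER
#' at each tension is the reference-tension yield divided by the yield at
#' that tension, so it starts near the full OER in anoxia and falls to 1
#' at the reference).
#'
#' @param quality test [radiation_quality()] (or [damage_model()]).
#' @param o2_grid oxygen tensions in % O2.
#' @param config a [simulation_config()].
#' @param dmso_M DMSO concentration applied to the whole sweep.
#' @return Long data frame: `quality`, `class`, `o2_percent`, `yield`,
#'   `se`, plus `oer`/`oer_se` on `total_DSB` rows.
#' @export
o2_sweep <- function(quality, o2_grid = c(0.001, 0.01, 0.1, 1, 2, 5, 21, 100),
                     config = simulation_config(n_clusters = 5e5), dmso_M = 0) {
  if (inherits(quality, "damage_model")) quality <- quality$quality
  pop <- generate_clusters(quality, config)
  ref_env <- environment_condition(dmso_M, quality$oxygen$reference_o2)
  y_ref <- tally_yields(maybe_thin(pop, combined_survival(ref_env, quality), config$seed), config)
  rows <- list()
  for (o2 in o2_grid) {
    env <- environment_condition(dmso_M, o2)
    y <- tally_yields(maybe_thin(pop, combined_survival(env, quality), config$seed), config)
    r <- oer(y_ref, y)
    d <- as.data.frame(y)
    d <- data.frame(quality = quality$name, class = d$class, o2_percent = o2,
                    yield = d$yield, se = d$se, oer = NA_real_, oer_se = NA_real_)
    d$oer[d$class == "total_DSB"] <- r[["value"]]
    d$oer_se[d$class == "total_DSB"] <- r[["se"]]
    rows[[length(rows) + 1L]] <- d
  }
  do.call(rbind, rows)
}

maybe_thin <- function(pop, s, seed) if (s < 1) thin_lesions(pop, s, seed) else pop
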