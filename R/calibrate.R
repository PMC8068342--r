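#' Baseline yield calibration target
#'
#' Per-class absolute yields (per Gy per Gbp) to which the cluster
#' generation model is fitted.  The default is the reference aerobic,
#' scavenger-free baseline for 62 MeV protons (LET 1.051 keV/um) from
#' published Monte Carlo damage-simulation benchmarks: BD 421.03,
#' SSB 177.77, SSB+ 8.04, 2SSB 1.01, DSB 7.19, DSB+ 0.99, DSB++ 0.12.
#'
#' The fit criterion uses four statistics derived from these values: the
#' BD fraction, the total-SSB fraction, the total-DSB fraction, and the
#' complex-DSB share (DSB+ + DSB++) of total DSB.  The overall cluster
#' rate is fixed by the total damage yield (one damage site per cluster).
#'
#' @param yields named numeric vector of the seven class yields.
#' @param tolerance relative tolerance on the four fitted statistics.
#' @return An object of class `calibration_target`.
#' @export
calibration_target <- function(yields = c(BD = 421.03, SSB = 177.77,
                                          `SSB+` = 8.04, `2SSB` = 1.01,
                                          DSB = 7.19, `DSB+` = 0.99,
                                          `DSB++` = 0.12),
                               tolerance = 0.03) {
  if (!all(YIELD_CLASSES %in% names(yields)))
    stopf("'yields' must name all classes: %s", paste(YIELD_CLASSES, collapse = ", "))
  yields <- yields[YIELD_CLASSES]
  if (any(yields < 0) || yields["BD"] <= 0 || yields["SSB"] <= 0 || yields["DSB"] <= 0)
    stopf("BD, SSB and DSB targets must be positive")
  check_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  total <- sum(yields)
  tdsb <- sum(yields[c("DSB", "DSB+", "DSB++")])
  stats <- c(frac_BD = unname(yields["BD"]) / total,
             frac_total_SSB = sum(yields[c("SSB", "SSB+", "2SSB")]) / total,
             frac_total_DSB = tdsb / total,
             complex_DSB_share = sum(yields[c("DSB+", "DSB++")]) / tdsb)
  structure(list(yields = yields, total = total, stats = stats,
                 tolerance = tolerance), class = "calibration_target")
}

## Class-fraction statistics of a simulated population, matching the
## layout of calibration_target$stats.
population_stats <- function(classes, n) {
  cnt <- table(factor(classes, levels = YIELD_CLASSES))
  f <- as.numeric(cnt) / n
  names(f) <- YIELD_CLASSES
  tdsb <- sum(f[c("DSB", "DSB+", "DSB++")])
  c(frac_BD = unname(f["BD"]),
    frac_total_SSB = sum(f[c("SSB", "SSB+", "2SSB")]),
    frac_total_DSB = tdsb,
    complex_DSB_share = if (tdsb > 0) sum(f[c("DSB+", "DSB++")]) / tdsb else 0)
}

#' Fit the cluster-generation model to baseline damage yields
#'
#' The central fitting function of the package.  Searches the shape
#' parameters of the cluster model --- mean extra-lesion count
#' `multiplicity_nu`, strand-break probability `p_strand_break` and
#' segment length `nseg` --- by derivative-free Nelder--Mead minimisation
#' of the summed squared relative error on four target statistics (BD
#' fraction, total-SSB fraction, total-DSB fraction, complex-DSB share).
#' The cluster rate `rho` needs no search: every cluster is one damage
#' site, so `rho` equals the target total damage yield.  The remaining
#' search exploits the model structure for variance reduction: the number
#' of strand breaks per cluster is a Bernoulli(`p`) plus a thinned Poisson
#' (`Poisson(nu * p)`), which is closed-form, while the split of clusters
#' with `b >= 2` breaks among the SSB+/2SSB/DSB/DSB+/DSB++ classes depends
#' only on `b` and `nseg` (break strands and positions are i.i.d. given
#' the counts).  Those conditional class probabilities are estimated once
#' per candidate segment length as seeded Monte Carlo geometry tables, so
#' the objective is a smooth deterministic function of `(nu, p)` and
#' Nelder--Mead converges tightly; `nseg` is scanned over an integer grid.
#' The optimum is then re-simulated end to end at `n_final` clusters and
#' the four statistics validated against the target tolerance (allowing
#' twice the Monte Carlo standard error of the validation run itself).
#'
#' @param target a [calibration_target()].
#' @param quality_name,let_keV_um label and nominal LET for the fitted quality.
#' @param scavenger,oxygen survival parameter sets attached to the fitted
#'   quality (defaults: 62 MeV proton scavenger preset; default oxygen
#'   hyperbola).
#' @param init named vector of starting values `c(nu, p)`.
#' @param nseg_grid integer segment lengths scanned (all > 10 bp); the
#'   best value is refined by checking its immediate neighbours.
#' @param n_geom clusters per break count used for the geometry tables.
#' @param n_final clusters for the final validation simulation.
#' @param maxit Nelder--Mead iteration budget per segment length.
#' @param seed root seed; the search and validation are reproducible.
#' @return An object of class `damage_model` with components `quality`
#'   (the calibrated [radiation_quality()]), `target`, `stats_fitted`,
#'   `residuals` (relative errors on the four statistics at `n_final`),
#'   `residual_se` (their Monte Carlo standard errors), `fitted_yields`
#'   (a `damage_yields` object at `n_final` clusters), `converged`,
#'   `optim` (optimiser output at the selected segment length) and
#'   `seed`.  If any residual exceeds the tolerance (plus twice its
#'   standard error) the model is returned with `converged = FALSE` and a
#'   warning reporting the best residuals.
#' @seealso [predict.damage_model()], [simulate.damage_model()],
#'   [calibrate_oxygen()], [anchor_rbe_quality()]
#' @export
damage_model <- function(target = calibration_target(),
                         quality_name = "proton62MeV", let_keV_um = 1.051,
                         scavenger = scavenger_preset("proton62MeV"),
                         oxygen = oxygen_params(),
                         init = c(nu = 0.7, p = 0.23),
                         nseg_grid = seq(12L, 36L, by = 2L),
                         n_geom = 4e4, n_final = 2e6,
                         maxit = 300, seed = 1L) {
  if (!inherits(target, "calibration_target")) stopf("'target' must be a calibration_target")
  rho <- target$total
  par0 <- c(log(init[["nu"]]), qlogis(init[["p"]]))

  fit_nseg <- function(nseg) {
    G <- geometry_table(nseg, n_geom = n_geom,
                        seed = derive_seed(seed, paste0("geom", nseg)))
    opt <- stats::optim(par0, analytic_objective, G = G,
                        target_stats = target$stats,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    opt$nseg <- nseg
    opt
  }
  fits <- lapply(as.integer(nseg_grid), fit_nseg)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  for (ns in best$nseg + c(-1L, 1L)) {      # refine on the unit grid
    if (ns > 10L && !(ns %in% nseg_grid)) {
      cand <- fit_nseg(ns)
      if (cand$value < best$value) best <- cand
    }
  }
  nu <- exp(best$par[1L]); p <- plogis(best$par[2L])
  quality <- radiation_quality(quality_name, let_keV_um, rho, nu, p,
                               best$nseg, scavenger = scavenger,
                               oxygen = oxygen)

  cfg <- simulation_config(n_clusters = n_final, seed = derive_seed(seed, "validate"))
  pop <- generate_clusters(quality, cfg, seed = cfg$seed)
  fitted <- tally_yields(pop, cfg)
  stats_fitted <- population_stats(classify_clusters(pop), pop$n_clusters)
  resid <- (stats_fitted - target$stats) / target$stats
  resid_se <- stats_standard_errors(fitted) / target$stats
  converged <- best$convergence == 0L &&
    all(abs(resid) <= target$tolerance + 2 * resid_se)
  if (!converged)
    warning(sprintf(
      "calibration did not reach tolerance %.3g; residuals: %s",
      target$tolerance,
      paste(sprintf("%s=%.3f", names(resid), resid), collapse = ", ")),
      call. = FALSE)
  structure(list(quality = quality, target = target,
                 stats_fitted = stats_fitted, residuals = resid,
                 residual_se = resid_se, fitted_yields = fitted,
                 converged = converged, n_geom = n_geom, n_final = n_final,
                 optim = best, seed = seed, call = match.call()),
            class = "damage_model")
}

## Conditional class probabilities P(class | b breaks, nseg) for
## b = 2..bmax, estimated by seeded simulation of break geometries
## (strands fair, positions uniform); base damages are irrelevant to the
## classification of these sectors.
geometry_table <- function(nseg, bmax = 12L, n_geom = 4e4, seed = 1L) {
  sector <- c("SSB+", "2SSB", "DSB", "DSB+", "DSB++")
  G <- matrix(0, nrow = bmax - 1L, ncol = length(sector),
              dimnames = list(2:bmax, sector))
  for (b in 2:bmax) {
    ## high-break sectors carry exponentially small weight in the break
    ## count pmf, so fewer geometry samples suffice there
    n_b <- as.integer(max(2000, n_geom / 4^(b - 2L)))
    pop <- with_seed(derive_seed(seed, paste0("b", b)), {
      cl <- rep.int(seq_len(n_b), b)
      lesion_population(cl, sample.int(nseg, n_b * b, replace = TRUE) - 1L,
                        sample.int(2L, n_b * b, replace = TRUE) - 1L,
                        rep(TRUE, n_b * b), n_b, nseg)
    })
    cls <- classify_clusters(pop)
    G[as.character(b), ] <- as.numeric(table(factor(cls, levels = sector))) / n_b
  }
  G
}

## Closed-form break-count pmf combined with the geometry table.
analytic_objective <- function(par, G, target_stats) {
  nu <- exp(par[1L]); p <- plogis(par[2L])
  if (nu > 20) return(1e6)
  bmax <- nrow(G) + 1L
  lam <- nu * p
  b <- 0:bmax
  w <- (1 - p) * stats::dpois(b, lam) + p * stats::dpois(b - 1L, lam)
  w[bmax + 1L] <- max(0, 1 - sum(w[seq_len(bmax)]))   # lump the tail
  sec <- as.numeric(w[3:(bmax + 1L)] %*% G)
  names(sec) <- colnames(G)
  tdsb <- sum(sec[c("DSB", "DSB+", "DSB++")])
  s <- c(frac_BD = w[1L],
         frac_total_SSB = w[2L] + sec[["SSB+"]] + sec[["2SSB"]],
         frac_total_DSB = tdsb,
         complex_DSB_share = if (tdsb > 0) (sec[["DSB+"]] + sec[["DSB++"]]) / tdsb else 0)
  sum(((s - target_stats) / target_stats)^2)
}

## Monte Carlo standard errors of the four fitted statistics of a
## validation run, on the same scale as the statistics themselves.
stats_standard_errors <- function(y) {
  n <- y$totals["total_damage", "count"]
  f_bd <- y$table$count[y$table$class == "BD"] / n
  f_ssb <- y$totals["total_SSB", "count"] / n
  f_dsb <- y$totals["total_DSB", "count"] / n
  d <- max(y$totals["total_DSB", "count"], 1)
  share <- sum(y$table$count[y$table$class %in% c("DSB+", "DSB++")]) / d
  c(frac_BD = sqrt(f_bd * (1 - f_bd) / n),
    frac_total_SSB = sqrt(f_ssb * (1 - f_ssb) / n),
    frac_total_DSB = sqrt(f_dsb * (1 - f_dsb) / n),
    complex_DSB_share = sqrt(share * (1 - share) / d))
}

#' @export
print.damage_model <- function(x, ...) {
  cat("Calibrated clustered DNA damage model\n")
  cat(sprintf("  quality: %s (rho = %.4g /Gy/Gbp, nu = %.4g, p_break = %.4g, nseg = %d bp)\n",
              x$quality$name, x$quality$cluster_rate_rho,
              x$quality$multiplicity_nu, x$quality$p_strand_break, x$quality$nseg))
  cat(sprintf("  converged: %s (max |relative residual| = %.4f, tolerance %.3g)\n",
              x$converged, max(abs(x$residuals)), x$target$tolerance))
  invisible(x)
}

#' @export
coef.damage_model <- function(object, ...) {
  q <- object$quality
  c(cluster_rate_rho = q$cluster_rate_rho, multiplicity_nu = q$multiplicity_nu,
    p_strand_break = q$p_strand_break, nseg = as.numeric(q$nseg))
}

#' @export
residuals.damage_model <- function(object, ...) object$residuals

#' @export
summary.damage_model <- function(object, ...) {
  out <- list(coef = coef(object), residuals = object$residuals,
              target = object$target$yields,
              fitted = yields_named(object$fitted_yields),
              converged = object$converged,
              counts = object$optim$counts, value = object$optim$value)
  class(out) <- "summary.damage_model"
  out
}

#' @export
print.summary.damage_model <- function(x, ...) {
  cat("Calibrated clustered DNA damage model\n\nParameters:\n")
  print(round(x$coef, 4))
  cat("\nTarget vs fitted class yields (per Gy per Gbp):\n")
  print(round(rbind(target = x$target, fitted = x$fitted[YIELD_CLASSES]), 2))
  cat("\nRelative residuals on fitted statistics:\n")
  print(round(x$residuals, 4))
  cat(sprintf("\nObjective %.3g after %d evaluations; converged: %s\n",
              x$value, x$counts[1L], x$converged))
  invisible(x)
}

yields_named <- function(y) {
  v <- c(y$table$yield, y$totals$yield)
  names(v) <- c(y$table$class, rownames(y$totals))
  v
}

#' Predict damage yields under environmental conditions
#'
#' Simulates the fitted model under each requested DMSO/oxygen condition
#' and returns the class yields in long format.  Conditions share the same
#' freshly generated baseline population and are thinned with common
#' random numbers, so predicted yields are coupled (monotone in the
#' survival factor).
#'
#' @param object a [damage_model()].
#' @param newdata data frame with columns `dmso_M` and `o2_percent` (one
#'   row per condition); default is the untreated aerobic condition.
#' @param n_clusters population size per prediction.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A data frame: `dmso_M`, `o2_percent`, `survival`, `class`,
#'   `yield`, `se`.
#' @export
predict.damage_model <- function(object, newdata = NULL, n_clusters = 2e6,
                                 seed = 1L, ...) {
  newdata <- newdata %||% data.frame(dmso_M = 0, o2_percent = object$quality$oxygen$reference_o2)
  if (!all(c("dmso_M", "o2_percent") %in% names(newdata)))
    stopf("'newdata' needs columns dmso_M and o2_percent")
  cfg <- simulation_config(n_clusters = n_clusters, seed = seed)
  pop <- generate_clusters(object$quality, cfg)
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    env <- environment_condition(newdata$dmso_M[i], newdata$o2_percent[i])
    s <- combined_survival(env, object$quality)
    y <- tally_yields(if (s < 1) thin_lesions(pop, s, seed = seed) else pop, cfg)
    v <- yields_named(y)
    sev <- c(y$table$se, y$totals$se)
    data.frame(dmso_M = env$dmso_M, o2_percent = env$o2_percent,
               survival = min(s, 1), class = names(v), yield = unname(v),
               se = sev, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Simulate damage yields from a fitted model
#'
#' `simulate()` draws `nsim` independent Monte Carlo replicates of the
#' damage spectrum under one condition.
#'
#' @param object a [damage_model()].
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param environment an [environment_condition()].
#' @param n_clusters clusters per replicate.
#' @param ... unused.
#' @return A list of `damage_yields` objects (length `nsim`), or a single
#'   object when `nsim = 1`.
#' @export
simulate.damage_model <- function(object, nsim = 1, seed = 1L,
                                  environment = environment_condition(),
                                  n_clusters = 1e5, ...) {
  reps <- lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(n_clusters = n_clusters,
                             seed = derive_seed(seed, paste0("rep", i)))
    simulate_damage_spectrum(object$quality, environment, cfg)
  })
  if (nsim == 1L) reps[[1L]] else reps
}

#' @export
plot.damage_model <- function(x, ...) {
  tgt <- x$target$yields
  fit <- yields_named(x$fitted_yields)[YIELD_CLASSES]
  m <- rbind(target = tgt, fitted = fit)
  graphics::barplot(m, beside = TRUE, log = "y", las = 2,
                    legend.text = rownames(m),
                    ylab = "yield (per Gy per Gbp)",
                    main = "Calibrated baseline damage spectrum", ...)
  invisible(x)
}

#' Total-DSB retention curve under per-lesion thinning
#'
#' Estimates the fraction of the total-DSB class yield retained when the
#' model's baseline population is Bernoulli-thinned at each survival value
#' in `s_grid`.  All grid points share one population and common thinning
#' uniforms, so the curve is monotone by construction; it is returned with
#' a monotone linear interpolator used by [calibrate_oxygen()].
#'
#' @param model a [damage_model()] or a bare [radiation_quality()].
#' @param s_grid survival grid in (0, 1].
#' @param n_clusters population size.
#' @param seed RNG seed.
#' @return A list with `s`, `retention`, the baseline total-DSB count, and
#'   interpolating functions `fun` (s -> retention) and `inv`
#'   (retention -> s).
#' @export
dsb_retention_curve <- function(model, s_grid = seq(0.25, 1, by = 0.025),
                                n_clusters = 2e6, seed = 1L) {
  quality <- if (inherits(model, "radiation_quality")) model else model$quality
  cfg <- simulation_config(n_clusters = n_clusters, seed = seed)
  pop <- generate_clusters(quality, cfg)
  base <- sum(tally_yields(pop, cfg)$totals["total_DSB", "count"])
  ret <- vapply(s_grid, function(s) {
    y <- tally_yields(thin_lesions(pop, s, seed = seed), cfg)
    y$totals["total_DSB", "count"] / base
  }, numeric(1))
  list(s = s_grid, retention = ret, base_count = base,
       fun = stats::approxfun(s_grid, ret, rule = 2),
       inv = stats::approxfun(ret, s_grid, rule = 2, ties = "ordered"))
}

#' Calibrate the oxygen hyperbola of a fitted damage model
#'
#' Fits the lesion-level oxygen parameters `(m_lesion, k_o2)` so that the
#' model reproduces (a) the DSB-class oxygen enhancement ratio between the
#' aerobic reference and the anoxic endpoint, and optionally (b) one
#' intermediate-tension total-DSB yield.  The class-level response is
#' obtained from the Monte Carlo retention curve
#' ([dsb_retention_curve()]); the two survival values implied by the
#' targets are inverted through it and the hyperbola parameters solved by
#' a Nelder--Mead least-squares step.  With `intermediate = NULL` only
#' `m_lesion` is fitted and `k_o2` keeps its current value.
#'
#' @param model a [damage_model()].
#' @param oer_target DSB-class OER (reference vs `hypoxic_o2`).
#' @param hypoxic_o2 anoxic endpoint tension in % O2.
#' @param intermediate optional list `list(o2_percent=, total_DSB=)` giving
#'   a held-in intermediate-tension total-DSB yield (per Gy per Gbp).
#' @param curve optional precomputed [dsb_retention_curve()].
#' @param n_clusters population size for the retention curve.
#' @param seed RNG seed.
#' @return An [oxygen_params()] object with a `"fit"` attribute recording
#'   targets, implied survivals, solver residual and seed.
#' @export
calibrate_oxygen <- function(model, oer_target = 2.9, hypoxic_o2 = 0.001,
                             intermediate = list(o2_percent = 0.1, total_DSB = 3.55),
                             curve = NULL, n_clusters = 2e6, seed = 1L) {
  stopifnot(inherits(model, "damage_model"))
  curve <- curve %||% dsb_retention_curve(model, n_clusters = n_clusters, seed = seed)
  ref <- model$quality$oxygen$reference_o2
  s_hyp <- curve$inv(1 / oer_target)
  h <- function(x, m, K) (m * x + K) / (x + K)
  if (is.null(intermediate)) {
    K <- model$quality$oxygen$k_o2
    obj <- function(lm) (h(hypoxic_o2, 1 + exp(lm), K) / h(ref, 1 + exp(lm), K) - s_hyp)^2
    opt <- stats::optimize(obj, c(log(1e-3), log(20)))
    m <- 1 + exp(opt$minimum)
    resid <- sqrt(opt$objective)
  } else {
    base_yield <- model$fitted_yields$totals["total_DSB", "yield"]
    s_int <- curve$inv(intermediate$total_DSB / base_yield)
    obj <- function(par) {
      m <- 1 + exp(par[1L]); K <- exp(par[2L])
      (h(hypoxic_o2, m, K) / h(ref, m, K) - s_hyp)^2 +
        (h(intermediate$o2_percent, m, K) / h(ref, m, K) - s_int)^2
    }
    opt <- stats::optim(c(log(0.75), log(0.7)), obj,
                        control = list(maxit = 500, reltol = 1e-12))
    m <- 1 + exp(opt$par[1L]); K <- exp(opt$par[2L])
    resid <- sqrt(opt$value)
  }
  out <- oxygen_params(m_lesion = m,
                       k_o2 = if (is.null(intermediate)) model$quality$oxygen$k_o2 else K,
                       reference_o2 = ref)
  attr(out, "fit") <- list(oer_target = oer_target, hypoxic_o2 = hypoxic_o2,
                           intermediate = intermediate, s_hypoxic = s_hyp,
                           residual = resid, seed = seed)
  out
}

#' Anchor a second radiation quality by its zero-scavenger RBE
#'
#' Builds a high-LET quality (helium ions by default) whose cluster rate
#' is scaled so that its zero-DMSO DSB-class RBE against the reference
#' model equals `rbe0`.  The lesion multiplicity is a stated design
#' parameter: high-LET tracks give denser clusters, so the complex-DSB
#' share (DSB+ and DSB++ among total DSB) is markedly higher than for the
#' low-LET reference.  Strand-break probability and segment length are
#' inherited from the reference model.
#'
#' @param model the calibrated low-LET reference [damage_model()].
#' @param rbe0 zero-scavenger DSB-class RBE anchor.
#' @param multiplicity_nu mean extra lesions per cluster for the new quality.
#' @param name,let_keV_um label and nominal LET.
#' @param scavenger scavenger parameters for the new quality.
#' @param oxygen oxygen parameters for the new quality; when `NULL` and
#'   `oer_endpoint` is given, `m_lesion` is refitted so the new quality's
#'   DSB-class OER endpoint matches `oer_endpoint` (with `k_o2` inherited
#'   from the reference), otherwise the reference oxygen parameters are
#'   inherited unchanged.
#' @param oer_endpoint optional DSB-class OER endpoint for the new quality
#'   (e.g. 1.2 for 3.31 MeV helium ions).
#' @param n_clusters population size used to measure the DSB fraction.
#' @param seed RNG seed.
#' @return A [radiation_quality()] with a `"fit"` attribute.
#' @export
anchor_rbe_quality <- function(model, rbe0 = 2.9, multiplicity_nu = 3,
                               name = "helium3.31MeV", let_keV_um = 120,
                               scavenger = scavenger_preset("helium3.31MeV"),
                               oxygen = NULL, oer_endpoint = NULL,
                               n_clusters = 1e6, seed = 1L) {
  stopifnot(inherits(model, "damage_model"))
  ref_q <- model$quality
  ## DSB fraction per cluster for the new shape parameters
  trial <- radiation_quality(name, let_keV_um, cluster_rate_rho = 1,
                             multiplicity_nu = multiplicity_nu,
                             p_strand_break = ref_q$p_strand_break,
                             nseg = ref_q$nseg, scavenger = scavenger,
                             oxygen = oxygen %||% ref_q$oxygen)
  cfg <- simulation_config(n_clusters = n_clusters, seed = seed)
  cls <- classify_clusters(generate_clusters(trial, cfg))
  frac_new <- mean(cls %in% c("DSB", "DSB+", "DSB++"))
  ref_dsb <- model$fitted_yields$totals["total_DSB", "yield"]
  rho <- rbe0 * ref_dsb / frac_new
  out <- radiation_quality(name, let_keV_um, cluster_rate_rho = rho,
                           multiplicity_nu = multiplicity_nu,
                           p_strand_break = ref_q$p_strand_break,
                           nseg = ref_q$nseg, scavenger = scavenger,
                           oxygen = oxygen %||% ref_q$oxygen)
  oxy_fit <- NULL
  if (is.null(oxygen) && !is.null(oer_endpoint)) {
    curve <- dsb_retention_curve(out, n_clusters = n_clusters,
                                 seed = derive_seed(seed, "anchor-oxy"))
    s_hyp <- curve$inv(1 / oer_endpoint)
    K <- ref_q$oxygen$k_o2
    ref <- ref_q$oxygen$reference_o2
    h <- function(x, m) (m * x + K) / (x + K)
    opt <- stats::optimize(function(lm) (h(0.001, 1 + exp(lm)) / h(ref, 1 + exp(lm)) - s_hyp)^2,
                           c(log(1e-4), log(20)))
    out$oxygen <- oxygen_params(1 + exp(opt$minimum), K, ref)
    oxy_fit <- list(oer_endpoint = oer_endpoint, s_hypoxic = s_hyp,
                    residual = sqrt(opt$objective))
  }
  attr(out, "fit") <- list(rbe0 = rbe0, reference_total_DSB = ref_dsb,
                           dsb_fraction = frac_new, oxygen = oxy_fit,
                           seed = seed)
  out
}
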