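## Shared fixtures.  The calibrated proton model is expensive, so it is
## fitted once per test run and cached; the acceptance checks additionally
## cache the large baseline population they share.

.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- damage_model(n_final = 5e5, seed = 101)
  .fixtures$model
}

acceptance_model <- function() {
  if (is.null(.fixtures$acc_model))
    .fixtures$acc_model <- damage_model(seed = 101)  # validates at 2e6
  .fixtures$acc_model
}

acceptance_population <- function(n = 2e6) {
  if (is.null(.fixtures$acc_pop)) {
    cfg <- simulation_config(n_clusters = n, seed = 202)
    .fixtures$acc_pop <- generate_clusters(acceptance_model()$quality, cfg)
    .fixtures$acc_cfg <- cfg
  }
  list(pop = .fixtures$acc_pop, cfg = .fixtures$acc_cfg)
}

total_dsb <- function(yields) yield_entry(yields, "total_DSB")[["value"]]

## Total-DSB yield (per Gy per Gbp) of the shared acceptance population
## thinned at a given per-lesion survival; coupled across survivals by the
## common thinning seed, and cached.
acc_dsb_yield <- function(survival) {
  key <- sprintf("s%.10f", survival)
  if (is.null(.fixtures$dsb)) .fixtures$dsb <- list()
  if (is.null(.fixtures$dsb[[key]])) {
    ap <- acceptance_population()
    pop <- if (survival < 1) thin_lesions(ap$pop, survival, seed = 202) else ap$pop
    .fixtures$dsb[[key]] <- total_dsb(tally_yields(pop, ap$cfg))
  }
  .fixtures$dsb[[key]]
}

## Oxygen parameters fitted to the OER endpoint and the 0.1%-O2 row,
## shared across the oxygen-dependent acceptance checks.
acc_oxygen <- function() {
  if (is.null(.fixtures$oxy))
    .fixtures$oxy <- calibrate_oxygen(acceptance_model(), seed = 303)
  .fixtures$oxy
}

## Helium quality anchored at zero-DMSO RBE 2.9, plus its own baseline
## population at acceptance scale.
acc_helium <- function() {
  if (is.null(.fixtures$helium)) {
    q <- anchor_rbe_quality(acceptance_model(), rbe0 = 2.9,
                            multiplicity_nu = 3, seed = 404)
    cfg <- simulation_config(n_clusters = 2e6, seed = 505)
    pop <- generate_clusters(q, cfg)
    .fixtures$helium <- list(quality = q, pop = pop, cfg = cfg)
  }
  .fixtures$helium
}

yields_named_for_test <- function(y) {
  v <- c(y$table$yield, y$totals$yield)
  names(v) <- c(y$table$class, rownames(y$totals))
  v
}
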