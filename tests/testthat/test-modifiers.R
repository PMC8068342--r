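test_that("DMSO survival factor follows the FNSD/CHMX hyperbola", {
  g <- scavenger_params(0.52, 0.21)
  expect_equal(dmso_survival_factor(0, g), 1)
  ## at c = CHMX the scavengeable component is halved
  expect_equal(dmso_survival_factor(0.21, g), 0.52 + 0.48 / 2)
  expect_equal(dmso_survival_factor(0.28, g), 0.52 + 0.48 * 0.21 / 0.49)
  expect_equal(dmso_survival_factor(1e9, g), 0.52, tolerance = 1e-6)
  ## monotone non-increasing, bounded on a dense grid
  s <- dmso_survival_factor(seq(0, 5, by = 0.01), g)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0.52 & s <= 1))
  expect_error(dmso_survival_factor(-0.1, g), ">= 0")
})

test_that("oxygen survival factor is a normalised increasing hyperbola", {
  ox <- oxygen_params(m_lesion = 1.75, k_o2 = 0.7, reference_o2 = 21)
  expect_equal(oxygen_survival_factor(21, ox), 1)
  h21 <- (1.75 * 21 + 0.7) / (21 + 0.7)
  expect_equal(oxygen_survival_factor(0.001, ox),
               ((1.75 * 0.001 + 0.7) / (0.001 + 0.7)) / h21)
  expect_gte(oxygen_survival_factor(100, ox), 1)
  s <- oxygen_survival_factor(seq(0, 100, by = 0.5), ox)
  expect_true(all(diff(s) >= 0))
  expect_error(oxygen_survival_factor(120, ox), "\\[0, 100\\]")
})

test_that("combined survival is the product of the two mechanisms", {
  q <- radiation_quality("q", 1, 600, 0.7, 0.2, 25,
                         scavenger = scavenger_preset("proton62MeV"))
  env <- environment_condition(0.1, 2)
  expect_equal(combined_survival(env, q),
               dmso_survival_factor(0.1, q$scavenger) *
                 oxygen_survival_factor(2, q$oxygen))
  expect_equal(combined_survival(environment_condition(0, 21), q), 1)
  expect_equal(combined_survival(environment_condition(0.1, 21), q),
               0.52 + 0.48 * 0.07 / 0.17)
})

test_that("thinning retains lesions at the requested Bernoulli rate", {
  q <- radiation_quality("q", 1, 10, 0, 0.3, 25)
  pop <- generate_clusters(q, simulation_config(n_clusters = 1e5, seed = 5))
  expect_identical(thin_lesions(pop, 1, seed = 1)$cluster, pop$cluster)
  expect_identical(n_lesions(thin_lesions(pop, 0, seed = 1)), 0L)
  kept <- n_lesions(thin_lesions(pop, 0.5, seed = 1)) / 1e5
  expect_lt(abs(kept - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("sequential thinning composes multiplicatively", {
  q <- radiation_quality("q", 1, 10, 0, 0.3, 25)
  pop <- generate_clusters(q, simulation_config(n_clusters = 1e5, seed = 6))
  two_step <- thin_lesions(thin_lesions(pop, 0.8, seed = 2), 0.7, seed = 3)
  one_step <- thin_lesions(pop, 0.56, seed = 4)
  p1 <- n_lesions(two_step) / 1e5
  p2 <- n_lesions(one_step) / 1e5
  se <- sqrt(2 * 0.56 * 0.44 / 1e5)
  expect_lt(abs(p1 - p2), 3 * se)
  expect_equal(two_step$meta$survival, 0.56)
})

test_that("common random numbers couple thinnings monotonically", {
  q <- radiation_quality("q", 1, 600, 0.8, 0.2, 25)
  pop <- generate_clusters(q, simulation_config(n_clusters = 5e4, seed = 7))
  key <- function(p) paste(p$cluster, p$position, p$strand, p$is_break)
  lo <- thin_lesions(pop, 0.4, seed = 11)
  hi <- thin_lesions(pop, 0.8, seed = 11)
  expect_true(all(key(lo) %in% key(hi)))
  ## hence every class-total yield is monotone in survival
  cfg <- simulation_config(genome_gbp = 1)
  for (cls in c("total_damage", "total_SSB", "total_DSB", "BD")) {
    expect_lte(yield_entry(tally_yields(lo, cfg, meta = list(genome_gbp = 1)), cls)[["value"]],
               yield_entry(tally_yields(hi, cfg, meta = list(genome_gbp = 1)), cls)[["value"]])
  }
})

test_that("thinning hits complex damage harder than simple damage", {
  ## class migration: percent reduction of total DSB >= that of BD
  q <- radiation_quality("q", 1, 616, 0.8, 0.2, 25)
  cfg <- simulation_config(n_clusters = 2e5, seed = 8)
  pop <- generate_clusters(q, cfg)
  y0 <- tally_yields(pop, cfg)
  for (s in c(0.9, 0.7, 0.5, 0.3)) {
    y1 <- tally_yields(thin_lesions(pop, s, seed = 8), cfg)
    red <- function(cls) percent_reduction(yield_entry(y0, cls)[["value"]],
                                           yield_entry(y1, cls)[["value"]])
    expect_gte(red("total_DSB"), red("BD"))
  }
})

test_that("forced survival endpoints behave as identity and annihilation", {
  q <- radiation_quality("q", 1, 600, 0.7, 0.2, 25)
  cfg <- simulation_config(n_clusters = 2e4, seed = 10)
  y0 <- simulate_damage_spectrum(q, environment_condition(0, 21), cfg)
  y1 <- simulate_damage_spectrum(q, config = cfg, survival = 1)
  expect_equal(yields_named_for_test(y0), yields_named_for_test(y1))
  yz <- simulate_damage_spectrum(q, config = cfg, survival = 0)
  expect_true(all(yz$table$yield == 0))
})
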