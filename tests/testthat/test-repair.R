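test_that("repair outcome structure: breaks religate, lone base damage repairs correctly", {
  p <- repair_params("SP_BER", q_bypass = 0.5)
  ## strand breaks only: nothing to bypass, no mutation possible
  for (s in 1:20) {
    out <- repair_cluster(c(3, 20), c(0, 1), c(TRUE, TRUE), p, seed = s)
    expect_identical(out$category, "correct")
  }
  ## isolated single base damage: no opposing lesion, always correct
  out <- repair_cluster(5, 0, FALSE, p, seed = 1)
  expect_identical(out$category, "correct")
  expect_identical(out$n_substitutions, 0L)
  ## DSB-class clusters are out of scope
  expect_error(repair_cluster(c(5, 8), c(0, 1), c(TRUE, TRUE), p), "non-DSB")
})

test_that("opposed same-position base damages mutate with exactly probability q", {
  ## whichever damage is excised first, its 1-nt patch covers the other:
  ## exactly one bypass incidence, so P(mutation) = q_bypass
  p <- repair_params("SP_BER", q_bypass = 0.25)
  want <- oracle_repair(c(5, 5), c(0, 1), c(FALSE, FALSE), p)
  expect_equal(unname(want["point_mutation"]), 0.25)
  set.seed(99)
  hits <- mean(vapply(1:2000, function(s)
    repair_cluster(c(5, 5), c(0, 1), c(FALSE, FALSE), p,
                   seed = s)$category == "point_mutation", logical(1)))
  expect_lt(abs(hits - 0.25), 4 * sqrt(0.25 * 0.75 / 2000))
})

test_that("repair simulation matches the exhaustive enumeration oracle", {
  cases <- list(
    ## two opposed base damages 3 bp apart: SP patch misses, LP may cover
    list(pos = c(5, 8), str = c(0, 1), brk = c(FALSE, FALSE), pw = "SP_BER"),
    list(pos = c(5, 8), str = c(0, 1), brk = c(FALSE, FALSE), pw = "LP_BER"),
    ## base damage facing an open break within 10 bp: conversion possible
    list(pos = c(5, 9), str = c(0, 1), brk = c(FALSE, TRUE), pw = "SP_BER"),
    ## three lesions, hybrid routing
    list(pos = c(2, 6, 9), str = c(0, 1, 0), brk = c(FALSE, FALSE, FALSE),
         pw = "NER_SP_BER"))
  nrep <- 1500
  for (cs in cases) {
    p <- repair_params(cs$pw, q_bypass = 0.3, p_ner = 0.4)
    want <- oracle_repair(cs$pos, cs$str, cs$brk, p)
    got <- table(factor(vapply(seq_len(nrep), function(s)
      repair_cluster(cs$pos, cs$str, cs$brk, p, seed = 7000 + s)$category,
      character(1)), levels = names(want))) / nrep
    for (cat in names(want)) {
      se <- sqrt(max(want[cat] * (1 - want[cat]), 1e-4) / nrep)
      expect_lt(abs(got[cat] - want[cat]), 4 * se,
                label = sprintf("%s / %s: got %.3f want %.3f",
                                cs$pw, cat, got[cat], want[cat]))
    }
  }
})

test_that("a base damage opposite a nearby open break can convert to a repair DSB", {
  p <- repair_params("SP_BER")
  ## order (bd first) -> transient gap within 10 bp of the open break ->
  ## conversion; order (break first) -> religated before the gap opens.
  want <- oracle_repair(c(5, 9), c(0, 1), c(FALSE, TRUE), p)
  expect_equal(unname(want["repair_dsb"]), 0.5)
  ## far-apart opposite pair (2SSB distance) never converts under SP
  far <- oracle_repair(c(0, 24), c(0, 1), c(FALSE, TRUE), p)
  expect_equal(unname(far["repair_dsb"]), 0)
})

test_that("zero bypass probability forces zero mutation frequency", {
  q <- radiation_quality("q", 1, 616, 0.8, 0.2, 25)
  cfg <- simulation_config(n_clusters = 2e4, seed = 21)
  pop <- generate_clusters(q, cfg)
  mf <- mutation_frequency(pop, repair_params("NER_LP_BER", q_bypass = 0),
                           cfg, seed = 1)
  expect_identical(mf$value, 0)
  ## and populations with no base damages cannot mutate either
  brk_only <- make_toy_clusters(replicate(50,
    data.frame(position = c(2, 20), strand = c(0, 1), kind = "break"),
    simplify = FALSE), nseg = 25)
  mf2 <- mutation_frequency(brk_only, repair_params("NER_LP_BER"),
                            simulation_config(genome_gbp = 1), seed = 1)
  expect_identical(mf2$value, 0)
})

test_that("mutation frequency of a toy population equals the enumeration", {
  ## 1-cluster population with the exact-q pair: value = q * per_cell / denom
  pop <- make_toy_clusters(list(
    data.frame(position = c(5, 5), strand = c(0, 1), kind = "bd")), nseg = 25)
  p <- repair_params("SP_BER", q_bypass = 0.25)
  cfg <- simulation_config(dose = 2, genome_gbp = 1, per_cell_factor = 6)
  mf <- mutation_frequency(pop, p, cfg, seed = 3)
  expect_equal(mf$value, 0.25 / 2 * 6)
  expect_identical(mf$n_clusters, 1L)
})

test_that("mutation frequency is monotone under coupled lesion thinning", {
  q <- radiation_quality("q", 1, 616, 0.8, 0.2, 25)
  cfg <- simulation_config(n_clusters = 5e4, seed = 22)
  pop <- generate_clusters(q, cfg)
  p <- repair_params("NER_LP_BER", q_bypass = 0.01)
  vals <- vapply(c(1, 0.8, 0.6, 0.4), function(s) {
    thinned <- if (s < 1) thin_lesions(pop, s, seed = 22) else pop
    mutation_frequency(thinned, p, cfg, seed = 23)$value
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("pathway sweep is monotone in DMSO and constant when survival is forced", {
  q <- radiation_quality("q", 1, 616, 0.8, 0.2, 25,
                         scavenger = scavenger_preset("proton62MeV"))
  sw <- pathway_sweep(q, dmso_grid = c(0, 0.2, 1),
                      config = simulation_config(n_clusters = 3e4, seed = 24),
                      repair_args = list(q_bypass = 0.01))
  for (pw in unique(sw$pathway)) {
    v <- sw$value[sw$pathway == pw]
    expect_true(all(diff(v) <= 0), label = pw)
  }
  ## degenerate scavenger (fnsd ~ 1) leaves frequencies unchanged
  q1 <- q; q1$scavenger <- scavenger_params(1, 0.07)
  sw1 <- pathway_sweep(q1, dmso_grid = c(0, 0.5),
                       config = simulation_config(n_clusters = 2e4, seed = 25),
                       pathways = "LP_BER", repair_args = list(q_bypass = 0.01))
  expect_equal(sw1$value[1], sw1$value[2])
})
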