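test_that("classification handles the canonical single- and two-lesion cases", {
  expect_identical(classify_cluster(100, 0, TRUE), "SSB")
  expect_identical(classify_cluster(100, 0, FALSE), "BD")
  expect_identical(classify_cluster(integer(), integer(), logical()), "EMPTY")
  ## 10-bp opposition rule
  expect_identical(classify_cluster(c(100, 106), c(0, 1), c(TRUE, TRUE)), "DSB")
  expect_identical(classify_cluster(c(100, 110), c(0, 1), c(TRUE, TRUE)), "DSB")
  expect_identical(classify_cluster(c(100, 111), c(0, 1), c(TRUE, TRUE)), "2SSB")
  expect_identical(classify_cluster(c(100, 120), c(0, 1), c(TRUE, TRUE)), "2SSB")
  expect_identical(classify_cluster(c(100, 104), c(0, 0), c(TRUE, TRUE)), "SSB+")
  ## base damages never change a strand-break-bearing class
  expect_identical(classify_cluster(c(100, 103, 106), c(0, 0, 1),
                                    c(TRUE, FALSE, TRUE)), "DSB")
})

test_that("complex multi-break clusters split into DSB+ and DSB++", {
  expect_identical(classify_cluster(c(100, 103, 106), c(0, 0, 1),
                                    c(TRUE, TRUE, TRUE)), "DSB+")
  expect_identical(classify_cluster(c(100, 103, 108, 110), c(0, 1, 0, 1),
                                    rep(TRUE, 4)), "DSB++")
})

test_that("classification agrees with the maximum-matching oracle on small clusters", {
  set.seed(42)
  for (rep in 1:600) {
    cl <- random_cluster(max_lesions = 5, max_pos = 29)
    got <- classify_cluster(cl$position, cl$strand, cl$is_break)
    want <- oracle_classify(cl$position, cl$strand, cl$is_break)
    expect_identical(got, want,
                     label = sprintf("pos=%s strand=%s brk=%s -> %s (oracle %s)",
                                     toString(cl$position), toString(cl$strand),
                                     toString(cl$is_break), got, want))
  }
})

test_that("vectorised classification matches the scalar classifier", {
  set.seed(7)
  recipe <- replicate(400, {
    cl <- random_cluster()
    data.frame(position = cl$position, strand = cl$strand,
               kind = ifelse(cl$is_break, "break", "bd"))
  }, simplify = FALSE)
  pop <- make_toy_clusters(recipe, nseg = 30)
  vec <- as.character(classify_clusters(pop))
  for (i in seq_along(recipe)) {
    r <- recipe[[i]]
    expect_identical(vec[i],
                     classify_cluster(r$position, r$strand, r$kind == "break"))
  }
})

test_that("single-lesion populations only produce BD and SSB", {
  q <- radiation_quality("q", 1, 10, multiplicity_nu = 0,
                         p_strand_break = 0.4, nseg = 25)
  pop <- generate_clusters(q, simulation_config(n_clusters = 2e4, seed = 3))
  expect_true(all(classify_clusters(pop) %in% c("BD", "SSB")))
})

test_that("yields normalise counts by dose and genome with Poisson errors", {
  ## 10 SSB clusters at 2 Gy over 1 Gbp
  recipe <- replicate(10, data.frame(position = 5, strand = 0, kind = "break"),
                      simplify = FALSE)
  pop <- make_toy_clusters(recipe, nseg = 25)
  y <- tally_yields(pop, simulation_config(dose = 2, genome_gbp = 1))
  expect_equal(yield_entry(y, "SSB"), c(value = 5, se = sqrt(10) / 2))
  expect_equal(yield_entry(y, "BD")[["value"]], 0)
  expect_error(tally_yields(pop, simulation_config(dose = 2, n_clusters = 5)),
               "genome size")
})

test_that("yield totals conserve counts and empty populations give zero yields", {
  empty <- make_toy_clusters(list())
  y0 <- tally_yields(empty, simulation_config(genome_gbp = 1))
  expect_true(all(y0$table$yield == 0))
  q <- radiation_quality("q", 1, 600, 0.7, 0.2, 25)
  cfg <- simulation_config(n_clusters = 5e4, seed = 9)
  y <- tally_yields(generate_clusters(q, cfg), cfg)
  expect_equal(y$totals["total_SSB", "count"],
               sum(y$table$count[y$table$class %in% c("SSB", "SSB+", "2SSB")]))
  expect_equal(y$totals["total_DSB", "count"],
               sum(y$table$count[y$table$class %in% c("DSB", "DSB+", "DSB++")]))
  expect_equal(y$totals["total_damage", "count"], sum(y$table$count))
  expect_equal(y$totals["total_damage", "count"], 5e4)  # one site per cluster
  expect_equal(y$totals["total_damage", "yield"],
               sum(y$table$yield), tolerance = 1e-12)
})
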