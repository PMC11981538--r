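test_that("generation is deterministic in the seed and validates analysis-ready", {
  spec <- synthetic_web_spec(seed = 99)
  w1 <- generate_niche_web(spec)
  w2 <- generate_niche_web(spec)
  expect_identical(w1$edges, w2$edges)
  a1 <- assign_attributes(w1, spec)
  a2 <- assign_attributes(w2, spec)
  expect_identical(a1$nodes, a2$nodes)
  expect_true(validate_analysis_ready(a1))
  # a different seed gives a different web
  w3 <- generate_niche_web(synthetic_web_spec(seed = 100))
  expect_false(identical(w1$edges, w3$edges))
  # seeded attribute files are byte-identical on rerun
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  e1 <- withr::local_tempfile(fileext = ".csv")
  e2 <- withr::local_tempfile(fileext = ".csv")
  write_food_web(a1, e1, f1)
  write_food_web(a2, e2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(e1), readLines(e2))
})

test_that("degenerate and invalid specs are handled", {
  one <- generate_niche_web(synthetic_web_spec(n_nodes = 1, seed = 1))
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
  expect_error(synthetic_web_spec(connectance = 0), "connectance")
  expect_error(synthetic_web_spec(n_basal_min = 0), "n_basal_min")
  expect_error(synthetic_web_spec(n_nodes = 4, n_basal_min = 5), "exceeds")
  expect_error(generate_niche_web(synthetic_web_spec(n_nodes = 10,
                                                     connectance = 0.95)),
               "infeasible")
  expect_error(generate_disturbance_pair(synthetic_web_spec(seed = 1),
                                         basal_replace = 1.2), "\\[0, 1\\]")
})

test_that("generated webs respect the basal floor and are acyclic and loop-free", {
  for (seed in 1:10) {
    spec <- synthetic_web_spec(seed = seed, n_nodes = 20, n_basal_min = 4)
    w <- generate_niche_web(spec)
    expect_false(any(w$edges$prey == w$edges$predator))
    basal <- w$nodes$name[!(w$nodes$name %in% w$edges$predator)]
    expect_gte(length(basal), 4)
    expect_true(check_connected(w)$connected)
    # acyclic: the DP oracle must terminate
    aw <- assign_attributes(w, spec)
    expect_no_error(tl_dag_oracle(aw))
  }
})

test_that("realized undirected density of the raw sampler is unbiased for the target", {
  target <- 0.217
  spec <- synthetic_web_spec(n_nodes = 23, connectance = target, seed = 1234)
  reps <- 200
  dens <- vapply(seq_len(reps), function(i) {
    s <- synthetic_web_spec(n_nodes = 23, connectance = target,
                            seed = 1234 + i)
    network_density(symmetrize(generate_niche_web(s, connected = FALSE)))
  }, numeric(1))
  se <- sd(dens) / sqrt(reps)
  expect_lt(abs(mean(dens) - target), 2 * se)
})

test_that("attribute assignment follows the sampling contract", {
  spec <- synthetic_web_spec(seed = 5, biomass_logsd = 0, bodymass_logsd = 0)
  w <- assign_attributes(generate_niche_web(spec), spec)
  basal <- w$nodes$name[!(w$nodes$name %in% w$edges$predator)]
  cons <- setdiff(w$nodes$name, basal)
  expect_true(all(w$nodes$biomass[match(basal, w$nodes$name)] == 1))
  expect_true(all(w$nodes$category[match(basal, w$nodes$name)] %in%
                    c("producer", "cyanobacteria", "detritus")))
  expect_true(all(w$nodes$category[match(cons, w$nodes$name)] == "animal"))
  # zero log-sd: all consumers share one biomass and one body mass
  expect_equal(length(unique(w$nodes$biomass[match(cons, w$nodes$name)])), 1)
  expect_equal(length(unique(w$nodes$body_mass[match(cons, w$nodes$name)])), 1)
})

test_that("disturbance pairs share the stated node fraction and stay connected", {
  spec <- synthetic_web_spec(seed = 21)
  none <- generate_disturbance_pair(spec, basal_replace = 0,
                                    consumer_turnover = 0)
  expect_identical(none$baseline$edges, none$perturbed$edges)
  expect_identical(none$baseline$nodes, none$perturbed$nodes)

  pair <- generate_disturbance_pair(spec, basal_replace = 1,
                                    consumer_turnover = 0.2)
  b <- pair$baseline; p <- pair$perturbed
  basal_b <- b$nodes$name[!(b$nodes$name %in% b$edges$predator)]
  basal_p <- p$nodes$name[!(p$nodes$name %in% p$edges$predator)]
  expect_length(intersect(basal_b, basal_p), 0)   # full basal replacement
  shared <- intersect(b$nodes$name, p$nodes$name)
  n_cons <- nrow(b$nodes) - length(basal_b)
  expect_equal(length(shared),
               nrow(b$nodes) - length(basal_b) - round(0.2 * n_cons))
  expect_true(check_connected(p)$connected)
  expect_true(validate_analysis_ready(p))
})

test_that("the full pipeline runs clean on a panel of seeded webs", {
  for (seed in 1:25) {
    w <- synth_web(seed = seed, n = 15)
    gm <- global_metrics(symmetrize(w))
    expect_true(all(is.finite(gm$value)))
    tl <- suppressWarnings(trophic_levels(w))
    expect_true(all(unclass(tl) >= 1))
    # consumers feeding only on basal nodes sit exactly at TL 2
    basal <- basal_nodes(w, warn = FALSE)
    for (j in setdiff(w$nodes$name, basal)) {
      prey <- w$edges$prey[w$edges$predator == j]
      if (all(prey %in% basal))
        expect_equal(unclass(tl)[[j]], 2, tolerance = 1e-12)
    }
    fm <- energy_fluxes(w)
    expect_true(all(fm$fluxes >= 0))
  }
})
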