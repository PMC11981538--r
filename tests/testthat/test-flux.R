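test_that("metabolic losses follow the allometry and basal-zero convention", {
  web <- food_web(
    edges = data.frame(prey = c("Plant", "Plant"), predator = c("A", "B")),
    nodes = data.frame(name = c("Plant", "A", "B"),
                       category = c("producer", "animal", "animal"),
                       biomass = c(NA, 1, 2), body_mass = c(NA, 1, 16)))
  X <- metabolic_losses(web, flux_parameters())
  expect_equal(unname(X["Plant"]), 0)
  expect_equal(unname(X["A"]), 0.71)            # M^b = 1
  expect_equal(unname(X["B"]), 0.71)            # 0.71 * 16^-0.25 * 2 = 0.71
  expect_error(metabolic_losses(chain_web(3)), "lack biomass")
})

test_that("feeding preferences are biomass-scaled and column-normalized", {
  web <- food_web(
    edges = data.frame(prey = c("P1", "P2", "P1"), predator = c("C", "C", "D")),
    nodes = data.frame(name = c("P1", "P2", "C", "D")))
  W <- preference_matrix(web, c(P1 = 3, P2 = 1, C = 1, D = 1))
  expect_equal(unname(W[c("P1", "P2"), "C"]), c(0.75, 0.25))
  expect_equal(unname(W["P1", "D"]), 1)
  Wu <- preference_matrix(web, c(P1 = 2, P2 = 2, C = 1, D = 1))
  expect_equal(unname(Wu[c("P1", "P2"), "C"]), c(0.5, 0.5))
  expect_error(preference_matrix(web, c(P1 = 0, P2 = 0, C = 1, D = 1)),
               "all-zero")
})

test_that("a single-link web is forced by the balance F * e = X", {
  web <- food_web(
    edges = data.frame(prey = "Plant", predator = "Grazer"),
    nodes = data.frame(name = c("Plant", "Grazer"),
                       category = c("producer", "animal"),
                       biomass = c(NA, 1), body_mass = c(NA, 1)))
  # choose a, b so X_grazer = 0.545 = e_plant; then F = X / e = 1
  fm <- energy_fluxes(web, flux_parameters(a = 0.545, b = 0))
  expect_equal(unname(fm$fluxes["Plant", "Grazer"]), 1.0, tolerance = 1e-12)
})

test_that("a three-level chain matches the independent two-unknown solve", {
  web <- food_web(
    edges = data.frame(prey = c("Detritus", "Worm"),
                       predator = c("Worm", "Fish")),
    nodes = data.frame(name = c("Detritus", "Worm", "Fish"),
                       category = c("detritus", "animal", "animal"),
                       biomass = c(NA, 4, 1), body_mass = c(NA, 0.1, 20)))
  p <- flux_parameters()
  fm <- energy_fluxes(web, p)
  X_w <- p$a * 0.1^p$b * 4
  X_f <- p$a * 20^p$b * 1
  # back-substitute by hand: G_f e_animal = X_f ; G_w e_detritus = X_w + G_f
  G_f <- X_f / p$efficiencies[["animal"]]
  G_w <- (X_w + G_f) / p$efficiencies[["detritus"]]
  expect_equal(unname(fm$fluxes["Detritus", "Worm"]), unname(G_w),
               tolerance = 1e-12)
  expect_equal(unname(fm$fluxes["Worm", "Fish"]), unname(G_f),
               tolerance = 1e-12)
})

test_that("flux balance, nonnegativity and support hold on synthetic webs", {
  for (seed in 1:8) {
    web <- synth_web(seed = seed, n = 18)
    fm <- energy_fluxes(web)
    res <- flux_balance_residuals(fm)
    X <- fm$losses[names(res)]
    expect_true(all(abs(res) < 1e-9 * (1 + abs(X))))
    expect_true(all(fm$fluxes >= 0))
    A <- as.matrix(fm$web)
    expect_true(all(fm$fluxes[A == 0] == 0))   # flux only on edges
  }
})

test_that("fluxes are exactly linear in the metabolic losses", {
  web <- synth_web(seed = 3, n = 15)
  p1 <- flux_parameters()
  p2 <- flux_parameters(a = p1$a * 3.7)        # scales every X by 3.7
  f1 <- energy_fluxes(web, p1)$fluxes
  f2 <- energy_fluxes(web, p2)$fluxes
  expect_equal(f2, 3.7 * f1, tolerance = 1e-10)
})

test_that("the dense solve equals leaf-to-root recursion on tree webs", {
  # a branching tree: two plants -> two herbivores -> one top predator
  tree <- food_web(
    edges = data.frame(prey = c("P1", "P2", "H1", "H2"),
                       predator = c("H1", "H2", "T", "T")),
    nodes = data.frame(name = c("P1", "P2", "H1", "H2", "T"),
                       category = c("producer", "producer", "animal", "animal",
                                    "animal"),
                       biomass = c(NA, NA, 5, 2, 1),
                       body_mass = c(NA, NA, 0.5, 0.2, 30)))
  fm <- energy_fluxes(tree)
  expect_equal(fm$fluxes, flux_dag_oracle(tree), tolerance = 1e-10)
  # and on generated acyclic webs (generalized predator-first recursion)
  for (seed in 4:6) {
    web <- synth_web(seed = seed, n = 14)
    expect_equal(energy_fluxes(web)$fluxes, flux_dag_oracle(web),
                 tolerance = 1e-9)
  }
})

test_that("nodes without data are dropped generically and off-path fluxes are stable", {
  web <- food_web(
    edges = data.frame(prey = c("P", "P", "A", "NoData"),
                       predator = c("A", "NoData", "Top", "Top2")),
    nodes = data.frame(
      name = c("P", "A", "NoData", "Top", "Top2"),
      category = c("producer", "animal", "animal", "animal", "animal"),
      biomass = c(NA, 2, NA, 1, 1), body_mass = c(NA, 1, NA, 8, 8)))
  expect_warning(fm <- energy_fluxes(web), "NoData")
  expect_false("NoData" %in% rownames(fm$fluxes))
  # Top2 lost its only prey and is treated as basal (zero loss, no inflow)
  expect_true("Top2" %in% fm$basal)
  # the P -> A -> Top pathway is unaffected by the drop
  alone <- food_web(
    edges = data.frame(prey = c("P", "A"), predator = c("A", "Top")),
    nodes = web$nodes[web$nodes$name %in% c("P", "A", "Top"), ])
  fa <- energy_fluxes(alone)
  expect_equal(fm$fluxes[c("P", "A"), c("A", "Top")],
               fa$fluxes[c("P", "A"), c("A", "Top")], tolerance = 1e-12)
})

test_that("flux summaries and the log10 display follow their definitions", {
  F1 <- matrix(c(0, 5, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  s <- flux_summaries(F1)
  expect_equal(s$n_fluxes, 1)
  expect_equal(s$diversity, 0)                 # one flux only
  k <- 7
  Fk <- diag(0, k + 1)
  Fk[1, 2:(k + 1)] <- 2.5                      # k equal fluxes
  expect_equal(flux_summaries(Fk)$diversity, log(k))
  set.seed(9)
  M <- matrix(runif(100) * (runif(100) > 0.5), 10)
  p <- M[M > 0] / sum(M)
  expect_equal(flux_summaries(M)$diversity, -sum(p * log(p)))
  expect_error(flux_summaries(matrix(0, 2, 2)), "zero")

  L <- flux_log10(matrix(c(0, 1, 1000, 0), 2))
  expect_equal(sort(L[is.finite(L)]), c(0, 3))
  expect_true(all(is.na(L[c(1, 4)])))          # structural zeros, never -Inf
  # trophic ordering of the display matrix
  web <- synth_web(seed = 2, n = 12)
  fm <- energy_fluxes(web)
  disp <- flux_log10(fm)
  tl <- unclass(trophic_levels(web))[rownames(disp)]
  expect_true(all(diff(tl) >= 0))
})
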