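test_that("basal identification follows the category and no-prey conventions", {
  web <- chain_web(3)
  expect_equal(basal_nodes(web), "c01")

  # detritus stays basal even with donor links into it
  don <- food_web(
    edges = data.frame(prey = c("Detritus", "Worm", "Plant"),
                       predator = c("Worm", "Detritus", "Worm")),
    nodes = data.frame(name = c("Detritus", "Worm", "Plant"),
                       category = c("detritus", "animal", "producer")))
  expect_equal(basal_nodes(don), c("Detritus", "Plant"))
  tl <- trophic_levels(don)
  expect_equal(unname(unclass(tl)[c("Detritus", "Plant", "Worm")]), c(1, 1, 2))

  two <- food_web(
    edges = data.frame(prey = c("P1", "P2"), predator = c("H", "H")),
    nodes = data.frame(name = c("P1", "P2", "H"),
                       category = c("producer", "producer", "animal")))
  expect_setequal(basal_nodes(two), c("P1", "P2"))

  dangling <- food_web(
    edges = data.frame(prey = "P", predator = "H"),
    nodes = data.frame(name = c("P", "H", "Lost"),
                       category = c("producer", "animal", "animal")))
  expect_warning(b <- basal_nodes(dangling), "dangling")
  expect_true("Lost" %in% b)
})

test_that("the linear solve reproduces chain and fan closed forms", {
  expect_equal(as.numeric(trophic_levels(chain_web(3))), c(1, 2, 3))
  expect_equal(as.numeric(trophic_levels(chain_web(6))), as.numeric(1:6))

  two_basal <- food_web(
    edges = data.frame(prey = c("P1", "P2"), predator = c("C", "C")),
    nodes = data.frame(name = c("P1", "P2", "C"),
                       category = c("producer", "producer", "animal")))
  expect_equal(unname(unclass(trophic_levels(two_basal))["C"]), 2.0)
})

test_that("the solve equals bottom-up dynamic programming on acyclic webs", {
  for (seed in 1:10) {
    web <- synth_web(seed = seed, n = 20)
    tl <- suppressWarnings(trophic_levels(web))
    oracle <- tl_dag_oracle(web)
    expect_equal(unclass(tl)[names(oracle)], oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(unclass(tl) >= 1))
    expect_lte(max(unclass(tl)), nrow(web$nodes))
  }
})

test_that("fixed-point iteration converges to the solve on omnivory loops", {
  # mutual predation between two consumers, both partly feeding on a plant
  loop <- food_web(
    edges = data.frame(prey = c("P", "P", "A", "B"),
                       predator = c("A", "B", "B", "A")),
    nodes = data.frame(name = c("P", "A", "B"),
                       category = c("producer", "animal", "animal")))
  tl <- unclass(trophic_levels(loop))
  # iterate TL <- 1 + Q TL from TL = 1
  nm <- names(tl)
  cur <- setNames(rep(1, 3), nm)
  for (it in 1:200) {
    nxt <- cur
    nxt["A"] <- 1 + mean(cur[c("P", "B")])
    nxt["B"] <- 1 + mean(cur[c("P", "A")])
    cur <- nxt
  }
  expect_equal(cur, tl, tolerance = 1e-8, ignore_attr = TRUE)
  # balance holds exactly at the solution
  expect_equal(tl[["A"]], 1 + mean(tl[c("P", "B")]), tolerance = 1e-12)
})

test_that("a consumer's TL never rises when an extra basal prey is added", {
  for (seed in 1:5) {
    web <- synth_web(seed = seed, n = 12)
    cons <- setdiff(web$nodes$name, basal_nodes(web, warn = FALSE))
    target <- cons[length(cons)]
    before <- unclass(suppressWarnings(trophic_levels(web)))[[target]]
    nodes2 <- rbind(web$nodes[, c("name", "category", "functional_group",
                                  "biomass", "body_mass", "period")],
                    data.frame(name = "ExtraPlant", category = "producer",
                               functional_group = "ExtraPlant", biomass = 1,
                               body_mass = NA, period = NA))
    web2 <- food_web(rbind(web$edges,
                           data.frame(prey = "ExtraPlant", predator = target)),
                     nodes2)
    after <- unclass(suppressWarnings(trophic_levels(web2)))[[target]]
    expect_lte(after, before + 1e-12)
  }
})

test_that("ungrounded diet cycles are rejected with the offending nodes named", {
  cyc <- food_web(
    edges = data.frame(prey = c("A", "B"), predator = c("B", "A")),
    nodes = data.frame(name = c("A", "B"), category = c("animal", "animal")))
  expect_error(suppressWarnings(trophic_levels(cyc)), "A, B")
})

test_that("reference comparison flags values outside the accepted range", {
  tl <- setNames(c(3.64, 3.00, 2.5), c("Eel", "Mullet", "Shrimp"))
  ref <- data.frame(node = c("Eel", "Mullet", "Shrimp"),
                    tl = c(3.39, 2.65, 2.5),
                    tolerance = c(0.3, 0.25, NA))
  rep <- compare_trophic_reference(tl, ref)
  expect_equal(rep$within, c(TRUE, FALSE, TRUE))
  expect_equal(rep$delta, c(0.25, 0.35, 0))
})

test_that("biomass-weighted diet shares shift TL toward the abundant prey", {
  web <- food_web(
    edges = data.frame(prey = c("P", "H", "P"), predator = c("H", "C", "C")),
    nodes = data.frame(name = c("P", "H", "C"),
                       category = c("producer", "animal", "animal"),
                       biomass = c(9, 1, 1)))
  equal <- unclass(trophic_levels(web))[["C"]]      # 1 + (1+2)/2 = 2.5
  wtd <- unclass(trophic_levels(web, share = "biomass"))[["C"]]
  expect_equal(equal, 2.5)
  expect_equal(wtd, 1 + (9 * 1 + 1 * 2) / 10)       # 2.1
})
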