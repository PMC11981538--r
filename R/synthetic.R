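#' Specification of a synthetic food web
#'
#' Parameters for the niche-interval generator and the attribute sampler.
#' Defaults emulate the scale of aggregated coastal-lagoon webs: 23 nodes,
#' target undirected density 0.217, at least 3 basal nodes, lognormal
#' biomasses spanning ~1 g zooplankton pools to ~1 kg fish stocks and body
#' masses spanning mg to kg.
#'
#' @param n_nodes node count.
#' @param connectance target undirected density `2L/(N(N-1))` of the
#'   symmetrized web, in (0, 1).
#' @param seed integer seed; one seed governs topology and attributes.
#' @param n_basal_min minimum number of basal nodes (>= 1; default 3,
#'   clamped to `n_nodes` for very small webs).
#' @param biomass_logmean,biomass_logsd lognormal parameters for consumer
#'   total biomass (g).
#' @param bodymass_logmean,bodymass_logsd lognormal parameters for consumer
#'   mean body mass (g).
#' @param basal_categories named probability vector over
#'   `producer`/`cyanobacteria`/`detritus` for basal node categories.
#' @param max_retries bound on connectivity resampling attempts.
#' @return a list of class `synthetic_web_spec`.
#' @export
synthetic_web_spec <- function(n_nodes = 23, connectance = 0.217, seed = 1,
                               n_basal_min = min(3, n_nodes),
                               biomass_logmean = 4, biomass_logsd = 1.5,
                               bodymass_logmean = 0, bodymass_logsd = 2,
                               basal_categories = c(producer = 0.5,
                                                    cyanobacteria = 0.25,
                                                    detritus = 0.25),
                               max_retries = 1000) {
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  if (connectance <= 0 || connectance >= 1) stop("connectance must be in (0, 1)")
  if (n_basal_min < 1) stop("n_basal_min must be >= 1")
  if (n_basal_min > n_nodes) stop("n_basal_min exceeds n_nodes")
  if (biomass_logsd < 0 || bodymass_logsd < 0) stop("log-sd parameters must be >= 0")
  if (!all(names(basal_categories) %in% .basal_categories))
    stop("basal_categories must be named by ",
         paste(.basal_categories, collapse = ", "))
  if (any(basal_categories < 0) || sum(basal_categories) <= 0)
    stop("basal_categories must be a nonnegative weight vector")
  structure(list(n_nodes = n_nodes, connectance = connectance,
                 seed = as.integer(seed), n_basal_min = n_basal_min,
                 biomass_logmean = biomass_logmean, biomass_logsd = biomass_logsd,
                 bodymass_logmean = bodymass_logmean, bodymass_logsd = bodymass_logsd,
                 basal_categories = basal_categories / sum(basal_categories),
                 max_retries = max_retries),
            class = "synthetic_web_spec")
}

# expected interval-width scale hitting the target undirected density
# exactly: with the m lowest-niche nodes forced basal and diet intervals of
# width r_j = x_j * n_j (x ~ Beta(1, 1/Ex - 1)) placed inside [0, n_j], each
# consumer contributes r_j * (N - 1) expected links, none mutual, so
# E[2L/(N(N-1))] = target when Ex = target * N(N+1) / (N(N+1) - m(m+1))
.niche_ex <- function(n, target, m) {
  ex <- target * n * (n + 1) / (n * (n + 1) - m * (m + 1))
  if (ex >= 1)
    stop("connectance ", target, " infeasible for n_nodes = ", n,
         " with ", m, " basal nodes")
  ex
}

.draw_niche_web <- function(spec) {
  n <- spec$n_nodes
  m <- min(spec$n_basal_min, n)
  nm <- sprintf("sp%0*d", max(2L, nchar(n)), seq_len(n))
  niche <- sort(runif(n))
  edges <- data.frame(prey = character(), predator = character())
  if (n > m) {
    ex <- .niche_ex(n, spec$connectance, m)
    beta <- 1 / ex - 1
    for (j in (m + 1):n) {
      r <- stats::rbeta(1, 1, beta) * niche[j]
      ctr <- runif(1, r / 2, max(r / 2, niche[j] - r / 2))
      prey <- setdiff(which(niche >= ctr - r / 2 & niche <= ctr + r / 2), j)
      if (length(prey))
        edges <- rbind(edges, data.frame(prey = nm[prey], predator = nm[j]))
    }
  }
  nodes <- data.frame(name = nm, niche = niche, stringsAsFactors = FALSE)
  food_web(edges, nodes, directed = TRUE, label = "synthetic")
}

#' Generate a niche-interval synthetic food web
#'
#' Draws niche values uniformly on (0, 1); the `n_basal_min` lowest-niche
#' nodes are forced basal (empty diet), every other node receives a
#' contiguous diet interval at or below its own niche position, with the
#' interval-width distribution calibrated so the expected undirected
#' density of the symmetrized web equals the target connectance. The
#' resulting webs are acyclic and self-loop free. With
#' `connected = TRUE` (the default for analysis-ready webs) draws are
#' resampled until the symmetrized web is a single component; note this
#' conditions the realized density upward — unbiasedness holds for the raw
#' sampler (`connected = FALSE`).
#'
#' @param spec a [synthetic_web_spec()].
#' @param connected resample (up to `spec$max_retries`) until connected.
#' @return a directed [food_web()]; its `nodes` table carries the niche
#'   values, and attribute `attempts` records the number of draws used.
#'   Fully reproducible from `spec$seed`.
#' @export
generate_niche_web <- function(spec, connected = TRUE) {
  stopifnot(inherits(spec, "synthetic_web_spec"))
  if (spec$n_nodes == 1) {
    w <- .with_seed(spec$seed, .draw_niche_web(spec))
    attr(w, "attempts") <- 1L
    return(w)
  }
  for (attempt in seq_len(spec$max_retries)) {
    w <- .with_seed(.derive_seed(spec$seed, attempt), .draw_niche_web(spec))
    if (!connected || check_connected(w)$connected) {
      attr(w, "attempts") <- attempt
      return(w)
    }
  }
  stop("no connected web in ", spec$max_retries, " draws (last draw had ",
       check_connected(w)$n_components, " components); raise connectance, ",
       "n_nodes or max_retries")
}

#' Assign ecological attributes to a synthetic topology
#'
#' Basal nodes (no prey) receive a category drawn from the spec's basal
#' category distribution and the placeholder biomass 1 (matching the
#' top-down flux convention); consumers are `animal` with lognormal
#' biomass and body mass. Reproducible from `spec$seed`; with zero log-sd
#' all consumers share identical values.
#'
#' @param web a [food_web()] from [generate_niche_web()].
#' @param spec the [synthetic_web_spec()] used to generate it.
#' @param categories optional probability vector overriding
#'   `spec$basal_categories` (used for perturbed regimes).
#' @return the web with `category`, `biomass`, `body_mass` filled in.
#' @export
assign_attributes <- function(web, spec, categories = NULL) {
  stopifnot(inherits(web, "food_web"), inherits(spec, "synthetic_web_spec"))
  probs <- if (is.null(categories)) spec$basal_categories
           else categories / sum(categories)
  .with_seed(.derive_seed(spec$seed, 7919L), {
    basal <- !(web$nodes$name %in% web$edges$predator)
    nodes <- web$nodes
    nodes$category <- NA_character_
    nodes$category[basal] <- sample(names(probs), sum(basal), replace = TRUE,
                                    prob = probs)
    nodes$category[!basal] <- "animal"
    nodes$biomass[basal] <- 1
    nodes$biomass[!basal] <- stats::rlnorm(sum(!basal), spec$biomass_logmean,
                                           spec$biomass_logsd)
    nodes$body_mass[!basal] <- stats::rlnorm(sum(!basal), spec$bodymass_logmean,
                                             spec$bodymass_logsd)
    food_web(web$edges, nodes, directed = web$directed, label = web$label)
  })
}

#' Generate a disturbance pair of food webs
#'
#' Emulates a before/after ecosystem contrast: a baseline web and a
#' perturbed web sharing most nodes, with a stated fraction of the basal
#' set replaced (e.g. macrophyte-like producers giving way to
#' cyanobacteria-like nodes) and a stated fraction of consumers turned
#' over. The perturbed web keeps the baseline topology (replaced nodes take
#' over the trophic position of their predecessors under new identities and
#' attributes), so both webs are connected by construction.
#'
#' @param spec a [synthetic_web_spec()].
#' @param basal_replace fraction of basal nodes replaced, in `[0, 1]`.
#' @param consumer_turnover fraction of consumers replaced, in `[0, 1]`.
#' @param post_basal_categories category distribution for replacement basal
#'   nodes (default shifts weight to cyanobacteria).
#' @return list with elements `baseline` and `perturbed` (both
#'   [food_web()]s) and `replaced` (character vector of baseline names that
#'   were replaced).
#' @export
generate_disturbance_pair <- function(spec, basal_replace = 1,
                                      consumer_turnover = 0.2,
                                      post_basal_categories = c(cyanobacteria = 0.6,
                                                                detritus = 0.3,
                                                                producer = 0.1)) {
  stopifnot(inherits(spec, "synthetic_web_spec"))
  if (basal_replace < 0 || basal_replace > 1 ||
      consumer_turnover < 0 || consumer_turnover > 1)
    stop("perturbation fractions must lie in [0, 1]")
  base <- assign_attributes(generate_niche_web(spec), spec)
  base$label <- "baseline"
  basal <- base$nodes$name[!(base$nodes$name %in% base$edges$predator)]
  cons <- setdiff(base$nodes$name, basal)
  nb <- round(basal_replace * length(basal))
  nc <- round(consumer_turnover * length(cons))

  repl <- .with_seed(.derive_seed(spec$seed, 104729L), {
    c(if (nb) sample(basal, nb), if (nc) sample(cons, nc))
  })
  if (length(repl) == 0) {
    pert <- base
    pert$label <- "perturbed"
    return(list(baseline = base, perturbed = pert, replaced = character()))
  }

  new_names <- stats::setNames(
    sprintf("nsp%0*d", max(2L, nchar(length(repl))), seq_along(repl)), repl)
  nodes <- base$nodes
  idx <- match(repl, nodes$name)
  nodes$name[idx] <- new_names[repl]
  nodes$functional_group[idx] <- new_names[repl]
  .with_seed(.derive_seed(spec$seed, 224737L), {
    is_b <- repl %in% basal
    pb <- post_basal_categories / sum(post_basal_categories)
    nodes$category[idx[is_b]] <- sample(names(pb), sum(is_b), replace = TRUE,
                                        prob = pb)
    nodes$biomass[idx[is_b]] <- 1
    nodes$body_mass[idx[is_b]] <- NA_real_
    nodes$biomass[idx[!is_b]] <- stats::rlnorm(sum(!is_b), spec$biomass_logmean,
                                               spec$biomass_logsd)
    nodes$body_mass[idx[!is_b]] <- stats::rlnorm(sum(!is_b), spec$bodymass_logmean,
                                                 spec$bodymass_logsd)
  })
  ed <- base$edges
  ed$prey <- ifelse(ed$prey %in% repl, new_names[ed$prey], ed$prey)
  ed$predator <- ifelse(ed$predator %in% repl, new_names[ed$predator], ed$predator)
  pert <- food_web(ed, nodes, directed = TRUE, label = "perturbed")
  list(baseline = base, perturbed = pert, replaced = unname(repl))
}
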