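#' Parameters of the energy-flux model
#'
#' Bundles the inputs of the flux-balance solve: assimilation efficiencies
#' by prey category, the allometric scaling of per-gram metabolic rate
#' (`x = a * M^b`, with `M` the mean individual body mass in g), and the
#' placeholder biomass given to basal nodes. Defaults follow the standard
#' bioenergetic configuration: efficiencies 0.906 for animal prey, 0.545
#' for producers and cyanobacteria, 0.158 for detritus; `a = 0.71`,
#' `b = -0.25` (metabolic-theory allometry). Basal nodes always have
#' metabolic loss 0 and, because the fluxes are estimated top-down, their
#' biomass is replaced by the placeholder (default 1); the placeholder
#' still participates in the biomass-scaled feeding preferences.
#'
#' @param efficiencies named numeric vector over categories, all in (0, 1].
#' @param a,b allometric coefficient and exponent of the per-gram metabolic
#'   rate.
#' @param basal_biomass placeholder biomass for basal nodes (g).
#' @return a list of class `flux_parameters`.
#' @export
flux_parameters <- function(efficiencies = c(animal = 0.906, producer = 0.545,
                                             cyanobacteria = 0.545,
                                             detritus = 0.158),
                            a = 0.71, b = -0.25, basal_biomass = 1) {
  if (is.null(names(efficiencies)) || !all(names(efficiencies) %in% .categories))
    stop("efficiencies must be named by category (",
         paste(.categories, collapse = ", "), ")")
  if (any(efficiencies <= 0 | efficiencies > 1))
    stop("efficiencies must lie in (0, 1]")
  if (basal_biomass <= 0) stop("basal_biomass must be > 0")
  structure(list(efficiencies = efficiencies, a = a, b = b,
                 basal_biomass = basal_biomass),
            class = "flux_parameters")
}

#' Metabolic losses per node
#'
#' `X_j = a * M_j^b * B_j` for non-basal nodes (per-gram allometric rate
#' times total biomass); `X_j = 0` for basal nodes.
#'
#' @param web a directed [food_web()] whose non-basal nodes carry `biomass`
#'   and `body_mass`.
#' @param params a [flux_parameters()] object.
#' @param basal character vector of basal node names (defaults to
#'   [basal_nodes()]).
#' @return named numeric vector of losses (same units as
#'   `a * biomass / time`).
#' @export
metabolic_losses <- function(web, params = flux_parameters(),
                             basal = basal_nodes(web, warn = FALSE)) {
  stopifnot(inherits(params, "flux_parameters"))
  nm <- web$nodes$name
  X <- stats::setNames(numeric(length(nm)), nm)
  cons <- setdiff(nm, basal)
  i <- match(cons, nm)
  if (any(is.na(web$nodes$biomass[i])) || any(is.na(web$nodes$body_mass[i])))
    stop("non-basal node(s) lack biomass or body mass: ",
         paste(cons[is.na(web$nodes$biomass[i]) | is.na(web$nodes$body_mass[i])],
               collapse = ", "))
  X[cons] <- params$a * web$nodes$body_mass[i]^params$b * web$nodes$biomass[i]
  X
}

#' Biomass-scaled feeding preference matrix
#'
#' `W[i, j] = B_i / sum(B over the prey of j)` for every edge i -> j:
#' each consumer's column distributes its diet over its prey in proportion
#' to prey biomass, and sums to 1.
#'
#' @param web a directed [food_web()].
#' @param biomass named vector of biomasses covering every prey node.
#' @return square matrix `W` (rows = prey, columns = consumers), columns of
#'   consumers summing to 1.
#' @export
preference_matrix <- function(web, biomass) {
  nm <- web$nodes$name
  W <- matrix(0, length(nm), length(nm), dimnames = list(prey = nm, predator = nm))
  ed <- web$edges[web$edges$prey != web$edges$predator, , drop = FALSE]
  for (j in unique(ed$predator)) {
    p <- ed$prey[ed$predator == j]
    b <- biomass[p]
    if (anyNA(b)) stop("missing biomass for prey of ", j, ": ",
                       paste(p[is.na(b)], collapse = ", "))
    if (sum(b) <= 0) stop("all-zero prey biomass for consumer ", j)
    W[p, j] <- b / sum(b)
  }
  W
}

#' Steady-state energy fluxes on a trophic web
#'
#' Estimates the flux matrix `F` (rows = prey, columns = consumers) under
#' the per-prey efficiency flux balance: for every non-basal consumer *j*,
#' assimilated inflow equals metabolic loss plus outflow to predators,
#' `sum_i e_i F[i,j] = X_j + sum_k F[j,k]`, with `e_i` the assimilation
#' efficiency of prey *i*'s category and `X_j` the metabolic loss. Writing
#' `F[i,j] = W[i,j] G_j` with biomass-scaled preferences `W` and total
#' consumption `G_j`, the balance is a linear system in `G`, solved
#' exactly (dense solve). All fluxes must be nonnegative; values in
#' `(-1e-9, 0)` are clipped to 0, anything more negative is an infeasible
#' parameterization and raises an error.
#'
#' Non-basal nodes lacking biomass or body-mass data are dropped from the
#' flux web with a warning (the drop is generic, not taxon-specific). Basal
#' nodes get the placeholder biomass and zero loss (see
#' [flux_parameters()]).
#'
#' @param web a directed [food_web()] with categories assigned.
#' @param params a [flux_parameters()] object.
#' @return an object of class `flux_model`: list with `fluxes` (matrix
#'   `F`), `consumption` (named `G`), `preferences` (`W`), `losses` (`X`),
#'   `efficiencies` (per node, by category), `basal`, `dropped`, `web`.
#' @examples
#' web <- food_web(
#'   edges = data.frame(prey = "Plant", predator = "Grazer"),
#'   nodes = data.frame(name = c("Plant", "Grazer"),
#'                      category = c("producer", "animal"),
#'                      biomass = c(NA, 1), body_mass = c(NA, 1))
#' )
#' fm <- energy_fluxes(web, flux_parameters(a = 0.545, b = 0))
#' fm$fluxes["Plant", "Grazer"]  # 1: forced by balance F * e = X
#' @export
energy_fluxes <- function(web, params = flux_parameters()) {
  stopifnot(inherits(web, "food_web"), inherits(params, "flux_parameters"))
  if (!web$directed) stop("energy fluxes are defined on the directed web")
  if (anyNA(web$nodes$category))
    stop("every node needs a category for the flux model")

  basal0 <- basal_nodes(web, warn = FALSE)
  lacking <- setdiff(web$nodes$name, basal0)
  lacking <- lacking[is.na(web$nodes$biomass[match(lacking, web$nodes$name)]) |
                     is.na(web$nodes$body_mass[match(lacking, web$nodes$name)])]
  if (length(lacking)) {
    warning("dropped from flux web (missing biomass/body mass): ",
            paste(lacking, collapse = ", "))
    keep <- setdiff(web$nodes$name, lacking)
    ed <- web$edges[web$edges$prey %in% keep & web$edges$predator %in% keep, ]
    web <- food_web(ed, web$nodes[web$nodes$name %in% keep, ],
                    directed = TRUE, label = web$label)
  }

  nm <- web$nodes$name
  basal <- basal_nodes(web, warn = FALSE)  # may grow: consumers whose prey dropped
  e <- params$efficiencies[web$nodes$category]
  if (anyNA(e))
    stop("no efficiency for category: ",
         paste(unique(web$nodes$category[is.na(e)]), collapse = ", "))
  e <- stats::setNames(as.numeric(e), nm)

  biomass <- stats::setNames(web$nodes$biomass, nm)
  # top-down estimation: true basal biomass is irrelevant to the balance and
  # replaced by the placeholder; dangling animals keep their own biomass
  cat_basal <- nm[web$nodes$category %in% .basal_categories]
  biomass[cat_basal] <- params$basal_biomass
  biomass[basal][is.na(biomass[basal])] <- params$basal_biomass
  W <- preference_matrix(web, biomass)
  X <- metabolic_losses(web, params, basal = basal)

  cons <- setdiff(nm, basal)
  G <- stats::setNames(numeric(length(nm)), nm)
  if (length(cons)) {
    # (sum_i W[i,j] e_i) G_j - sum_k W[j,k] G_k = X_j  over consumers j
    A <- diag(colSums(W[, cons, drop = FALSE] * e), nrow = length(cons))
    dimnames(A) <- list(cons, cons)
    A <- A - W[cons, cons, drop = FALSE]
    Gc <- tryCatch(solve(A, X[cons]),
                   error = function(err) stop("flux system is singular: ",
                                              conditionMessage(err)))
    if (any(Gc < -1e-9))
      stop("infeasible parameterization: negative consumption for ",
           paste(cons[Gc < -1e-9], collapse = ", "))
    G[cons] <- pmax(Gc, 0)
  }
  F <- W %*% diag(G, nrow = length(nm))
  dimnames(F) <- list(prey = nm, predator = nm)
  F[F < 0 & F > -1e-9] <- 0
  if (any(F < 0))
    stop("infeasible parameterization: negative flux")

  structure(list(fluxes = F, consumption = G, preferences = W, losses = X,
                 efficiencies = e, basal = basal, dropped = lacking,
                 web = web, params = params),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  s <- flux_summaries(x)
  cat(sprintf("<flux_model%s> %d nodes (%d basal), %d positive fluxes\n",
              if (nzchar(x$web$label)) paste0(" '", x$web$label, "'") else "",
              nrow(x$fluxes), length(x$basal), s$n_fluxes))
  cat(sprintf("  total flux %.4g, Shannon flow diversity H = %.4g\n",
              s$total, s$diversity))
  if (length(x$dropped))
    cat("  dropped (no data):", paste(x$dropped, collapse = ", "), "\n")
  res <- flux_balance_residuals(x)
  if (length(res))
    cat(sprintf("  max |balance residual| = %.3g\n", max(abs(res))))
  invisible(x)
}

#' @export
summary.flux_model <- function(object, ...) {
  F <- object$fluxes
  pos <- F[F > 0]
  out <- c(flux_summaries(object),
           list(range = range(pos), residual = max(abs(c(0,
                flux_balance_residuals(object))))))
  class(out) <- "summary.flux_model"
  out
}

#' @export
print.summary.flux_model <- function(x, ...) {
  cat(sprintf("fluxes: %d positive, total %.4g, range [%.3g, %.3g]\n",
              x$n_fluxes, x$total, x$range[1], x$range[2]))
  cat(sprintf("Shannon flow diversity H = %.4g; max balance residual %.3g\n",
              x$diversity, x$residual))
  invisible(x)
}

#' Flux-balance residuals
#'
#' Conservation check: for every non-basal consumer *j*,
#' `sum_i e_i F[i,j] - X_j - sum_k F[j,k]`, which must vanish at the solve
#' tolerance.
#'
#' @param fm a [energy_fluxes()] result.
#' @return named numeric vector over consumers.
#' @export
flux_balance_residuals <- function(fm) {
  stopifnot(inherits(fm, "flux_model"))
  cons <- setdiff(rownames(fm$fluxes), fm$basal)
  vapply(cons, function(j) {
    sum(fm$efficiencies * fm$fluxes[, j]) - fm$losses[j] - sum(fm$fluxes[j, ])
  }, numeric(1))
}

#' Log10 display matrix of fluxes
#'
#' Entrywise `log10` of the strictly positive fluxes; structural zeros
#' become `NA` (never `-Inf`). Rows and columns are ordered by ascending
#' trophic level when levels are supplied (or computable from the model's
#' web), matching the usual weighted-interaction-matrix display.
#'
#' @param fm a [energy_fluxes()] result or a nonnegative matrix.
#' @param tl optional [trophic_levels()] (or named vector) used for
#'   ordering; `NULL` orders by the model's own web (matrix input: no
#'   reordering).
#' @return matrix of `log10` fluxes with `NA` at structural zeros.
#' @export
flux_log10 <- function(fm, tl = NULL) {
  F <- if (inherits(fm, "flux_model")) fm$fluxes else as.matrix(fm)
  if (any(F < 0)) stop("fluxes must be nonnegative")
  if (is.null(tl) && inherits(fm, "flux_model"))
    tl <- trophic_levels(fm$web)
  if (!is.null(tl)) {
    ord <- names(sort(unclass(tl)[rownames(F)]))
    F <- F[ord, ord, drop = FALSE]
  }
  out <- suppressWarnings(log10(F))
  out[!is.finite(out) & F == 0] <- NA
  out
}

#' Flux counts, total and flow diversity
#'
#' Summaries of a flux matrix: the number of positive fluxes, their total,
#' and the Shannon diversity `H = -sum(p log p)` of the normalized positive
#' fluxes (natural log), a flow-diversity index.
#'
#' @param fm a [energy_fluxes()] result or a nonnegative matrix.
#' @return list with `n_fluxes`, `total`, `diversity`.
#' @export
flux_summaries <- function(fm) {
  F <- if (inherits(fm, "flux_model")) fm$fluxes else as.matrix(fm)
  pos <- F[F > 0]
  if (!length(pos)) stop("all fluxes are zero")
  p <- pos / sum(pos)
  list(n_fluxes = length(pos), total = sum(pos), diversity = -sum(p * log(p)))
}
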