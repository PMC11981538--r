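#' Network density
#'
#' `D = 2L / (N (N - 1))`: the fraction of realized links among all
#' possible unordered pairs of the simple undirected web.
#'
#' @param web an undirected [food_web()] (use [symmetrize()] first),
#'   `N >= 2`, no self-loops.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(web) {
  .check_undirected(web, min_n = 2)
  n <- nrow(web$nodes)
  2 * nrow(web$edges) / (n * (n - 1))
}

#' Degree-weighted overall clustering coefficient
#'
#' Local clustering `c_i = 2 t_i / (k_i (k_i - 1))` (with `t_i` the number
#' of triangles through node *i*; nodes with degree < 2 contribute 0),
#' averaged over nodes with each node weighted by its degree:
#' `CL = sum(k_i c_i) / sum(k_i)`. This is the "weighted overall"
#' clustering used in UCINET-style whole-network cohesion summaries.
#'
#' @param web an undirected [food_web()] with at least one link.
#' @return `CL` in `[0, 1]`.
#' @export
clustering_overall <- function(web) {
  .check_undirected(web, min_n = 1)
  if (nrow(web$edges) == 0) stop("web has no links; CL is undefined")
  A <- as.matrix(web) * 1
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
  sum(k * ci) / sum(k)
}

#' Local clustering coefficients
#'
#' @param web an undirected [food_web()].
#' @return named vector of `c_i` (0 for nodes with degree < 2).
#' @export
local_clustering <- function(web) {
  .check_undirected(web, min_n = 1)
  A <- as.matrix(web) * 1
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  stats::setNames(ifelse(k < 2, 0, tri / (k * (k - 1) / 2)), web$nodes$name)
}

#' Average geodesic distance
#'
#' Mean shortest-path length over all unordered pairs of distinct nodes.
#' (On an undirected web, averaging over ordered pairs gives the same
#' value.)
#'
#' @param web a connected undirected [food_web()], `N >= 2`.
#' @return mean distance `d >= 1`.
#' @export
average_distance <- function(web) {
  .check_undirected(web, min_n = 2)
  comp <- check_connected(web)
  if (!comp$connected)
    stop("web is disconnected (", comp$n_components, " components: ",
         paste(vapply(comp$components, function(x) paste(x, collapse = "+"), ""),
               collapse = " | "), "); average distance is undefined")
  dm <- igraph::distances(.as_igraph(web))
  mean(dm[upper.tri(dm)])
}

#' Small-world index
#'
#' The ratio `SW = CL / d` of the degree-weighted clustering coefficient to
#' the average distance, used as a cohesion-versus-distance summary.
#'
#' @param cl clustering coefficient `CL`.
#' @param d average distance (> 0).
#' @return `CL / d`.
#' @export
small_world <- function(cl, d) {
  if (any(d <= 0)) stop("average distance must be > 0")
  cl / d
}

#' Normalized degree centrality
#'
#' `nDC_i = k_i / (N - 1)`: the number of direct links of a node divided by
#' the maximum possible.
#'
#' @param web an undirected [food_web()], `N >= 2`.
#' @param normalized if `FALSE`, return raw degrees.
#' @return named vector in `[0, 1]` (or raw degrees).
#' @export
degree_centrality <- function(web, normalized = TRUE) {
  .check_undirected(web, min_n = 2)
  k <- igraph::degree(.as_igraph(web))
  k <- k[web$nodes$name]
  if (normalized) k / (nrow(web$nodes) - 1) else k
}

#' Normalized betweenness centrality
#'
#' Raw betweenness `B_i = sum over pairs j < k (excluding i) of
#' sigma_jk(i) / sigma_jk`, where `sigma_jk` counts shortest paths and
#' `sigma_jk(i)` those passing through *i* — computed exactly (Brandes
#' accumulation, no sampling; ties between equally short paths are resolved
#' by exact path counting, never by picking one). By default the result is
#' expressed as a percentage of the undirected maximum
#' `(N - 1)(N - 2) / 2`.
#'
#' @param web a connected undirected [food_web()], `N >= 3`.
#' @param percent if `FALSE`, return the fraction in `[0, 1]` instead of
#'   percent of maximum.
#' @return named vector, `nBC_i` in `[0, 100]` (or `[0, 1]`).
#' @export
betweenness_centrality <- function(web, percent = TRUE) {
  .check_undirected(web, min_n = 3)
  B <- igraph::betweenness(.as_igraph(web), directed = FALSE)
  B <- B[web$nodes$name]
  n <- nrow(web$nodes)
  frac <- B / ((n - 1) * (n - 2) / 2)
  if (percent) 100 * frac else frac
}

#' Global indices of a symmetrized web
#'
#' The six whole-web indices used for web-to-web comparison: node count N,
#' undirected link count L, density D, degree-weighted clustering CL,
#' average distance d, and the small-world ratio SW = CL/d.
#'
#' @param web an undirected [food_web()] (a directed web is symmetrized
#'   with a message).
#' @return a data frame with columns `metric`, `abbreviation`, `value`.
#' @export
global_metrics <- function(web) {
  if (web$directed) {
    message("symmetrizing directed web for global metrics")
    web <- symmetrize(web)
  }
  cl <- clustering_overall(web)
  d <- average_distance(web)
  data.frame(
    metric = c("Number of nodes", "Number of links", "Network density",
               "Weighted overall graph clustering coefficient",
               "Average distance", "Small world index"),
    abbreviation = c("N", "L", "D", "CL", "d", "SW"),
    value = c(nrow(web$nodes), nrow(web$edges), network_density(web), cl, d,
              small_world(cl, d)),
    stringsAsFactors = FALSE
  )
}

#' Node-level indices
#'
#' Normalized degree and betweenness centrality on the symmetrized web,
#' plus the trophic level from the directed web when available.
#'
#' @param web a [food_web()]; if directed, centralities are computed on its
#'   symmetrization and TL on the directed web itself.
#' @return data frame with columns `node`, `nDC`, `nBC`, `TL` (TL is `NA`
#'   for undirected input).
#' @export
node_metrics <- function(web) {
  s <- if (web$directed) symmetrize(web) else web
  tl <- if (web$directed) as.numeric(trophic_levels(web)) else NA_real_
  data.frame(node = web$nodes$name,
             nDC = unname(degree_centrality(s)),
             nBC = unname(betweenness_centrality(s)),
             TL = tl,
             stringsAsFactors = FALSE)
}

.check_undirected <- function(web, min_n = 1) {
  stopifnot(inherits(web, "food_web"))
  if (web$directed)
    stop("this index is defined on the symmetrized web; call symmetrize() first")
  if (nrow(web$nodes) < min_n)
    stop("web must have at least ", min_n, " nodes")
  if (any(web$edges$prey == web$edges$predator))
    stop("web has self-loops; indices assume a simple graph")
  invisible(TRUE)
}
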