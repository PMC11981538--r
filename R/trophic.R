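#' Basal nodes of a directed web
#'
#' Basal nodes are fixed at trophic level 1 and carry zero metabolic loss:
#' every node whose category is producer, cyanobacteria or detritus, plus
#' any node with no prey at all. Detritus is basal by convention even when
#' it receives donor links; those links are excluded from the trophic-level
#' system. An animal with no prey and no basal category is a dangling
#' consumer: it is treated as basal for solvability, with a warning.
#'
#' @param web a directed [food_web()].
#' @param warn warn about dangling consumers (default `TRUE`).
#' @return character vector of basal node names (alphabetical).
#' @export
basal_nodes <- function(web, warn = TRUE) {
  stopifnot(inherits(web, "food_web"))
  if (!web$directed) stop("basal nodes are defined on the directed web")
  has_prey <- web$nodes$name %in% web$edges$predator
  by_cat <- !is.na(web$nodes$category) & web$nodes$category %in% .basal_categories
  dangling <- !has_prey & !by_cat & !is.na(web$nodes$category) &
    web$nodes$category == "animal"
  if (warn && any(dangling))
    warning("dangling consumer(s) with no prey treated as basal: ",
            paste(web$nodes$name[dangling], collapse = ", "))
  .sort_c(web$nodes$name[by_cat | !has_prey])
}

#' Prey-averaged trophic levels
#'
#' Solves the diet-weighted linear system `TL_i = 1 + sum_j q_ij TL_j`,
#' where `q_ij` is the share of prey *j* in the diet of consumer *i*.
#' Basal nodes (see [basal_nodes()]) are fixed at `TL = 1`. On a binary web
#' the diet shares are equal over the prey (`share = "equal"`, the default);
#' `share = "biomass"` weights the diet by prey biomass instead. The system
#' is solved exactly (dense linear solve; residual checked below 1e-10).
#' Cannibalistic self-loops are excluded from diet shares.
#'
#' @param web a directed [food_web()].
#' @param share `"equal"` (binary web) or `"biomass"` (prey-biomass
#'   weighted diet shares; requires biomass on all prey of each consumer).
#' @return an object of class `trophic_levels`: a named numeric vector of
#'   trophic levels (>= 1) with attributes `basal` (names fixed at 1) and
#'   `share`.
#' @examples
#' web <- food_web(
#'   edges = data.frame(prey = c("Detritus", "Copepoda"),
#'                      predator = c("Copepoda", "Shrimp")),
#'   nodes = data.frame(name = c("Detritus", "Copepoda", "Shrimp"),
#'                      category = c("detritus", "animal", "animal"))
#' )
#' trophic_levels(web)  # 1, 2, 3
#' @export
trophic_levels <- function(web, share = c("equal", "biomass")) {
  stopifnot(inherits(web, "food_web"))
  if (!web$directed) stop("trophic levels are defined on the directed web")
  share <- match.arg(share)
  nm <- web$nodes$name
  n <- length(nm)
  basal <- basal_nodes(web, warn = TRUE)
  ed <- web$edges[web$edges$prey != web$edges$predator, , drop = FALSE]

  # consumers must be grounded: some diet chain must reach a basal node
  prey_of <- split(ed$prey, factor(ed$predator, levels = nm))
  grounded <- nm %in% basal
  names(grounded) <- nm
  repeat {
    newly <- !grounded & vapply(prey_of, function(p) any(grounded[p]), NA)
    if (!any(newly)) break
    grounded[newly] <- TRUE
  }
  if (!all(grounded))
    stop("diet cycle with no basal input; trophic levels undefined for: ",
         paste(nm[!grounded], collapse = ", "))

  M <- diag(n)
  dimnames(M) <- list(nm, nm)
  for (j in setdiff(nm, basal)) {
    p <- prey_of[[j]]
    w <- if (share == "equal") rep(1, length(p)) else {
      b <- web$nodes$biomass[match(p, nm)]
      if (anyNA(b))
        stop("share = \"biomass\" needs biomass on every prey of ", j)
      b
    }
    w <- w / sum(w)
    for (k in seq_along(p)) M[j, p[k]] <- M[j, p[k]] - w[k]
  }
  b <- rep(1, n)
  tl <- solve(M, b)
  stopifnot(max(abs(M %*% tl - b)) < 1e-10)
  structure(stats::setNames(as.numeric(tl), nm), basal = basal, share = share,
            label = web$label, class = "trophic_levels")
}

#' @export
print.trophic_levels <- function(x, digits = 2, ...) {
  cat(sprintf("Trophic levels (%s diet shares; %d basal node%s at TL = 1)\n",
              attr(x, "share"), length(attr(x, "basal")),
              if (length(attr(x, "basal")) == 1) "" else "s"))
  v <- round(unclass(x), digits)
  print(v[order(-v, names(v), method = "radix")])
  invisible(x)
}

#' Compare computed trophic levels to reference values
#'
#' Literature trophic levels (e.g. diet-based estimates for fish) come with
#' a tolerance; a computed value is flagged as within range when
#' `|computed - reference| <= tolerance`.
#'
#' @param levels a [trophic_levels()] object (or named numeric vector).
#' @param reference data frame with columns `node`, `tl` and optionally
#'   `tolerance` (filled with `default_tolerance` where missing).
#' @param default_tolerance tolerance used where the reference gives none
#'   (default 0.3).
#' @return data frame with columns `node`, `computed`, `reference`,
#'   `tolerance`, `delta`, `within`.
#' @export
compare_trophic_reference <- function(levels, reference, default_tolerance = 0.3) {
  stopifnot(is.data.frame(reference), all(c("node", "tl") %in% names(reference)))
  tol <- if ("tolerance" %in% names(reference)) reference$tolerance else NA_real_
  tol <- ifelse(is.na(tol), default_tolerance, tol)
  computed <- unclass(levels)[reference$node]
  delta <- as.numeric(computed) - reference$tl
  data.frame(node = reference$node,
             computed = as.numeric(computed),
             reference = reference$tl,
             tolerance = tol,
             delta = delta,
             within = !is.na(delta) & abs(delta) <= tol,
             stringsAsFactors = FALSE)
}
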