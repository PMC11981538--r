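#' Aggregation scheme: raw taxa to functional-group nodes
#'
#' A many-to-one mapping from raw taxon names to functional-group node
#' names (a taxon is never split across groups). Accepts a named character
#' vector (`c(taxon = "Group", ...)`) or a data frame with columns `taxon`
#' and `functional_group`.
#'
#' @param x named character vector or data frame.
#' @return a named character vector of class `aggregation_scheme`.
#' @export
aggregation_scheme <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("taxon", "functional_group") %in% names(x)))
      stop("data frame scheme needs `taxon` and `functional_group` columns")
    x <- stats::setNames(as.character(x$functional_group), as.character(x$taxon))
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(!nzchar(names(x))))
    stop("scheme must be a named character vector (taxon -> group)")
  if (anyDuplicated(names(x)))
    stop("a taxon appears twice in the scheme: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  structure(as.character(x), names = names(x), class = "aggregation_scheme")
}

#' Aggregate a food web into functional groups
#'
#' Pools raw taxa into functional-group nodes. An edge joins two groups
#' whenever any raw edge joins members of the two groups (binary collapse);
#' within-group feeding becomes a self-loop and is dropped, because the
#' density formula `2L/N(N-1)` assumes a simple graph. Group biomass is the
#' sum of member biomasses; group body mass is the biomass-weighted mean of
#' member body masses (members lacking either value are excluded from the
#' mean); the category is inherited from the members and must agree.
#'
#' @param web a directed [food_web()].
#' @param scheme an [aggregation_scheme()] (or anything it accepts) covering
#'   every node of `web`.
#' @return an aggregated directed `food_web`.
#' @export
aggregate_web <- function(web, scheme) {
  stopifnot(inherits(web, "food_web"))
  scheme <- aggregation_scheme(scheme)
  missing <- setdiff(web$nodes$name, names(scheme))
  if (length(missing))
    stop("scheme does not cover node(s): ", paste(missing, collapse = ", "))
  grp <- scheme[web$nodes$name]

  agg_nodes <- do.call(rbind, lapply(.sort_c(unique(grp)), function(g) {
    m <- web$nodes[grp == g, , drop = FALSE]
    cats <- unique(m$category[!is.na(m$category)])
    if (length(cats) > 1)
      stop("conflicting categories in group '", g, "': ",
           paste(sprintf("%s (%s)", m$name, m$category), collapse = ", "))
    biomass <- if (all(is.na(m$biomass))) NA_real_ else sum(m$biomass, na.rm = TRUE)
    ok <- !is.na(m$biomass) & !is.na(m$body_mass)
    body_mass <- if (any(ok))
      sum(m$biomass[ok] * m$body_mass[ok]) / sum(m$biomass[ok])
    else if (any(!is.na(m$body_mass)))
      mean(m$body_mass, na.rm = TRUE)  # no weights available: plain mean
    else NA_real_
    periods <- unique(unlist(strsplit(m$period[!is.na(m$period)], ";")))
    data.frame(name = g,
               category = if (length(cats)) cats else NA_character_,
               functional_group = g,
               biomass = biomass, body_mass = body_mass,
               period = if (length(periods)) paste(.sort_c(periods), collapse = ";")
                        else NA_character_,
               stringsAsFactors = FALSE)
  }))

  ed <- data.frame(prey = unname(scheme[web$edges$prey]),
                   predator = unname(scheme[web$edges$predator]))
  ed <- unique(ed[ed$prey != ed$predator, , drop = FALSE])
  food_web(edges = ed, nodes = agg_nodes, directed = web$directed,
           label = if (nzchar(web$label)) paste(web$label, "aggregated") else "aggregated")
}
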