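#' Construct a binary food web
#'
#' A `food_web` is a binary trophic graph together with a node attribute
#' table. Directed edges are stored prey -> predator, i.e. in the direction
#' of energy flow; undirected webs (produced by [symmetrize()]) store each
#' unordered pair once with the endpoints in alphabetical order.
#'
#' @param edges data frame with character columns `prey` and `predator`
#'   (one interaction per row; duplicates collapse to a single edge).
#' @param nodes data frame with at least a `name` column; optional columns
#'   `category` (one of `"producer"`, `"cyanobacteria"`, `"detritus"`,
#'   `"animal"`), `functional_group` (defaults to `name`), `biomass` (total
#'   biomass, g), `body_mass` (mean individual body mass, g) and `period`.
#'   Missing optional columns are filled with `NA`.
#' @param directed logical; `TRUE` for a trophic (prey -> predator) web.
#' @param label free-text label used in printing and output file names.
#'
#' @return An object of class `food_web`: a list with elements `nodes`
#'   (attribute data frame, alphabetical by name), `edges` (edge data frame,
#'   sorted), `directed` and `label`.
#'
#' @examples
#' web <- food_web(
#'   edges = data.frame(prey = c("Detritus", "Copepoda"),
#'                      predator = c("Copepoda", "Shrimp")),
#'   nodes = data.frame(name = c("Detritus", "Copepoda", "Shrimp"),
#'                      category = c("detritus", "animal", "animal"))
#' )
#' web
#' @seealso [read_food_web()], [symmetrize()], [aggregate_web()]
#' @export
food_web <- function(edges, nodes, directed = TRUE, label = "") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"name" %in% names(nodes)) stop("`nodes` must have a `name` column")
  nodes$name <- as.character(nodes$name)
  if (anyNA(nodes$name) || any(!nzchar(nodes$name)))
    stop("node names must be nonempty")
  if (anyDuplicated(nodes$name))
    stop("duplicate node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  for (col in c("category", "functional_group", "period"))
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  for (col in c("biomass", "body_mass"))
    if (!col %in% names(nodes)) nodes[[col]] <- NA_real_
  nodes$functional_group <- ifelse(is.na(nodes$functional_group),
                                   nodes$name, as.character(nodes$functional_group))
  bad_cat <- !is.na(nodes$category) & !nodes$category %in% .categories
  if (any(bad_cat))
    stop("unknown category: ", paste(unique(nodes$category[bad_cat]), collapse = ", "),
         " (expected one of ", paste(.categories, collapse = ", "), ")")
  for (col in c("biomass", "body_mass")) {
    nodes[[col]] <- as.numeric(nodes[[col]])
    if (any(!is.na(nodes[[col]]) & nodes[[col]] <= 0))
      stop("`", col, "` must be > 0 where present")
  }
  nodes <- nodes[.order_c(nodes$name),
                 c("name", "category", "functional_group", "biomass",
                   "body_mass", "period", setdiff(names(nodes),
                   c("name", "category", "functional_group", "biomass",
                     "body_mass", "period"))), drop = FALSE]
  rownames(nodes) <- NULL

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(prey = character(), predator = character())
  } else {
    if (!all(c("prey", "predator") %in% names(edges)))
      stop("`edges` must have `prey` and `predator` columns")
    edges <- data.frame(prey = as.character(edges$prey),
                        predator = as.character(edges$predator))
    unknown <- setdiff(c(edges$prey, edges$predator), nodes$name)
    if (length(unknown))
      stop("edge endpoints not in node table: ", paste(unknown, collapse = ", "))
    if (!directed) {
      swap <- edges$predator < edges$prey
      tmp <- edges$prey[swap]
      edges$prey[swap] <- edges$predator[swap]
      edges$predator[swap] <- tmp
    }
    edges <- unique(edges)
    edges <- edges[.order_c(paste(edges$prey, edges$predator, sep = "\r")), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }

  structure(list(nodes = nodes, edges = edges, directed = directed,
                 label = as.character(label)),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  kind <- if (x$directed) "directed" else "undirected"
  cat(sprintf("<food_web%s> %s: %d nodes, %d %s links\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              kind, nrow(x$nodes), nrow(x$edges),
              if (x$directed) "trophic" else "symmetrized"))
  cats <- table(x$nodes$category, useNA = "ifany")
  cat("  categories:", paste(sprintf("%s=%d", names(cats), cats), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.food_web <- function(object, ...) {
  w <- object
  comp <- check_connected(w)
  s <- if (w$directed) symmetrize(w) else w
  out <- list(label = w$label, directed = w$directed,
              n_nodes = nrow(w$nodes), n_edges = nrow(w$edges),
              n_undirected_links = nrow(s$edges),
              connected = comp$connected, n_components = comp$n_components,
              basal = if (w$directed) basal_nodes(w, warn = FALSE) else character())
  class(out) <- "summary.food_web"
  out
}

#' @export
print.summary.food_web <- function(x, ...) {
  cat(sprintf("food_web '%s': N = %d, directed edges = %d, undirected L = %d\n",
              x$label, x$n_nodes, x$n_edges, x$n_undirected_links))
  cat(sprintf("  connected: %s (%d component%s)\n", x$connected,
              x$n_components, if (x$n_components == 1) "" else "s"))
  if (length(x$basal))
    cat("  basal nodes:", paste(x$basal, collapse = ", "), "\n")
  invisible(x)
}

#' Adjacency matrix of a food web
#'
#' For a directed web, `A[i, j] = 1` when node *i* is eaten by node *j*
#' (rows = prey, columns = predators); for an undirected web the matrix is
#' symmetric. Node order is alphabetical.
#'
#' @param x a [food_web()].
#' @param ... unused.
#' @return a square 0/1 integer matrix with dimnames.
#' @export
as.matrix.food_web <- function(x, ...) {
  nm <- x$nodes$name
  A <- matrix(0L, length(nm), length(nm), dimnames = list(prey = nm, predator = nm))
  if (nrow(x$edges)) {
    A[cbind(x$edges$prey, x$edges$predator)] <- 1L
    if (!x$directed) A[cbind(x$edges$predator, x$edges$prey)] <- 1L
  }
  A
}

# igraph view of a web (internal)
.as_igraph <- function(web) {
  igraph::graph_from_data_frame(web$edges, directed = web$directed,
                                vertices = web$nodes$name)
}

#' Read a food web from edge-list and attribute CSV files
#'
#' The edge file follows the predator/prey dialect of published interaction
#' tables: header `predator,prey`, one interaction per row. Edges are stored
#' internally as prey -> predator (energy flow), so the two columns are
#' swapped on read. The attribute file has header
#' `taxon,functional_group,category,period,biomass_g,body_mass_g`; empty
#' cells mean missing data.
#'
#' @param edge_file,attribute_file CSV paths.
#' @param label label for the resulting web.
#' @return a directed [food_web()]. Duplicate edge rows collapse to one edge.
#' @export
read_food_web <- function(edge_file, attribute_file, label = "") {
  ed <- utils::read.csv(edge_file, stringsAsFactors = FALSE)
  if (nrow(ed) == 0) stop("empty edge file: ", edge_file)
  if (!all(c("predator", "prey") %in% names(ed)))
    stop("edge file must have `predator` and `prey` columns: ", edge_file)
  at <- utils::read.csv(attribute_file, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (nrow(at) == 0) stop("empty attribute file: ", attribute_file)
  if (!"taxon" %in% names(at))
    stop("attribute file must have a `taxon` column: ", attribute_file)
  unknown <- which(!(ed$predator %in% at$taxon) | !(ed$prey %in% at$taxon))
  if (length(unknown))
    stop("edge file row(s) ", paste(unknown, collapse = ", "),
         " name nodes absent from the attribute file: ",
         paste(unique(setdiff(c(ed$predator, ed$prey), at$taxon)), collapse = ", "))
  nodes <- data.frame(
    name = at$taxon,
    category = if ("category" %in% names(at)) at$category else NA_character_,
    functional_group = if ("functional_group" %in% names(at)) at$functional_group else NA_character_,
    biomass = if ("biomass_g" %in% names(at)) at$biomass_g else NA_real_,
    body_mass = if ("body_mass_g" %in% names(at)) at$body_mass_g else NA_real_,
    period = if ("period" %in% names(at)) at$period else NA_character_,
    stringsAsFactors = FALSE
  )
  food_web(edges = data.frame(prey = ed$prey, predator = ed$predator),
           nodes = nodes, directed = TRUE, label = label)
}

#' Write a food web to CSV files
#'
#' Inverse of [read_food_web()]: emits the `predator,prey` edge dialect and
#' the `taxon,...` attribute dialect, plus (optionally) the square 0/1
#' adjacency matrix with rows = prey and columns = predators.
#'
#' @param web a [food_web()].
#' @param edge_file,attribute_file output CSV paths.
#' @param matrix_file optional path for the adjacency matrix CSV.
#' @return invisibly, the paths written.
#' @export
write_food_web <- function(web, edge_file, attribute_file, matrix_file = NULL) {
  stopifnot(inherits(web, "food_web"))
  ed <- data.frame(predator = web$edges$predator, prey = web$edges$prey)
  utils::write.csv(ed, edge_file, row.names = FALSE, quote = FALSE)
  at <- data.frame(taxon = web$nodes$name,
                   functional_group = web$nodes$functional_group,
                   category = web$nodes$category,
                   period = web$nodes$period,
                   biomass_g = web$nodes$biomass,
                   body_mass_g = web$nodes$body_mass)
  utils::write.csv(at, attribute_file, row.names = FALSE, quote = FALSE, na = "")
  paths <- c(edge_file, attribute_file)
  if (!is.null(matrix_file)) {
    utils::write.csv(as.data.frame(as.matrix(web)), matrix_file, quote = FALSE)
    paths <- c(paths, matrix_file)
  }
  invisible(paths)
}

#' Symmetrize a trophic web
#'
#' Joins nodes *i* and *j* by an undirected link whenever either feeds on
#' the other (`x_ij + x_ji >= 1`); mutual predation collapses to a single
#' link, so the undirected link count never exceeds the directed edge count.
#' Idempotent: an undirected web is returned unchanged.
#'
#' @param web a [food_web()].
#' @return an undirected `food_web` with the same nodes and label.
#' @export
symmetrize <- function(web) {
  stopifnot(inherits(web, "food_web"))
  if (!web$directed) return(web)
  food_web(edges = web$edges, nodes = web$nodes, directed = FALSE,
           label = web$label)
}

#' Connectivity check
#'
#' A web is analysis-ready only when it is a single connected component
#' under symmetrization. Returns the verdict together with the components
#' for diagnostics.
#'
#' @param web a [food_web()].
#' @return a list with `connected` (logical), `n_components` and
#'   `components` (list of character vectors of node names).
#' @export
check_connected <- function(web) {
  stopifnot(inherits(web, "food_web"))
  if (nrow(web$nodes) == 0) stop("empty web")
  g <- .as_igraph(if (web$directed) symmetrize(web) else web)
  cmp <- igraph::components(g)
  comps <- split(names(cmp$membership), cmp$membership)
  comps <- unname(comps[order(-vapply(comps, length, 1L))])
  list(connected = cmp$no == 1L, n_components = cmp$no,
       components = lapply(comps, .sort_c))
}

#' Validate that a web is ready for network analysis
#'
#' Checks the conventions every downstream computation assumes: no
#' self-loops, every node carries a category, and the symmetrized web is a
#' single connected component.
#'
#' @param web a [food_web()].
#' @param require_category logical; set `FALSE` for bare topologies (e.g.
#'   fresh synthetic webs before [assign_attributes()]).
#' @return invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_analysis_ready <- function(web, require_category = TRUE) {
  stopifnot(inherits(web, "food_web"))
  problems <- character()
  loops <- web$edges$prey == web$edges$predator
  if (any(loops))
    problems <- c(problems, paste0("self-loops: ",
      paste(unique(web$edges$prey[loops]), collapse = ", ")))
  if (require_category && anyNA(web$nodes$category))
    problems <- c(problems, paste0("missing category: ",
      paste(web$nodes$name[is.na(web$nodes$category)], collapse = ", ")))
  comp <- check_connected(web)
  if (!comp$connected)
    problems <- c(problems, sprintf("web has %d components", comp$n_components))
  if (length(problems))
    stop("web is not analysis-ready:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}
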