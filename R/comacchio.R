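#' Published study tables for the Comacchio Lagoon contrast
#'
#' Accessors for the printed tables of the Comacchio Lagoon pre- versus
#' post-eutrophication study that ship with the package as plain CSV:
#' the environmental conditions of the two periods, the global metrics of
#' the two aggregated webs, and the taxon-to-functional-group table used
#' to aggregate the raw webs to 23 nodes.
#'
#' `comacchio_environment()` returns the environmental table (columns
#' `variable`, `unit`, `pre_year`, `pre`, `post_year`, `post`); the
#' chlorophyll-a `pre` value is the censored bound `"<1.00"`, which
#' [percent_change()] parses as 1.00. `comacchio_global_metrics()` returns
#' the published global indices (N, L, D, CL, d, SW) for both aggregated
#' webs. Note the published POST density (0.221) is inconsistent with
#' `2L/(N(N-1))` at the published `N = 23, L = 52` (which gives 0.206) — a
#' typo in the source table; the PRE column is internally consistent.
#' `comacchio_functional_groups()` returns the taxon table (columns
#' `taxon`, `functional_group`, `category`, `pre`, `post`); the `category`
#' column is this package's classification of each taxon into
#' producer/cyanobacteria/detritus/animal.
#'
#' @return data frames (see above).
#' @name comacchio_tables
NULL

.extdata <- function(fname) {
  path <- system.file("extdata", fname, package = "trophoweb")
  if (!nzchar(path)) stop("bundled file not found: ", fname)
  path
}

#' @rdname comacchio_tables
#' @export
comacchio_environment <- function() {
  utils::read.csv(.extdata("comacchio_environment.csv"),
                  colClasses = c(pre = "character", post = "character"),
                  stringsAsFactors = FALSE)
}

#' @rdname comacchio_tables
#' @export
comacchio_global_metrics <- function() {
  utils::read.csv(.extdata("comacchio_global_metrics.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname comacchio_tables
#' @export
comacchio_functional_groups <- function() {
  utils::read.csv(.extdata("comacchio_functional_groups.csv"),
                  stringsAsFactors = FALSE)
}

#' Aggregation scheme for a Comacchio period
#'
#' Builds the [aggregation_scheme()] (taxon -> functional group) for one
#' period, restricted to the taxa recorded in that period.
#'
#' @param period `"PRE"` or `"POST"`.
#' @return an [aggregation_scheme()].
#' @export
comacchio_scheme <- function(period = c("PRE", "POST")) {
  period <- match.arg(period)
  fg <- comacchio_functional_groups()
  fg <- fg[if (period == "PRE") fg$pre else fg$post, ]
  aggregation_scheme(stats::setNames(fg$functional_group, fg$taxon))
}

#' Load a raw Comacchio interaction web from user-supplied files
#'
#' The raw predator-prey edge lists of the two periods were published as a
#' supplementary spreadsheet and are not bundled with this package. Export
#' them to the CSV dialect of [read_food_web()] (`predator,prey` edge list
#' plus a `taxon,...` attribute table named
#' `comacchio_<period>_edges.csv` / `comacchio_<period>_attributes.csv`,
#' lower-case period) and point `dir` at the folder to load them; node
#' categories default to the classification in
#' [comacchio_functional_groups()] when the attribute file lacks them.
#'
#' @param period `"PRE"` or `"POST"`.
#' @param dir directory containing the exported CSV files.
#' @return a directed [food_web()].
#' @export
comacchio_raw_web <- function(period = c("PRE", "POST"), dir = NULL) {
  period <- match.arg(period)
  if (is.null(dir))
    stop("the raw Comacchio edge lists are distributed as a supplementary ",
         "spreadsheet and are not bundled; export them to CSV and pass `dir` ",
         "(see ?comacchio_raw_web)")
  edge_file <- file.path(dir, sprintf("comacchio_%s_edges.csv", tolower(period)))
  attr_file <- file.path(dir, sprintf("comacchio_%s_attributes.csv", tolower(period)))
  web <- read_food_web(edge_file, attr_file, label = sprintf("%s raw", period))
  if (anyNA(web$nodes$category)) {
    fg <- comacchio_functional_groups()
    fill <- fg$category[match(web$nodes$name, fg$taxon)]
    web$nodes$category <- ifelse(is.na(web$nodes$category), fill,
                                 web$nodes$category)
  }
  web
}
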