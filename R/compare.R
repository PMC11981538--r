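#' Percent change between two period values
#'
#' `(post - pre) / pre * 100`. Censored inputs written as a bound (e.g.
#' `"<1.00"`) are parsed as the bound itself.
#'
#' @param pre,post numeric values, or strings optionally prefixed with
#'   `"<"` or `">"`.
#' @return percent change (vectorized).
#' @examples
#' percent_change(15.33, 19.28)   # 25.77...
#' percent_change("<1.00", 54)    # 5300
#' @export
percent_change <- function(pre, post) {
  pre <- .parse_bound(pre)
  post <- .parse_bound(post)
  if (any(pre == 0)) stop("percent change undefined for pre = 0")
  (post - pre) / pre * 100
}

.parse_bound <- function(x) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(sub("^[<>]\\s*", "", trimws(x))))
  if (anyNA(out)) stop("cannot parse value(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' Compare two trophic webs
#'
#' Pairs up the global indices of the two symmetrized webs, lists the
#' shared nodes with their trophic-level shift (classified as decrease /
#' no change / increase; values are compared after rounding to 2 decimals,
#' so `|delta| < 0.005` counts as no change), optionally summarizes energy
#' fluxes, and optionally recomputes percent changes for an environmental
#' table.
#'
#' @param pre_web,post_web directed, analysis-ready [food_web()]s.
#' @param flux_params optional [flux_parameters()]; when given and the
#'   attribute data allow it, flux summaries are included.
#' @param env optional data frame with columns `variable`, `pre`, `post`
#'   (values may carry `"<"` bounds).
#' @return object of class `web_comparison`: list with `global` (metric,
#'   pre, post), `shared` (node, tl_pre, tl_post, delta, change),
#'   `n_shared`, `flux` (or `NULL`), `environmental` (or `NULL`), `labels`.
#' @export
compare_webs <- function(pre_web, post_web, flux_params = NULL, env = NULL) {
  stopifnot(inherits(pre_web, "food_web"), inherits(post_web, "food_web"))
  gm_pre <- global_metrics(symmetrize(pre_web))
  gm_post <- global_metrics(symmetrize(post_web))
  global <- data.frame(metric = gm_pre$metric, abbreviation = gm_pre$abbreviation,
                       pre = gm_pre$value, post = gm_post$value,
                       stringsAsFactors = FALSE)

  tl_pre <- trophic_levels(pre_web)
  tl_post <- trophic_levels(post_web)
  shared <- intersect(pre_web$nodes$name, post_web$nodes$name)
  shared <- .sort_c(shared)
  a <- round(unclass(tl_pre)[shared], 2)
  b <- round(unclass(tl_post)[shared], 2)
  shifts <- data.frame(node = shared, tl_pre = as.numeric(a),
                       tl_post = as.numeric(b),
                       delta = as.numeric(b - a),
                       change = ifelse(b < a, "decrease",
                                ifelse(b > a, "increase", "no change")),
                       stringsAsFactors = FALSE)

  flux <- NULL
  if (!is.null(flux_params)) {
    flux <- tryCatch({
      do.call(rbind, lapply(list(pre = pre_web, post = post_web), function(w) {
        s <- flux_summaries(suppressWarnings(energy_fluxes(w, flux_params)))
        data.frame(web = w$label, n_fluxes = s$n_fluxes, total = s$total,
                   diversity = s$diversity, stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      warning("flux summaries skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(flux)) rownames(flux) <- NULL
  }

  environmental <- NULL
  if (!is.null(env)) {
    stopifnot(all(c("variable", "pre", "post") %in% names(env)))
    environmental <- data.frame(variable = env$variable, pre = env$pre,
                                post = env$post,
                                percent_change = percent_change(env$pre, env$post),
                                stringsAsFactors = FALSE)
  }

  structure(list(global = global, shared = shifts, n_shared = length(shared),
                 flux = flux, environmental = environmental,
                 labels = c(pre_web$label, post_web$label)),
            class = "web_comparison")
}

#' @export
print.web_comparison <- function(x, ...) {
  cat(sprintf("Comparison of '%s' vs '%s'\n", x$labels[1], x$labels[2]))
  cat("\nGlobal metrics:\n")
  g <- x$global
  g$pre <- round(g$pre, 3)
  g$post <- round(g$post, 3)
  print(g[, c("abbreviation", "pre", "post")], row.names = FALSE)
  tab <- table(factor(x$shared$change,
                      levels = c("decrease", "no change", "increase")))
  cat(sprintf("\nShared nodes: %d (decrease %d, no change %d, increase %d)\n",
              x$n_shared, tab["decrease"], tab["no change"], tab["increase"]))
  moved <- x$shared[x$shared$change != "no change", , drop = FALSE]
  if (nrow(moved)) print(moved, row.names = FALSE)
  if (!is.null(x$flux)) {
    cat("\nFlux summaries:\n")
    f <- x$flux
    f$total <- signif(f$total, 4)
    f$diversity <- round(f$diversity, 3)
    print(f, row.names = FALSE)
  }
  if (!is.null(x$environmental)) {
    cat("\nEnvironmental change:\n")
    e <- x$environmental
    e$percent_change <- round(e$percent_change, 2)
    print(e, row.names = FALSE)
  }
  invisible(x)
}

#' Run the full two-web analysis and write all output tables
#'
#' Orchestrates the whole pipeline on one or two directed webs: optional
#' functional-group aggregation, validation, global and node metrics,
#' trophic levels, energy fluxes (long table, square matrix and log10
#' display matrix per web), the pairwise comparison report and a run log
#' recording every parameter. Outputs are plain CSV/text and contain no
#' timestamps, so a rerun with identical inputs is byte-identical.
#'
#' @param pre_web directed [food_web()] (the baseline / first period).
#' @param post_web optional second web; without it the comparison section
#'   is omitted.
#' @param out_dir output directory (created if needed).
#' @param scheme optional [aggregation_scheme()] applied to both webs.
#' @param flux_params [flux_parameters()] for the energy-flux stage; `NULL`
#'   skips fluxes.
#' @param env optional environmental table (see [compare_webs()]).
#' @return invisibly, a list with the `comparison` (or `NULL`) and the
#'   vector of `files` written.
#' @export
run_full_analysis <- function(pre_web, post_web = NULL, out_dir,
                              scheme = NULL, flux_params = flux_parameters(),
                              env = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log_lines <- c("trophoweb full analysis",
                 sprintf("parameter rounding: global 3 dp, node-level 2 dp"))
  if (!is.null(flux_params))
    log_lines <- c(log_lines,
      sprintf("flux parameters: a = %g, b = %g, basal biomass = %g", flux_params$a,
              flux_params$b, flux_params$basal_biomass),
      sprintf("efficiencies: %s", paste(sprintf("%s = %g",
              names(flux_params$efficiencies), flux_params$efficiencies),
              collapse = ", ")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  webs <- if (is.null(post_web)) list(pre_web) else list(pre_web, post_web)
  webs <- lapply(seq_along(webs), function(i) {
    w <- webs[[i]]
    if (!nzchar(w$label)) w$label <- c("pre", "post")[i]
    if (!is.null(scheme)) w <- stage("aggregate", aggregate_web(w, scheme))
    stage("validate", validate_analysis_ready(w))
    w
  })

  slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    files <<- c(files, path)
  }

  gm <- stage("global_metrics", lapply(webs, function(w)
    global_metrics(symmetrize(w))))
  gdf <- gm[[1]][, c("metric", "abbreviation")]
  for (i in seq_along(webs))
    gdf[[slug(webs[[i]]$label)]] <- round(gm[[i]]$value, 3)
  emit(gdf, "global_metrics.csv")

  tls <- list()
  for (i in seq_along(webs)) {
    w <- webs[[i]]
    nmx <- stage("node_metrics", {
      df <- node_metrics(w)
      df$nDC <- round(df$nDC, 2)
      df$nBC <- round(df$nBC, 2)
      df$TL <- round(df$TL, 2)
      df
    })
    emit(nmx, sprintf("node_metrics_%s.csv", slug(w$label)))
    tls[[i]] <- stage("trophic_levels", trophic_levels(w))
  }
  tl_df <- data.frame(node = .sort_c(unique(unlist(lapply(webs,
             function(w) w$nodes$name)))), stringsAsFactors = FALSE)
  for (i in seq_along(webs))
    tl_df[[slug(webs[[i]]$label)]] <-
      round(as.numeric(unclass(tls[[i]])[tl_df$node]), 2)
  emit(tl_df, "trophic_levels.csv")

  if (!is.null(flux_params)) {
    for (i in seq_along(webs)) {
      w <- webs[[i]]
      fm <- stage("energy_fluxes", withCallingHandlers(
        energy_fluxes(w, flux_params),
        warning = function(cnd) {
          log_lines <<- c(log_lines, paste0("WARN: [", w$label, "] ",
                                            conditionMessage(cnd)))
          invokeRestart("muffleWarning")
        }))
      F <- fm$fluxes
      pos <- which(F > 0, arr.ind = TRUE)
      long <- data.frame(prey = rownames(F)[pos[, 1]],
                         predator = colnames(F)[pos[, 2]],
                         flux = F[pos], stringsAsFactors = FALSE)
      long <- long[.order_c(paste(long$prey, long$predator, sep = "\r")), ]
      emit(long, sprintf("fluxes_%s.csv", slug(w$label)))
      emit(as.data.frame(F), sprintf("flux_matrix_%s.csv", slug(w$label)))
      emit(as.data.frame(round(flux_log10(fm), 4)),
           sprintf("flux_log10_%s.csv", slug(w$label)))
    }
  }

  comparison <- NULL
  if (length(webs) == 2) {
    comparison <- stage("compare", compare_webs(webs[[1]], webs[[2]],
                                                flux_params = flux_params,
                                                env = env))
    emit(comparison$shared, "comparison_shared_nodes.csv")
    g <- comparison$global
    g$pre <- round(g$pre, 3)
    g$post <- round(g$post, 3)
    emit(g, "comparison_global.csv")
    if (!is.null(comparison$environmental)) {
      e <- comparison$environmental
      e$percent_change <- round(e$percent_change, 2)
      emit(e, "comparison_environment.csv")
    }
    txt <- file.path(out_dir, "comparison_report.txt")
    con <- file(txt, open = "wt")
    sink(con)
    print(comparison)
    sink()
    close(con)
    files <- c(files, txt)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)
  invisible(list(comparison = comparison, files = files))
}
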