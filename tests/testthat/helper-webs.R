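# web builders and independent oracles used across the suite

chain_web <- function(n = 3) {
  nm <- sprintf("c%02d", seq_len(n))
  food_web(
    edges = if (n > 1) data.frame(prey = nm[-n], predator = nm[-1]) else
      data.frame(prey = character(), predator = character()),
    nodes = data.frame(name = nm,
                       category = c("producer", rep("animal", n - 1))),
    label = "chain"
  )
}

# undirected web from a symmetric 0/1 adjacency matrix
web_from_adj <- function(A, names = sprintf("v%02d", seq_len(nrow(A)))) {
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  food_web(
    edges = data.frame(prey = names[idx[, 1]], predator = names[idx[, 2]]),
    nodes = data.frame(name = names),
    directed = FALSE
  )
}

star_web <- function(n_leaves = 4) {
  A <- matrix(0L, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  web_from_adj(A)
}

triangle_web <- function() web_from_adj(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))

path_web <- function(n = 3) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  web_from_adj(A)
}

complete_web <- function(n) web_from_adj(1 - diag(n))

# all simple undirected graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    A <- matrix(0L, n, n)
    on <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    for (k in on) {
      A[pairs[k, 1], pairs[k, 2]] <- 1L
      A[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    A
  })
}

adj_connected <- function(A) {
  n <- nrow(A)
  seen <- c(1L, integer(n - 1))
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(A[v, ] == 1 & seen == 0)
    seen[nb] <- 1L
    queue <- c(queue, nb)
  }
  all(seen == 1)
}

random_connected_adj <- function(n, p) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A <- A + t(A)
    if (adj_connected(A)) return(A)
  }
}

# exact betweenness by exhaustive enumeration of all simple paths
brute_betweenness <- function(A) {
  n <- nrow(A)
  B <- numeric(n)
  paths_between <- function(from, to) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == to) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (w in which(A[v, ] == 1)) if (!w %in% path) walk(c(path, w))
    }
    walk(from)
    found
  }
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    ps <- paths_between(j, k)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L)
    geod <- ps[lens == min(lens)]
    sigma <- length(geod)
    interior <- unlist(lapply(geod, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      cnt <- table(interior)
      B[as.integer(names(cnt))] <- B[as.integer(names(cnt))] + cnt / sigma
    }
  }
  B
}

# all-pairs shortest paths by Floyd-Warshall, independent of igraph
brute_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# local clustering by explicit neighbour-pair counting
brute_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      links <- links + A[nb[a], nb[b]]
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

# trophic levels by bottom-up dynamic programming on an acyclic web
tl_dag_oracle <- function(web) {
  nm <- web$nodes$name
  basal <- basal_nodes(web, warn = FALSE)
  tl <- setNames(rep(NA_real_, length(nm)), nm)
  tl[basal] <- 1
  ed <- web$edges
  while (anyNA(tl)) {
    progressed <- FALSE
    for (j in nm[is.na(tl)]) {
      prey <- ed$prey[ed$predator == j]
      if (!anyNA(tl[prey])) {
        tl[j] <- 1 + mean(tl[prey])
        progressed <- TRUE
      }
    }
    if (!progressed) stop("oracle: web is not a grounded DAG")
  }
  tl
}

# flux solve by predator-first back-substitution on an acyclic web,
# with W, X and e recomputed from first principles
flux_dag_oracle <- function(web, params = flux_parameters()) {
  nm <- web$nodes$name
  basal <- basal_nodes(web, warn = FALSE)
  biom <- setNames(web$nodes$biomass, nm)
  biom[web$nodes$category %in% c("producer", "cyanobacteria", "detritus")] <-
    params$basal_biomass
  biom[basal][is.na(biom[basal])] <- params$basal_biomass
  e <- setNames(params$efficiencies[web$nodes$category], nm)
  X <- setNames(numeric(length(nm)), nm)
  cons <- setdiff(nm, basal)
  X[cons] <- params$a * web$nodes$body_mass[match(cons, nm)]^params$b *
    web$nodes$biomass[match(cons, nm)]
  W <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  ed <- web$edges
  for (j in cons) {
    p <- ed$prey[ed$predator == j]
    W[p, j] <- biom[p] / sum(biom[p])
  }
  # predators strictly before their prey (reverse topological peel)
  remaining <- cons
  order_top <- character()
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(j) {
      preds <- ed$predator[ed$prey == j]
      !any(preds %in% remaining)
    }, NA)]
    if (!length(free)) stop("oracle: consumer predation graph has a cycle")
    order_top <- c(order_top, free)
    remaining <- setdiff(remaining, free)
  }
  G <- setNames(numeric(length(nm)), nm)
  for (j in order_top) {
    G[j] <- (X[j] + sum(W[j, ] * G)) / sum(W[, j] * e)
  }
  F <- W %*% diag(G)
  dimnames(F) <- list(prey = nm, predator = nm)
  F
}

# a small analysis-ready synthetic web with attributes
synth_web <- function(seed = 7, n = 15, connectance = 0.22) {
  spec <- synthetic_web_spec(n_nodes = n, connectance = connectance, seed = seed)
  assign_attributes(generate_niche_web(spec), spec)
}
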