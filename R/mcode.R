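#' Adjacency-list representation of a simple undirected graph
#'
#' Accepts an edge data frame (`source`, `target`; signs and any other
#' columns are ignored — clustering treats edges as unsigned), a `grn`
#' object, or an existing adjacency list. Self-loops are dropped and
#' parallel edges collapsed; neighbor vectors are sorted for
#' deterministic iteration.
#'
#' @param x Edge data frame, `grn`, or named list of character vectors.
#' @param isolated Optional additional node ids with no edges.
#' @return Named list: node id -> sorted character vector of neighbors.
#' @export
as_adjacency <- function(x, isolated = character(0)) {
  if (inherits(x, "grn")) {
    isolated <- union(isolated, x$nodes$gene_id)
    x <- x$edges
  }
  if (is.data.frame(x)) {
    a <- as.character(x$source)
    b <- as.character(x$target)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    nodes <- sort(unique(c(a, b, isolated)))
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    for (n in nodes) adj[[n]] <- character(0)
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
    lapply(adj, function(v) sort(unique(v)))
  } else {
    lapply(x, function(v) sort(unique(as.character(v))))
  }
}

# Core numbers of an adjacency list by iterative peeling.
.core_numbers <- function(adj) {
  nodes <- names(adj)
  deg <- vapply(adj, length, integer(1))
  core <- stats::setNames(integer(length(nodes)), nodes)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  k <- 0L
  remaining <- length(nodes)
  while (remaining > 0) {
    low <- nodes[alive & deg <= k]
    if (!length(low)) {
      k <- k + 1L
      next
    }
    for (v in low) {
      if (!alive[[v]]) next
      queue <- v
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (!alive[[u]] || deg[[u]] > k) next
        core[[u]] <- k
        alive[[u]] <- FALSE
        remaining <- remaining - 1L
        for (w in adj[[u]]) {
          if (alive[[w]]) {
            deg[[w]] <- deg[[w]] - 1L
            if (deg[[w]] <= k) queue <- c(queue, w)
          }
        }
      }
    }
  }
  core
}

.induced_adj <- function(adj, nodes) {
  sub <- adj[nodes]
  lapply(sub, function(v) v[v %in% nodes])
}

.edge_count <- function(adj) {
  sum(vapply(adj, length, integer(1))) / 2
}

.density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' MCODE vertex weighting
#'
#' For each vertex `v` with degree >= `degree_cutoff`, take the subgraph
#' induced by the closed neighborhood (`v` and its neighbors), find its
#' maximal core number `kmax`, and set
#' `weight(v) = kmax * density(highest k-core)`, the density being that
#' of the kmax-core subgraph itself — the core-clustering coefficient of
#' the published MCODE algorithm. Scoring the core rather than the whole
#' neighborhood makes the weight robust to low-degree bystander
#' neighbors, which is what lets densely connected modules outrank
#' background vertices; including `v` itself keeps the weights of a
#' dense module's members homogeneous. Vertices below the degree cutoff
#' get weight 0.
#'
#' @param adj Graph acceptable to [as_adjacency()].
#' @param degree_cutoff Minimum degree to be weighted; default 2.
#' @return Named numeric vector of weights.
#' @export
weight_vertices <- function(adj, degree_cutoff = 2) {
  adj <- as_adjacency(adj)
  w <- stats::setNames(numeric(length(adj)), names(adj))
  for (v in names(adj)) {
    nb <- adj[[v]]
    if (length(nb) < degree_cutoff) next
    sub <- .induced_adj(adj, c(v, nb))
    cores <- .core_numbers(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    core_nodes <- names(cores)[cores == kmax]
    core_sub <- .induced_adj(sub, core_nodes)
    w[[v]] <- kmax * .density(length(core_nodes), .edge_count(core_sub))
  }
  w
}

#' Score of a candidate complex: density times size
#'
#' @param members Character vector of node ids (subset of the graph).
#' @param adj Graph acceptable to [as_adjacency()].
#' @return `density * |members|`; singletons and empty sets score 0.
#' @export
score_complex <- function(members, adj) {
  adj <- as_adjacency(adj)
  stopifnot(all(members %in% names(adj)))
  if (length(members) < 2) return(0)
  sub <- .induced_adj(adj, members)
  .density(length(members), .edge_count(sub)) * length(members)
}

#' MCODE complex prediction
#'
#' Seeds complexes from the highest-weighted unvisited vertex and grows
#' them breadth-first, admitting neighbors whose weight is at least
#' `seed_weight * (1 - vwp)`. With `fluff = FALSE` (default) every node
#' belongs to at most one complex. `haircut = TRUE` removes members with
#' fewer than two intra-complex neighbors (single pass); a complex whose
#' seed is removed, or that shrinks below two members, is discarded.
#' Complexes are ranked by score (density x size), ties by size then
#' seed id; all tie-breaking is lexicographic for determinism.
#'
#' @param adj Graph acceptable to [as_adjacency()].
#' @param weights Optional weights from [weight_vertices()] (computed if
#'   missing).
#' @param vwp Vertex weight percentage; default 0.2.
#' @param haircut Remove singly-connected members; default TRUE.
#' @param fluff Reserved; only `FALSE` (node-disjoint complexes) is
#'   implemented.
#' @param degree_cutoff Passed to [weight_vertices()]; default 2.
#' @return List of complexes, each a list with `seed`, `members`
#'   (sorted), `size`, `density`, `score`.
#' @export
predict_complexes <- function(adj, weights = NULL, vwp = 0.2,
                              haircut = TRUE, fluff = FALSE,
                              degree_cutoff = 2) {
  if (fluff) stop("fluff post-processing is not implemented")
  adj <- as_adjacency(adj)
  if (is.null(weights)) weights <- weight_vertices(adj, degree_cutoff)
  nodes <- names(adj)
  # seeds in decreasing weight, lexicographic within ties
  seed_order <- nodes[order(-weights[nodes], nodes)]
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  complexes <- list()
  for (seed in seed_order) {
    if (visited[[seed]] || weights[[seed]] <= 0) next
    threshold <- weights[[seed]] * (1 - vwp)
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (!visited[[v]] && weights[[v]] >= threshold) {
            visited[[v]] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- sort(nxt)
    }
    if (haircut && length(members) > 1) {
      sub <- .induced_adj(adj, members)
      keep <- members[vapply(sub[members], length, integer(1)) >= 2]
      if (!(seed %in% keep)) next
      members <- keep
    }
    if (length(members) < 2) next
    sub <- .induced_adj(adj, members)
    dens <- .density(length(members), .edge_count(sub))
    complexes[[length(complexes) + 1]] <- list(
      seed = seed, members = sort(members), size = length(members),
      density = dens, score = dens * length(members))
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               -vapply(complexes, `[[`, numeric(1), "size"),
               vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord]
}

#' Write MCODE clusters to a TSV (rank, score, size, members)
#' @param clusters List from [predict_complexes()].
#' @param path Output path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(
    rank = seq_along(clusters),
    score = vapply(clusters, `[[`, numeric(1), "score"),
    size = vapply(clusters, `[[`, numeric(1), "size"),
    seed = vapply(clusters, `[[`, character(1), "seed"),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
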