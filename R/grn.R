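#' Construct a gene regulatory network object
#'
#' Edges are undirected co-expression pairs; the stored `source`/`target`
#' orientation is metadata (a TF source is what the binding filter acts
#' on). Duplicate unordered pairs are collapsed keeping the lowest layer.
#'
#' @param edges Data frame with `source`, `target`, `sign` (+1/-1),
#'   `layer` (1/2/3), and optionally `evidence_filtered`.
#' @param role_tables Named list of character vectors assigning roles
#'   (e.g. `list(PrLP = ..., TF = ..., "Ts/RTR" = ..., stress = ...,
#'   memory = ...)`).
#' @return Object of class `grn`: list with `nodes` (data.frame
#'   `gene_id`, `roles` comma-separated) and `edges`.
#' @export
grn_network <- function(edges, role_tables = list()) {
  if (nrow(edges)) {
    key <- ifelse(edges$source < edges$target,
                  paste(edges$source, edges$target, sep = "\r"),
                  paste(edges$target, edges$source, sep = "\r"))
    ord <- order(edges$layer)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  if (!"evidence_filtered" %in% names(edges)) {
    edges$evidence_filtered <- rep(FALSE, nrow(edges))
  }
  gene_ids <- sort(unique(c(edges$source, edges$target,
                            unlist(role_tables, use.names = FALSE))))
  roles <- vapply(gene_ids, function(g) {
    paste(names(role_tables)[vapply(role_tables, function(v) g %in% v,
                                    logical(1))], collapse = ",")
  }, character(1))
  edges <- edges[order(edges$layer, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = data.frame(gene_id = gene_ids, roles = unname(roles),
                       stringsAsFactors = FALSE),
    edges = edges
  ), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat("  layers:", paste(sprintf("L%d=%d", sort(unique(x$edges$layer)),
        table(x$edges$layer)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the three-layer gene regulatory network
#'
#' Layer 1: significant co-expression among PrLPs. Layer 2: co-expression
#' between PrLPs and transcription factors. Layer 3: stress- and
#' memory-related genes correlated with the prionome. Each edge is tagged
#' with the lowest layer in which it appears; duplicate pairs collapse to
#' that layer. Genes absent from every role table become nodes with empty
#' roles (with a warning).
#'
#' @param prlp_edges,tf_edges,stress_memory_edges Data frames with
#'   `source`, `target`, `sign` columns (already thresholded).
#' @param role_tables Named list of role id vectors (see
#'   [grn_network()]).
#' @return A `grn` object.
#' @export
assemble_layers <- function(prlp_edges, tf_edges, stress_memory_edges,
                            role_tables) {
  tag <- function(df, layer) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(source = character(), target = character(),
                        sign = integer(), layer = integer(),
                        stringsAsFactors = FALSE))
    }
    df <- df[, c("source", "target", "sign"), drop = FALSE]
    df$layer <- layer
    df
  }
  edges <- rbind(tag(prlp_edges, 1L), tag(tf_edges, 2L),
                 tag(stress_memory_edges, 3L))
  known <- unlist(role_tables, use.names = FALSE)
  unknown <- setdiff(unique(c(edges$source, edges$target)), known)
  if (length(unknown)) {
    warning("gene(s) absent from all role tables get empty roles: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
  }
  grn_network(edges, role_tables)
}

#' Node degrees of a GRN
#' @param network A `grn` object.
#' @return Named integer vector (every node, including isolates).
#' @export
grn_degrees <- function(network) {
  degs <- stats::setNames(integer(nrow(network$nodes)),
                          network$nodes$gene_id)
  tab <- table(c(network$edges$source, network$edges$target))
  degs[names(tab)] <- as.integer(tab)
  degs
}

#' Find hub nodes by degree
#'
#' Hubs are the nodes in the top `top_fraction` of the degree ranking;
#' all ties at the boundary degree are included (so a regular graph is
#' all hubs).
#'
#' @param network A `grn` object.
#' @param top_fraction Fraction of nodes to take; default 0.05.
#' @return Character vector of hub gene ids (sorted by decreasing
#'   degree, ties by id).
#' @export
find_hubs <- function(network, top_fraction = 0.05) {
  degs <- grn_degrees(network)
  if (!length(degs)) return(character(0))
  k <- max(1L, ceiling(length(degs) * top_fraction))
  cutoff <- sort(degs, decreasing = TRUE)[k]
  hubs <- degs[degs >= cutoff]
  names(hubs)[order(-hubs, names(hubs))]
}

#' Export a network as a SIF edge list
#'
#' One line per edge: `source<TAB>relation<TAB>target`, relation `pos`
#' or `neg`.
#'
#' @param network A `grn` object.
#' @param path Output path.
#' @export
export_sif <- function(network, path) {
  e <- network$edges
  lines <- if (nrow(e)) {
    paste(e$source, ifelse(e$sign >= 0, "pos", "neg"), e$target,
          sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Import a SIF edge list as a network
#'
#' @param path SIF path (3 tab-separated columns; relation `pos`/`neg`).
#' @param role_tables Optional role tables for node annotation.
#' @return A `grn` object (layer set to 1 for all edges).
#' @export
import_sif <- function(path, role_tables = list()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3 |
                 !vapply(parts, function(p) p[2] %in% c("pos", "neg"),
                         logical(1)))
  if (length(bad)) {
    stop("malformed SIF line ", bad[1], ": ", lines[bad[1]])
  }
  edges <- if (length(parts)) {
    data.frame(source = vapply(parts, `[`, "", 1),
               target = vapply(parts, `[`, "", 3),
               sign = ifelse(vapply(parts, `[`, "", 2) == "pos", 1L, -1L),
               layer = 1L, stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               sign = integer(), layer = integer(),
               stringsAsFactors = FALSE)
  }
  grn_network(edges, role_tables)
}

#' Write node attributes (roles, degree) as a sidecar TSV
#' @param network A `grn` object.
#' @param path Output path.
#' @export
write_node_attributes_tsv <- function(network, path) {
  df <- network$nodes
  df$degree <- as.integer(grn_degrees(network)[df$gene_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
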