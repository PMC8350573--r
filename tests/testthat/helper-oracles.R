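# Shared fixtures and independent oracles used across test files.

# llr table whose per-residue scores we can control exactly: start from
# the packaged tables, then overwrite the llr map (the scanner consumes
# only $llr).
flat_llr_table <- function(value = 0.5) {
  tab <- build_llr_table()
  tab$llr <- stats::setNames(rep(value, length(CANONICAL_AA)),
                             CANONICAL_AA)
  tab
}

random_aa_seq <- function(n, freqs = aa_composition("species_background")) {
  paste(sample(CANONICAL_AA, n, replace = TRUE, prob = freqs),
        collapse = "")
}

# brute-force oracle: best window of exactly l_core by direct summation
oracle_core_score <- function(sequence, llr_table, l_core) {
  chars <- strsplit(sequence, "")[[1]]
  vals <- llr_table$llr[chars]
  vals[is.na(vals)] <- 0
  n <- length(vals)
  if (n < l_core) return(NULL)
  scores <- vapply(seq_len(n - l_core + 1), function(i)
    sum(vals[i:(i + l_core - 1)]), numeric(1))
  i <- match(TRUE, scores >= max(scores) - 1e-9)  # leftmost near-tie
  list(score = scores[i], core_start = i, core_end = i + l_core - 1L)
}

# exhaustive oracle: best segment [i, j] containing the core window
oracle_domain <- function(sequence, llr_table, core_start, core_end) {
  chars <- strsplit(sequence, "")[[1]]
  vals <- llr_table$llr[chars]
  vals[is.na(vals)] <- 0
  n <- length(vals)
  best <- -Inf
  best_ij <- c(core_start, core_end)
  for (i in seq_len(core_start)) {
    for (j in core_end:n) {
      s <- sum(vals[i:j])
      if (s > best + 1e-12) {
        best <- s
        best_ij <- c(i, j)
      }
    }
  }
  list(domain_start = best_ij[1], domain_end = best_ij[2])
}

# textbook double-loop correlation oracle (sums computed by hand)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# Erdos-Renyi edge list on node ids v1..vn (character)
random_edges <- function(n, p, prefix = "v") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(source = pairs[keep, 1], target = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# independent MCODE weight oracle built on igraph's coreness
oracle_weights <- function(edges, isolated = character(0),
                           degree_cutoff = 2) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(unique(c(
                                       edges$source, edges$target,
                                       isolated))))
  w <- stats::setNames(numeric(igraph::vcount(g)),
                       igraph::V(g)$name)
  for (v in igraph::V(g)$name) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
    if (length(nb) < degree_cutoff) next
    sub <- igraph::induced_subgraph(g, c(v, nb))
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    core <- igraph::induced_subgraph(sub,
                                     igraph::V(sub)[cores == kmax])
    nv <- igraph::vcount(core)
    w[[v]] <- kmax * 2 * igraph::ecount(core) / (nv * (nv - 1))
  }
  w
}

# two K5 cliques joined by a single bridge edge
bridged_k5_edges <- function() {
  k5 <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(source = p[, 1], target = p[, 2],
               stringsAsFactors = FALSE)
  }
  a <- sprintf("A%d", 1:5)
  b <- sprintf("B%d", 1:5)
  rbind(k5(a), k5(b),
        data.frame(source = "A1", target = "B1",
                   stringsAsFactors = FALSE))
}

# planted dense-module graph: n_mod modules of m_size with intra edge
# prob p_in, embedded in a background of n_noise noise nodes; background
# edges (prob p_out) involve at least one noise node, so distinct
# modules touch only through the background
planted_module_graph <- function(n_mod = 5, m_size = 8, n_noise = 40,
                                 p_in = 0.9, p_out = 0.05) {
  total <- n_mod * m_size + n_noise
  ids <- sprintf("n%03d", seq_len(total))
  module_of <- c(rep(seq_len(n_mod), each = m_size), rep(0, n_noise))
  pairs <- t(combn(seq_len(total), 2))
  same <- module_of[pairs[, 1]] != 0 &
    module_of[pairs[, 1]] == module_of[pairs[, 2]]
  cross <- module_of[pairs[, 1]] != 0 & module_of[pairs[, 2]] != 0 &
    !same
  keep <- stats::runif(nrow(pairs)) <
    ifelse(same, p_in, ifelse(cross, 0, p_out))
  list(edges = data.frame(source = ids[pairs[keep, 1]],
                          target = ids[pairs[keep, 2]],
                          stringsAsFactors = FALSE),
       modules = split(ids[module_of != 0], module_of[module_of != 0]),
       ids = ids)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}
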