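#' Dual-method pairwise correlations between gene expression profiles
#'
#' Computes, for every unordered gene pair, the Pearson and Spearman
#' correlations over samples, each with a two-sided p-value from the
#' t approximation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (Spearman ranks use average ties). Genes with zero
#' variance cannot be correlated; their pairs are excluded and the gene
#' ids recorded in the `zero_variance` attribute (with a warning).
#'
#' @param mat Numeric matrix, genes x samples, >= 3 samples.
#' @return Data frame with columns `gene_a`, `gene_b` (lexicographic,
#'   `gene_a < gene_b`), `r_pearson`, `p_pearson`, `r_spearman`,
#'   `p_spearman`; attribute `n_samples`; attribute `zero_variance`.
#' @export
pairwise_correlations <- function(mat) {
  if (ncol(mat) < 3) stop("need at least 3 samples")
  if (is.null(rownames(mat))) stop("matrix must have gene rownames")
  sds <- apply(mat, 1, stats::sd)
  flat <- rownames(mat)[sds == 0]
  if (length(flat)) {
    warning("excluding zero-variance gene(s): ",
            paste(flat, collapse = ", "))
    mat <- mat[sds > 0, , drop = FALSE]
  }
  n_genes <- nrow(mat)
  n <- ncol(mat)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      r_pearson = numeric(), p_pearson = numeric(),
                      r_spearman = numeric(), p_spearman = numeric(),
                      stringsAsFactors = FALSE)
  if (n_genes < 2) {
    attr(empty, "n_samples") <- n
    attr(empty, "zero_variance") <- flat
    return(empty)
  }
  rp <- stats::cor(t(mat), method = "pearson")
  rs <- stats::cor(t(mat), method = "spearman")
  p_from_r <- function(r) {
    r2 <- pmin(abs(r), 1)
    tt <- r2 * sqrt(n - 2) / sqrt(pmax(1 - r2^2, .Machine$double.eps))
    2 * stats::pt(-tt, df = n - 2)
  }
  idx <- which(upper.tri(rp), arr.ind = TRUE)
  g1 <- rownames(mat)[idx[, 1]]
  g2 <- rownames(mat)[idx[, 2]]
  swap <- g1 > g2
  edges <- data.frame(
    gene_a = ifelse(swap, g2, g1),
    gene_b = ifelse(swap, g1, g2),
    r_pearson = rp[idx],
    p_pearson = p_from_r(rp[idx]),
    r_spearman = rs[idx],
    p_spearman = p_from_r(rs[idx]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_samples") <- n
  attr(edges, "zero_variance") <- flat
  edges
}

#' Threshold dual-method correlation edges into a binary signed matrix
#'
#' An unordered pair becomes a signed entry (+1 or -1) iff both
#' `|r_pearson| >= r_cut` and `|r_spearman| >= r_cut`, both p-values are
#' `< p_cut`, and the two correlation signs agree (`mode = "and"`, the
#' default conservative rule). With `mode = "or"` a pair passes if either
#' method clears both cutoffs; signs must still agree between methods
#' whenever both r are nonzero. Optionally the p-values are
#' Benjamini-Hochberg adjusted (per method) before thresholding.
#'
#' @param edges Data frame from [pairwise_correlations()].
#' @param r_cut Absolute correlation cutoff; default 0.8.
#' @param p_cut P-value cutoff; default 0.01.
#' @param mode `"and"` (both methods must pass) or `"or"`.
#' @param adjust_p If `TRUE`, apply Benjamini-Hochberg to each method's
#'   p-values first; default `FALSE` (raw p-values).
#' @return An object of class `signed_matrix`: list with `genes`,
#'   `entries` (symmetric matrix in {-1, 0, 1}, zero diagonal), `r_cut`,
#'   `p_cut`, and `r_pearson` (the symmetric Pearson matrix, for
#'   downstream clustering).
#' @export
threshold_edges <- function(edges, r_cut = 0.8, p_cut = 0.01,
                            mode = c("and", "or"), adjust_p = FALSE) {
  mode <- match.arg(mode)
  pp <- edges$p_pearson
  ps <- edges$p_spearman
  if (adjust_p) {
    pp <- stats::p.adjust(pp, "BH")
    ps <- stats::p.adjust(ps, "BH")
  }
  pass_p <- abs(edges$r_pearson) >= r_cut & pp < p_cut
  pass_s <- abs(edges$r_spearman) >= r_cut & ps < p_cut
  agree <- sign(edges$r_pearson) == sign(edges$r_spearman)
  call <- if (mode == "and") pass_p & pass_s & agree else
    (pass_p | pass_s) & agree

  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  m <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  rmat <- matrix(NA_real_, length(genes), length(genes),
                 dimnames = list(genes, genes))
  diag(rmat) <- 1
  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  rmat[cbind(ia, ib)] <- edges$r_pearson
  rmat[cbind(ib, ia)] <- edges$r_pearson
  sgn <- ifelse(call, sign(edges$r_pearson), 0L)
  m[cbind(ia, ib)] <- sgn
  m[cbind(ib, ia)] <- sgn
  structure(list(genes = genes, entries = m, r_cut = r_cut, p_cut = p_cut,
                 r_pearson = rmat),
            class = "signed_matrix")
}

#' @export
print.signed_matrix <- function(x, ...) {
  nz <- sum(x$entries != 0) / 2
  cat("signed_matrix:", length(x$genes), "genes,", nz, "edges",
      sprintf("(|r| >= %g, p < %g); %d positive, %d negative\n",
              x$r_cut, x$p_cut,
              sum(x$entries == 1) / 2, sum(x$entries == -1) / 2))
  invisible(x)
}

#' Order genes by loading on the first principal component
#'
#' Computes the first eigenvector of the gene-gene Pearson correlation
#' matrix and orders genes by their loading, the ordering used to lay out
#' correlograms so co-regulated blocks appear contiguous. Orientation is
#' fixed by requiring a non-negative loading for the first gene in input
#' order (the eigenvector sign is otherwise arbitrary).
#'
#' @param x Either an expression matrix (genes x samples, rownames) or a
#'   square correlation matrix with dimnames.
#' @return Character vector of gene ids in first-PC order.
#' @export
order_by_first_pc <- function(x) {
  r <- if (nrow(x) == ncol(x) &&
           !is.null(rownames(x)) && identical(rownames(x), colnames(x))) {
    x
  } else {
    stats::cor(t(x))
  }
  genes <- rownames(r)
  if (length(genes) == 1) return(genes)
  if (anyNA(r) || all(abs(r) < .Machine$double.eps)) {
    warning("degenerate correlation matrix; keeping input order")
    return(genes)
  }
  ev <- eigen(r, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[1] < 0) v <- -v
  genes[order(v, decreasing = TRUE)]
}

#' Cluster the thresholded prionome and flag inter-cluster antagonism
#'
#' Average-linkage hierarchical clustering of genes on the distance
#' `1 - r` (Pearson), cut into `k` clusters. The antagonism flag is TRUE
#' when more than half of the nonzero inter-cluster entries of the binary
#' signed matrix are negative — the signature of two mutually
#' antagonistic co-expression modules.
#'
#' @param bsm A [threshold_edges()] `signed_matrix`.
#' @param k Number of clusters; default 2.
#' @return List with `labels` (named integer cluster assignment; empty
#'   when the matrix has no nonzero entries), `antagonistic` (logical),
#'   and `n_inter_neg` / `n_inter_edges` counts.
#' @export
detect_sign_clusters <- function(bsm, k = 2) {
  stopifnot(inherits(bsm, "signed_matrix"))
  if (all(bsm$entries == 0)) {
    return(list(labels = integer(0), antagonistic = FALSE,
                n_inter_neg = 0L, n_inter_edges = 0L))
  }
  d <- stats::as.dist(1 - bsm$r_pearson)
  labels <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  inter <- outer(labels, labels, "!=") & upper.tri(bsm$entries)
  vals <- bsm$entries[inter]
  n_edges <- sum(vals != 0)
  n_neg <- sum(vals == -1)
  list(labels = labels,
       antagonistic = n_edges > 0 && n_neg / n_edges > 0.5,
       n_inter_neg = as.integer(n_neg),
       n_inter_edges = as.integer(n_edges))
}

#' Write the long-form edge table and signed matrix to TSV
#'
#' @param edges Data frame from [pairwise_correlations()].
#' @param bsm A [threshold_edges()] object (for the `call` column and the
#'   matrix file).
#' @param edges_path,matrix_path Output paths (either may be `NULL`).
#' @export
write_coexpression_tsv <- function(edges, bsm, edges_path = NULL,
                                   matrix_path = NULL) {
  if (!is.null(edges_path)) {
    ia <- match(edges$gene_a, bsm$genes)
    ib <- match(edges$gene_b, bsm$genes)
    edges$call <- bsm$entries[cbind(ia, ib)]
    utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(matrix_path)) {
    df <- data.frame(gene_id = bsm$genes, bsm$entries, check.names = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
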