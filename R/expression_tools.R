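#' Ratio of expression potential
#'
#' `(mean_value - signal_background) / (expression_potential -
#' signal_background + epsilon)`. The epsilon (default 1) keeps the
#' denominator positive when the expression potential and the signal
#' background (nearly) coincide.
#'
#' @param mean_value Mean signal of the gene under the condition.
#' @param signal_background Platform background signal.
#' @param expression_potential Maximal expression of the gene across
#'   conditions; must be >= `signal_background`.
#' @param epsilon Denominator guard; default 1.
#' @return The ratio (numeric).
#' @export
expression_potential_ratio <- function(mean_value, signal_background,
                                       expression_potential, epsilon = 1) {
  if (any(signal_background < 0)) stop("signal_background must be >= 0")
  if (any(expression_potential < signal_background)) {
    stop("expression_potential must be >= signal_background")
  }
  (mean_value - signal_background) /
    (expression_potential - signal_background + epsilon)
}

#' Min-max normalize a numeric vector to [0, 1]
#'
#' `(x - min) / (max - min)`; constant vectors map to all zeros.
#'
#' @param row Numeric vector (length >= 1).
#' @return Vector in `[0, 1]`, same length.
#' @export
minmax_normalize <- function(row) {
  rng <- range(row)
  if (rng[1] == rng[2]) return(rep(0, length(row)))
  (row - rng[1]) / (rng[2] - rng[1])
}

#' Min-max normalize every row of an expression matrix
#' @param mat Numeric matrix (genes x samples).
#' @return Matrix with every row rescaled to `[0, 1]`.
#' @export
minmax_normalize_matrix <- function(mat) {
  t(apply(mat, 1, minmax_normalize)) |>
    `dimnames<-`(dimnames(mat))
}

#' Log2 fold change with pseudocount
#'
#' `log2((treatment + pseudocount) / (control + pseudocount))`.
#'
#' @param treatment,control Non-negative expression values.
#' @param pseudocount Added to both; default 1.
#' @return log2 fold change.
#' @export
log2_fold_change <- function(treatment, control, pseudocount = 1) {
  log2((treatment + pseudocount) / (control + pseudocount))
}

#' Filter tabular alignment hits to the best homolog per query
#'
#' Rows must pass all three cutoffs (strict inequalities): `e_value <
#' evalue_max`, query coverage `> coverage_min` percent, and
#' `percent_identity > identity_min` percent, with coverage defined as
#' `100 * alignment_length / query_length`. Among passing rows, each
#' query keeps the row with the minimal e-value; ties resolve to maximal
#' `bit_score`, then lexicographic `subject_id`.
#'
#' @param rows Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `bit_score`, and
#'   `query_length` (join one in from a lengths table if absent).
#' @param evalue_max E-value cutoff; default `1e-5`.
#' @param coverage_min Coverage cutoff (percent); default 50.
#' @param identity_min Identity cutoff (percent); default 35.
#' @return Data frame, at most one row per query, with a `coverage`
#'   column added.
#' @export
filter_homologs <- function(rows, evalue_max = 1e-5, coverage_min = 50,
                            identity_min = 35) {
  required <- c("query_id", "subject_id", "percent_identity",
                "alignment_length", "e_value", "bit_score", "query_length")
  missing <- setdiff(required, names(rows))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(rows$query_length)) {
    stop("missing query_length for query: ",
         paste(unique(rows$query_id[is.na(rows$query_length)]),
               collapse = ", "))
  }
  rows$coverage <- 100 * rows$alignment_length / rows$query_length
  keep <- rows$e_value < evalue_max &
    rows$coverage > coverage_min &
    rows$percent_identity > identity_min
  passing <- rows[keep, , drop = FALSE]
  if (!nrow(passing)) return(passing)
  ord <- order(passing$query_id, passing$e_value, -passing$bit_score,
               passing$subject_id)
  passing <- passing[ord, , drop = FALSE]
  passing[!duplicated(passing$query_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Read a 12-column tabular alignment file (outfmt-6 dialect)
#'
#' Columns: query_id, subject_id, percent_identity, alignment_length,
#' mismatches, gap_opens, q_start, q_end, s_start, s_end, e_value,
#' bit_score. Query lengths are joined in from a two-column lengths TSV
#' (`query_id`, `query_length`).
#'
#' @param path Alignment TSV path.
#' @param lengths_path Optional query-lengths TSV path.
#' @return Data frame of [AlignmentRow][filter_homologs] columns.
#' @export
read_alignment_tsv <- function(path, lengths_path = NULL) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "q_start",
            "q_end", "s_start", "s_end", "e_value", "bit_score")
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = cols)
  if (!is.null(lengths_path)) {
    len <- utils::read.table(lengths_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    df$query_length <- len$query_length[match(df$query_id, len$query_id)]
  }
  df
}

#' Read an expression matrix TSV (genes in rows, sample header)
#'
#' @param path TSV path; first column gene ids, remaining columns samples.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE)
  mat <- as.matrix(df)
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  mat
}

#' Write an expression matrix TSV
#' @param mat Numeric matrix, gene rownames, sample colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
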