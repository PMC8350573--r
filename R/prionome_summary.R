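#' Prionome density
#'
#' Fraction of a proteome called as prion-like: `n_prlps / proteome_size`.
#'
#' @param n_prlps Number of called PrLPs.
#' @param proteome_size Total proteins in the proteome (>= 1).
#' @return Exact quotient (tables display it to 4 decimals).
#' @export
compute_density <- function(n_prlps, proteome_size) {
  if (proteome_size < 1) stop("proteome_size must be >= 1")
  if (n_prlps < 0 || n_prlps > proteome_size) {
    stop("n_prlps must lie in [0, proteome_size]")
  }
  n_prlps / proteome_size
}

#' Default functional category rules
#'
#' An ordered keyword -> category priority list emulating a ten-category
#' functional classification of prion-like proteins. The rules are
#' illustrative keyword heuristics (annotation pipelines differ); the
#' transposon/retrotransposon category is the one the Ts/RTR share is
#' computed from.
#'
#' @return A list of `(category, keywords)` pairs, highest priority first.
#' @export
default_category_rules <- function() {
  list(
    list(category = "Ts/RTR",
         keywords = c("transposon", "retrotransposon", "transposable",
                      "gag-pol", "polyprotein", "reverse transcriptase")),
    list(category = "RNA-binding/regulation/transcription",
         keywords = c("rna-binding", "rna binding", "rna recognition",
                      "rrm", "helicase", "exonuclease", "splicing")),
    list(category = "DNA-binding/replication/TF",
         keywords = c("transcription factor", "dna-binding", "dna binding",
                      "zinc finger", "homeobox", "bzip", "myb")),
    list(category = "Transport",
         keywords = c("transporter", "transport", "carrier", "channel")),
    list(category = "Signaling",
         keywords = c("kinase", "phosphatase", "receptor", "signaling")),
    list(category = "Flowering/development",
         keywords = c("flowering", "floral", "development", "meristem")),
    list(category = "Stress response",
         keywords = c("stress", "heat shock", "cold", "drought")),
    list(category = "Metabolism",
         keywords = c("synthase", "metabolism", "metabolic", "oxidase",
                      "reductase")),
    list(category = "Protein fate",
         keywords = c("ubiquitin", "protease", "proteasome", "chaperone")),
    list(category = "Chromatin",
         keywords = c("histone", "chromatin", "methyltransferase"))
  )
}

#' Assign a functional category from free-text annotation
#'
#' Case-insensitive keyword matching against an ordered priority list of
#' rules; the first rule with any matching keyword wins, otherwise
#' `"unclassified"`.
#'
#' @param annotation_text Free-text description of the protein/gene.
#' @param category_rules Ordered list of `(category, keywords)` rules,
#'   e.g. [default_category_rules()].
#' @return Category label (character scalar).
#' @export
categorize <- function(annotation_text,
                       category_rules = default_category_rules()) {
  if (!length(category_rules)) {
    warning("empty category rules: everything is unclassified")
    return("unclassified")
  }
  text <- tolower(annotation_text)
  for (rule in category_rules) {
    if (any(vapply(tolower(rule$keywords),
                   function(k) grepl(k, text, fixed = TRUE), logical(1)))) {
      return(rule$category)
    }
  }
  "unclassified"
}

#' Collapse protein-level prionome entries to gene level
#'
#' Isoforms sharing a `gene_id` collapse to one row, keeping the maximum
#' `core_score` (and that row's other fields).
#'
#' @param entries Data frame with at least `gene_id` and `core_score`.
#' @return Data frame with one row per gene.
#' @export
collapse_to_genes <- function(entries) {
  if (!nrow(entries)) return(entries)
  ord <- order(entries$gene_id, -entries$core_score)
  e <- entries[ord, , drop = FALSE]
  e[!duplicated(e$gene_id), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Summarize a prionome
#'
#' Per-category counts and percentage shares, the Ts/RTR share, and the
#' prionome density. Percentages are exact internally and rounded to the
#' nearest integer for the `pct_display` column.
#'
#' @param entries Data frame with columns `category` (and optionally
#'   `species`); one row per counted entity (proteins or genes).
#' @param proteome_size Total proteins in the proteome.
#' @param ts_rtr_category Label of the transposon/retrotransposon
#'   category; default `"Ts/RTR"`.
#' @return A list of class `prionome_summary`: `species`, `n_prlps`,
#'   `proteome_size`, `density`, `categories` (data.frame with `category`,
#'   `count`, `pct`, `pct_display`), and `ts_rtr_share_pct` (exact
#'   percentage, NA when `n_prlps` is 0).
#' @export
#' @examples
#' e <- data.frame(category = c(rep("Ts/RTR", 131), rep("Other", 70)))
#' s <- summarize_prionome(e, proteome_size = 55000)
#' round(s$ts_rtr_share_pct)  # 65
summarize_prionome <- function(entries, proteome_size,
                               ts_rtr_category = "Ts/RTR") {
  species <- if (nrow(entries) && "species" %in% names(entries)) {
    sp <- unique(entries$species)
    if (length(sp) > 1) stop("entries span multiple species: ",
                             paste(sp, collapse = ", "))
    sp
  } else NA_character_
  n <- nrow(entries)
  tab <- if (n) table(entries$category) else NULL
  categories <- data.frame(
    category = if (is.null(tab)) character(0) else names(tab),
    count = if (is.null(tab)) integer(0) else as.integer(tab),
    stringsAsFactors = FALSE
  )
  categories$pct <- if (n) 100 * categories$count / n else numeric(nrow(categories))
  categories$pct_display <- round(categories$pct)
  ts <- categories$pct[categories$category == ts_rtr_category]
  structure(
    list(species = species,
         n_prlps = n,
         proteome_size = proteome_size,
         density = compute_density(n, proteome_size),
         categories = categories[order(-categories$count,
                                       categories$category), , drop = FALSE],
         ts_rtr_share_pct = if (length(ts)) ts else if (n) 0 else NA_real_),
    class = "prionome_summary"
  )
}

#' @export
print.prionome_summary <- function(x, ...) {
  cat("Prionome summary", if (!is.na(x$species)) paste0("(", x$species, ")"),
      "\n  PrLPs:", x$n_prlps, "of", x$proteome_size,
      sprintf("(density %.4f)\n", x$density))
  if (nrow(x$categories)) {
    print(x$categories, row.names = FALSE)
  }
  invisible(x)
}

#' Write a prionome summary table to TSV
#' @param summary A [summarize_prionome()] object.
#' @param path Output path.
#' @export
write_summary_tsv <- function(summary, path) {
  df <- summary$categories
  n <- nrow(df)
  df$species <- rep(summary$species, n)
  df$n_prlps <- rep(summary$n_prlps, n)
  df$proteome_size <- rep(summary$proteome_size, n)
  df$density <- rep(round(summary$density, 4), n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
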