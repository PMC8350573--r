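#' Build a log-likelihood-ratio table for prion-like-domain scoring
#'
#' The per-residue score is `log2(foreground / blended_background)`, in
#' bits, where the background blends a species-specific composition with a
#' default composition:
#' `blended = (alpha/100) * species_bg + (1 - alpha/100) * default_bg`.
#' `alpha = 100` scores against the species background alone, `alpha = 0`
#' against the default background alone.
#'
#' @param foreground Named frequencies over [CANONICAL_AA] (prion-domain
#'   composition). Defaults to the packaged Q/N-rich table.
#' @param species_bg,default_bg Named background frequencies over
#'   [CANONICAL_AA].
#' @param alpha Blend percentage in `[0, 100]`; default 50.
#' @return An object of class `llr_table`: a list with elements
#'   `foreground_freqs`, `species_bg_freqs`, `default_bg_freqs`, `alpha`,
#'   and `llr` (named numeric, bits).
#' @export
#' @examples
#' tab <- build_llr_table()
#' tab$llr[["Q"]] > 0  # Q is enriched in prion domains
build_llr_table <- function(foreground = aa_composition("prion_foreground"),
                            species_bg = aa_composition("species_background"),
                            default_bg = aa_composition("default_background"),
                            alpha = 50) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 100) {
    stop("`alpha` must be a single number in [0, 100], got: ", alpha)
  }
  check_freqs <- function(x, what) {
    missing <- setdiff(CANONICAL_AA, names(x))
    if (length(missing)) {
      stop(what, " is missing entries for: ", paste(missing, collapse = ", "))
    }
    x <- x[CANONICAL_AA]
    if (abs(sum(x) - 1) > 1e-9) {
      stop(what, " frequencies must sum to 1 (got ", format(sum(x)), ")")
    }
    x
  }
  foreground <- check_freqs(foreground, "foreground")
  species_bg <- check_freqs(species_bg, "species background")
  default_bg <- check_freqs(default_bg, "default background")

  w <- alpha / 100
  blended <- w * species_bg + (1 - w) * default_bg
  bad <- names(blended)[blended <= 0]
  if (length(bad)) {
    stop("blended background frequency is not positive for residue(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      foreground_freqs = foreground,
      species_bg_freqs = species_bg,
      default_bg_freqs = default_bg,
      alpha = alpha,
      llr = log2(foreground / blended)
    ),
    class = "llr_table"
  )
}

#' @export
print.llr_table <- function(x, ...) {
  cat("llr_table (bits), alpha =", x$alpha, "\n")
  print(round(x$llr, 3))
  invisible(x)
}

# Per-residue LLR vector for a sequence string; ambiguity codes and any
# letter outside the canonical alphabet contribute 0.
.residue_llr <- function(sequence, llr_table) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  vals <- llr_table$llr[chars]
  vals[is.na(vals)] <- 0
  unname(vals)
}

#' Best fixed-length window score (COREscore) of a protein sequence
#'
#' Scans all contiguous windows of exactly `l_core` residues and returns
#' the maximum window sum of per-residue log-likelihood ratios, together
#' with the 1-based inclusive window coordinates. Ties resolve to the
#' leftmost window. Sequences shorter than `l_core` are unscorable and
#' return `NULL` (proteome-level scans record them as such rather than
#' erroring).
#'
#' @param sequence Amino-acid string.
#' @param llr_table An [build_llr_table()] object.
#' @param l_core Window length (residues); default 60.
#' @return A list `(score, core_start, core_end)`, or `NULL` if the
#'   sequence is shorter than `l_core`.
#' @export
core_score <- function(sequence, llr_table, l_core = 60) {
  stopifnot(inherits(llr_table, "llr_table"), l_core >= 1)
  n <- nchar(sequence)
  if (n < l_core) return(NULL)
  vals <- .residue_llr(sequence, llr_table)
  cs <- cumsum(c(0, vals))
  win <- cs[(l_core + 1):(n + 1)] - cs[1:(n - l_core + 1)]
  # leftmost maximum, with a tolerance so that windows whose sums are
  # analytically tied (same residue multiset) are not split by
  # floating-point accumulation order
  i <- match(TRUE, win >= max(win) - 1e-9)
  list(score = win[i], core_start = i, core_end = i + l_core - 1L)
}

#' Expand a scored core window to maximal-scoring domain boundaries
#'
#' Returns the contiguous segment containing the core window whose total
#' LLR sum is maximal over all such segments. Because the left and right
#' extensions contribute independently, the optimum is the core plus the
#' best-scoring left suffix and right prefix, each included only if its
#' sum is strictly positive.
#'
#' @param sequence Amino-acid string.
#' @param llr_table An [build_llr_table()] object.
#' @param core_start,core_end 1-based inclusive core window from
#'   [core_score()].
#' @return A list `(domain_start, domain_end)`, 1-based inclusive.
#' @export
domain_boundaries <- function(sequence, llr_table, core_start, core_end) {
  n <- nchar(sequence)
  stopifnot(core_start >= 1, core_end >= core_start, core_end <= n)
  vals <- .residue_llr(sequence, llr_table)

  domain_start <- core_start
  if (core_start > 1) {
    left <- vals[(core_start - 1):1]          # walking outward
    sums <- cumsum(left)
    if (max(sums) > 0) {
      domain_start <- core_start - which.max(sums)
    }
  }
  domain_end <- core_end
  if (core_end < n) {
    right <- vals[(core_end + 1):n]
    sums <- cumsum(right)
    if (max(sums) > 0) {
      domain_end <- core_end + which.max(sums)
    }
  }
  list(domain_start = domain_start, domain_end = domain_end)
}

#' Call prion-like domains across a proteome
#'
#' Scores every protein with [core_score()] and keeps those whose
#' COREscore is at or above `threshold`. The result is sorted by
#' descending score, ties by protein id.
#'
#' @param proteome Named character vector of amino-acid sequences, or an
#'   `Biostrings::AAStringSet`. Names are protein ids and must be unique.
#' @param llr_table An [build_llr_table()] object.
#' @param l_core Core window length; default 60.
#' @param threshold COREscore cutoff in bits; default 25. Comparison is
#'   `>=`.
#' @return A data.frame with columns `protein_id`, `core_start`,
#'   `core_end`, `core_score`, `domain_start`, `domain_end` (1-based
#'   inclusive coordinates).
#' @export
call_prlds <- function(proteome, llr_table, l_core = 60, threshold = 25) {
  if (methods::is(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  ids <- names(proteome)
  if (length(proteome) && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
    stop("every protein must have an id (names on the sequence vector)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  hits <- lapply(seq_along(proteome), function(i) {
    cs <- core_score(proteome[[i]], llr_table, l_core)
    if (is.null(cs) || cs$score < threshold) return(NULL)
    dom <- domain_boundaries(proteome[[i]], llr_table,
                             cs$core_start, cs$core_end)
    data.frame(protein_id = ids[i],
               core_start = cs$core_start, core_end = cs$core_end,
               core_score = cs$score,
               domain_start = dom$domain_start,
               domain_end = dom$domain_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(hits, list(.empty_hits())))
  out[order(-out$core_score, out$protein_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

.empty_hits <- function() {
  data.frame(protein_id = character(), core_start = integer(),
             core_end = integer(), core_score = numeric(),
             domain_start = integer(), domain_end = integer(),
             stringsAsFactors = FALSE)
}

#' Read a protein FASTA file as a named character vector
#'
#' The first whitespace-delimited token of each header is the protein id;
#' the remainder is kept as the description attribute.
#'
#' @param path Path to a (multi-)FASTA amino-acid file.
#' @return Named character vector of uppercase sequences, with a
#'   `descriptions` attribute (named character).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  out <- stats::setNames(toupper(as.character(aa)), ids)
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

#' Write PrLD hits to TSV
#'
#' @param hits Data frame from [call_prlds()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PrLD hits TSV written by [write_hits_tsv()]
#' @param path Input path.
#' @return Data frame of hits.
#' @export
read_hits_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
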