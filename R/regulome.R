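#' Extract strand-aware promoter regions from a genome and its annotation
#'
#' For each gene the transcription start site (TSS) is the 5'-most base
#' of the representative mRNA (the longest; ties by feature id; genes
#' without mRNA children fall back to the gene feature itself). The
#' promoter covers `upstream` bases 5' of the TSS plus `downstream` bases
#' starting at the TSS (the TSS base is the first base of the downstream
#' segment), so an interior promoter is `upstream + downstream` bases
#' (default 1,500 + 200 = 1,700). Minus-strand promoters are
#' reverse-complemented so the sequence reads promoter-oriented
#' (5' -> 3' toward the gene). Intervals are clipped at contig edges and
#' flagged `truncated`.
#'
#' @param gff3 Path to a GFF3 file, or a `GRanges` of gene/mRNA features
#'   with `type`, `ID`, `Parent` metadata columns.
#' @param genome Path to a genome FASTA, or a `Biostrings::DNAStringSet`
#'   named by chromosome.
#' @param upstream,downstream Promoter extent in bp; defaults 1500 / 200.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open genomic coordinates), `truncated`, and
#'   `sequence` (promoter-oriented).
#' @export
extract_promoters <- function(gff3, genome, upstream = 1500,
                              downstream = 200) {
  gr <- if (is.character(gff3)) rtracklayer::import(gff3) else gff3
  dna <- if (is.character(genome)) {
    Biostrings::readDNAStringSet(genome)
  } else genome
  names(dna) <- sub("\\s.*$", "", names(dna))

  types <- as.character(gr$type)
  genes <- gr[types == "gene"]
  mrnas <- gr[types == "mRNA"]
  mrna_parent <- if (length(mrnas)) {
    vapply(mrnas$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else character(0)

  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    gene_id <- g$ID
    if (is.na(GenomicRanges::start(g)) || is.na(GenomicRanges::end(g))) {
      warning("gene without coordinates skipped: ", gene_id)
      return(NULL)
    }
    chrom <- as.character(GenomicRanges::seqnames(g))
    if (!chrom %in% names(dna)) {
      stop("chromosome absent from genome FASTA: ", chrom)
    }
    kids <- mrnas[!is.na(mrna_parent) & mrna_parent == gene_id]
    rep_feat <- if (length(kids)) {
      w <- GenomicRanges::width(kids)
      cand <- kids[w == max(w)]
      ids <- as.character(cand$ID)
      cand[order(ids)][1]
    } else g
    strand <- as.character(GenomicRanges::strand(rep_feat))
    if (!strand %in% c("+", "-")) {
      warning("gene without usable strand skipped: ", gene_id)
      return(NULL)
    }
    # TSS as a 0-based coordinate of the 5'-most transcribed base
    tss0 <- if (strand == "+") GenomicRanges::start(rep_feat) - 1L
            else GenomicRanges::end(rep_feat) - 1L
    if (strand == "+") {
      s0 <- tss0 - upstream
      e0 <- tss0 + downstream
    } else {
      s0 <- tss0 - downstream + 1L
      e0 <- tss0 + upstream + 1L
    }
    clen <- length(dna[[chrom]])
    cs <- max(s0, 0L)
    ce <- min(e0, clen)
    truncated <- (cs != s0) || (ce != e0)
    seq <- as.character(Biostrings::subseq(dna[[chrom]], cs + 1L, ce))
    if (strand == "-") {
      seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               start = cs, end = ce, truncated = truncated,
               sequence = seq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), truncated = logical(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write promoter sequences to FASTA
#' @param promoters Data frame from [extract_promoters()].
#' @param path Output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- promoters$gene_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a JASPAR-style plain-count position weight matrix
#'
#' Accepts the 4-line plain format, with or without a `>` header line and
#' with or without `A [ ... ]` decoration.
#'
#' @param path PWM file path.
#' @return 4 x L numeric count matrix with rownames A, C, G, T.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4) stop("expected 4 count rows, got ", length(lines))
  parse_row <- function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[?", "", trimws(l))
    l <- gsub("\\]$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }
  m <- do.call(rbind, lapply(lines, parse_row))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Convert a count PWM to log2-odds against a background
#'
#' @param counts 4 x L count matrix (rownames A, C, G, T).
#' @param pseudocount Added to every cell before normalizing; default
#'   0.25.
#' @param background Background base frequencies; default uniform.
#' @return 4 x L log2-odds matrix.
#' @export
pwm_log_odds <- function(counts, pseudocount = 0.25,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  stopifnot(nrow(counts) == 4)
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  log2(probs / background[rownames(counts)])
}

#' Consensus sequence of a count PWM
#' @param counts 4 x L count matrix.
#' @return Consensus string (ties to the first of A,C,G,T).
#' @export
pwm_consensus <- function(counts) {
  paste(rownames(counts)[apply(counts, 2, which.max)], collapse = "")
}

.REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Scan a promoter sequence with a log-odds PWM on both strands
#'
#' Every window of the motif length is scored on the forward sequence and
#' on its reverse complement; windows containing `N` are skipped. A hit
#' is a window whose log-odds score is `>= score_threshold`.
#'
#' @param promoter Promoter sequence (character scalar, promoter
#'   oriented).
#' @param pwm 4 x L log2-odds matrix from [pwm_log_odds()].
#' @param score_threshold Minimum window score.
#' @return Data frame with `offset` (0-based position of the window start
#'   on the forward promoter), `strand` (`+`/`-`), `score`.
#' @export
scan_binding_sites <- function(promoter, pwm, score_threshold) {
  L <- ncol(pwm)
  n <- nchar(promoter)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  chars <- strsplit(toupper(promoter), "", fixed = TRUE)[[1]]
  score_strand <- function(cv, strand) {
    idx <- match(cv, c("A", "C", "G", "T"))
    nw <- length(cv) - L + 1
    scores <- numeric(nw)
    for (j in seq_len(L)) {
      col <- pwm[, j][idx[j:(j + nw - 1)]]
      col[is.na(col)] <- -Inf          # window spans N or ambiguity
      scores <- scores + col
    }
    i <- which(scores >= score_threshold)
    if (!length(i)) return(NULL)
    # map reverse-strand window starts back to forward coordinates
    off <- if (strand == "+") i - 1L else length(cv) - (i + L - 1L)
    data.frame(offset = as.integer(off), strand = strand,
               score = scores[i], stringsAsFactors = FALSE)
  }
  rc <- rev(unname(.REVCOMP[chars]))
  rc[is.na(rc)] <- "N"
  out <- rbind(score_strand(chars, "+"), score_strand(rc, "-"))
  if (is.null(out)) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a TF -> target binding-evidence table by scanning promoters
#'
#' @param promoters Data frame from [extract_promoters()].
#' @param tf_pwms Named list of log-odds PWMs (names = TF ids).
#' @param score_threshold Minimum window score (scalar or per-TF named
#'   vector).
#' @return Data frame with `tf_id`, `target_gene_id`, `source` ("scan"),
#'   `offset`, `score` (best hit per pair).
#' @export
scan_evidence <- function(promoters, tf_pwms, score_threshold) {
  thr_of <- function(tf) if (length(score_threshold) > 1)
    score_threshold[[tf]] else score_threshold
  # TFs sharing a PWM and threshold share one scan of the promoters
  keys <- vapply(names(tf_pwms), function(tf)
    paste(c(dim(tf_pwms[[tf]]), tf_pwms[[tf]], thr_of(tf)),
          collapse = ","), character(1))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(names(tf_pwms), function(tf) {
    key <- keys[[tf]]
    if (is.null(cache[[key]])) {
      cache[[key]] <- list(do.call(rbind, lapply(seq_len(nrow(promoters)),
        function(i) {
          hits <- scan_binding_sites(promoters$sequence[i],
                                     tf_pwms[[tf]], thr_of(tf))
          if (!nrow(hits)) return(NULL)
          best <- hits[which.max(hits$score), , drop = FALSE]
          data.frame(target_gene_id = promoters$gene_id[i],
                     source = "scan", offset = best$offset,
                     score = best$score, stringsAsFactors = FALSE)
        })))
    }
    hits <- cache[[key]][[1]]
    if (is.null(hits)) return(NULL)
    cbind(data.frame(tf_id = tf, stringsAsFactors = FALSE), hits)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_id = character(), target_gene_id = character(),
                      source = character(), offset = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Filter candidate regulatory edges by promoter cis-binding evidence
#'
#' Edges whose source node is a transcription factor are retained only
#' when the (TF, target) pair appears in the evidence table; retained TF
#' edges are flagged `evidence_filtered = TRUE`. Edges whose source is
#' not a TF pass through unchanged (the filter applies only to TF-binding
#' claims). Idempotent.
#'
#' @param edges Data frame with at least `source` and `target` columns.
#' @param evidence Data frame with `tf_id` and `target_gene_id` columns
#'   (database export or [scan_evidence()] output).
#' @param tf_ids Character vector of gene ids with the TF role.
#' @return Subset of `edges` with an `evidence_filtered` logical column.
#' @export
filter_by_binding <- function(edges, evidence, tf_ids) {
  if (!nrow(edges)) {
    edges$evidence_filtered <- logical(0)
    return(edges)
  }
  key <- paste(evidence$tf_id, evidence$target_gene_id, sep = "\r")
  is_tf_edge <- edges$source %in% tf_ids
  supported <- paste(edges$source, edges$target, sep = "\r") %in% key
  keep <- !is_tf_edge | supported
  out <- edges[keep, , drop = FALSE]
  out$evidence_filtered <- is_tf_edge[keep] & supported[keep]
  rownames(out) <- NULL
  out
}

#' Read a TF binding-evidence TSV (tf_id, target_gene_id[, offset, score])
#' @param path TSV path with a header line.
#' @return Data frame with a `source` column set to "database" if absent.
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"source" %in% names(df)) df$source <- "database"
  df
}
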