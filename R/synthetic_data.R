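#' Generate a synthetic proteome with planted prion-like domains
#'
#' Background residues are drawn i.i.d. from a background composition; a
#' chosen fraction of proteins additionally receives an 80-residue
#' segment drawn from the prion-domain foreground composition, planted at
#' a random interior offset. The companion truth table records the
#' planted intervals for recovery testing. Byte-identical for identical
#' `(arguments, seed)`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of protein lengths; default
#'   `c(150, 600)`. Lower bound must be >= `planted_length` when
#'   planting.
#' @param planted_fraction Fraction of proteins that get a planted
#'   domain; default 0.1.
#' @param seed Integer seed.
#' @param planted_length Planted segment length; default 80 (comfortably
#'   above the 60-residue core window).
#' @param foreground,background Composition tables (see
#'   [aa_composition()]).
#' @return List with `proteome` (named character vector, ids `P00001`..)
#'   and `truth` (data.frame `protein_id`, `planted`, `seg_start`,
#'   `seg_end`, 1-based inclusive).
#' @export
gen_proteome <- function(n_proteins, length_range = c(150, 600),
                         planted_fraction = 0.1, seed = 1,
                         planted_length = 80,
                         foreground = aa_composition("prion_foreground"),
                         background = aa_composition("species_background")) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1)
  if (planted_fraction > 0 && length_range[1] < planted_length) {
    stop("length_range lower bound must be >= planted_length (",
         planted_length, ") when planting is requested")
  }
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n_proteins))
  lens <- if (n_proteins) {
    sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  } else integer(0)
  n_planted <- round(n_proteins * planted_fraction)
  planted_idx <- if (n_planted) sort(sample(n_proteins, n_planted)) else
    integer(0)
  seqs <- character(n_proteins)
  seg_start <- rep(NA_integer_, n_proteins)
  seg_end <- rep(NA_integer_, n_proteins)
  for (i in seq_len(n_proteins)) {
    s <- sample(CANONICAL_AA, lens[i], replace = TRUE, prob = background)
    if (i %in% planted_idx) {
      # interior offset: planted segment never touches either terminus
      lo <- 2L
      hi <- lens[i] - planted_length
      st <- if (hi <= lo) lo else sample(lo:hi, 1)
      seg <- sample(CANONICAL_AA, planted_length, replace = TRUE,
                    prob = foreground)
      s[st:(st + planted_length - 1)] <- seg
      seg_start[i] <- st
      seg_end[i] <- st + planted_length - 1L
    }
    seqs[i] <- paste(s, collapse = "")
  }
  list(
    proteome = stats::setNames(seqs, ids),
    truth = data.frame(protein_id = ids,
                       planted = seq_len(n_proteins) %in% planted_idx,
                       seg_start = seg_start, seg_end = seg_end,
                       stringsAsFactors = FALSE)
  )
}

#' Write a named character vector of sequences to FASTA
#' @param seqs Named character vector (amino-acid or nucleotide).
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Expected intra-module correlation of the diurnal generator
#'
#' Module genes are phase-locked sinusoids plus Gaussian noise; two genes
#' of the same module then correlate at
#' `r = (A^2/2) / (A^2/2 + sd^2)` in expectation (the sinusoid variance
#' over a full evenly-sampled period is `A^2/2`).
#'
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @return Expected Pearson correlation.
#' @export
expected_intra_r <- function(amplitude, noise_sd) {
  v <- amplitude^2 / 2
  v / (v + noise_sd^2)
}

#' Noise level that yields a target intra-module correlation
#' @param target_r Desired intra-module correlation in (0, 1].
#' @param amplitude Sinusoid amplitude; default 1.
#' @return Gaussian noise standard deviation.
#' @export
noise_sd_for_r <- function(target_r, amplitude = 1) {
  stopifnot(target_r > 0, target_r <= 1)
  sqrt((amplitude^2 / 2) * (1 / target_r - 1))
}

#' Generate a diurnal expression matrix with planted co-expression modules
#'
#' Samples are evenly spaced over one day-night cycle (48 samples = one
#' 24 h period at 30 min resolution). Each module's genes share a
#' phase-shifted sinusoid (`baseline + amplitude * sin(2*pi*t/period +
#' phase)`) plus i.i.d. Gaussian noise, giving intra-module correlation
#' [expected_intra_r()] and cross-module correlation attenuated by the
#' cosine of the phase difference. Remaining genes are independent
#' Gaussian noise. Values are truncated at zero to stay TPM-like.
#'
#' @param n_genes Total genes (module genes + noise genes).
#' @param n_samples Number of time points; default 48.
#' @param module_spec Data frame with columns `size`, `phase` (radians)
#'   and optionally `amplitude` (default 1).
#' @param noise_sd Gaussian noise sd added to module genes; default
#'   `noise_sd_for_r(0.95)`.
#' @param seed Integer seed.
#' @param baseline Additive offset keeping values positive; default 10.
#' @param period Period in hours; default 24 over a 24 h sampling span.
#' @return List with `matrix` (genes x samples, rownames `G0001`..,
#'   colnames `T01`..) and `truth` (data.frame `gene_id`, `module`
#'   (0 = noise gene), `phase`, `amplitude`).
#' @export
gen_diurnal_matrix <- function(n_genes, n_samples = 48, module_spec,
                               noise_sd = noise_sd_for_r(0.95), seed = 1,
                               baseline = 10, period = 24) {
  if (!all(c("size", "phase") %in% names(module_spec))) {
    stop("module_spec needs `size` and `phase` columns")
  }
  if (is.null(module_spec$amplitude)) module_spec$amplitude <- 1
  if (any(module_spec$size < 1) || any(!is.finite(module_spec$phase)) ||
      any(module_spec$amplitude <= 0)) {
    stop("unattainable module specification (sizes >= 1, finite phases, ",
         "positive amplitudes required)")
  }
  n_module <- sum(module_spec$size)
  if (n_module > n_genes) stop("module sizes exceed n_genes")
  set.seed(seed)
  t_hours <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  mat <- matrix(0, n_genes, n_samples,
                dimnames = list(gene_ids,
                                sprintf("T%02d", seq_len(n_samples))))
  module_of <- integer(n_genes)
  phase_of <- rep(NA_real_, n_genes)
  amp_of <- rep(NA_real_, n_genes)
  row <- 1L
  for (m in seq_len(nrow(module_spec))) {
    ph <- module_spec$phase[m]
    A <- module_spec$amplitude[m]
    signal <- baseline + A * sin(2 * pi * t_hours / period + ph)
    for (i in seq_len(module_spec$size[m])) {
      mat[row, ] <- signal + stats::rnorm(n_samples, sd = noise_sd)
      module_of[row] <- m
      phase_of[row] <- ph
      amp_of[row] <- A
      row <- row + 1L
    }
  }
  while (row <= n_genes) {
    mat[row, ] <- baseline + stats::rnorm(n_samples, sd = 1)
    row <- row + 1L
  }
  mat <- pmax(mat, 0)
  list(
    matrix = mat,
    truth = data.frame(gene_id = gene_ids, module = module_of,
                       phase = phase_of, amplitude = amp_of,
                       stringsAsFactors = FALSE)
  )
}

.NUCS <- c("A", "C", "G", "T")

.revcomp_chr <- function(s) {
  paste(rev(unname(.REVCOMP[strsplit(toupper(s), "")[[1]]])),
        collapse = "")
}

#' Generate a genome with annotated genes and planted promoter motifs
#'
#' Genes are laid out on one chromosome, alternating strands, with at
#' least 2 kb between neighbouring gene starts; each planted target gene
#' receives the motif consensus at a random offset inside its promoter
#' window (`upstream` bp before to `downstream` bp after the TSS). The
#' truth table records the promoter-oriented offset of each plant.
#'
#' @param n_genes Number of genes.
#' @param motif Consensus string over ACGT, or a 4 x L count matrix.
#' @param planted_target_ids Gene ids (`GENE0001`..) to plant the motif
#'   in; or a number, interpreted as "plant in the first k genes".
#' @param seed Integer seed.
#' @param upstream,downstream Promoter extent; defaults 1500 / 200.
#' @param spacing Distance between consecutive gene starts (>= 2000 +
#'   gene length); default 4000.
#' @param gene_length Annotated gene length; default 1000.
#' @param genome_length Optional total chromosome length; errors if too
#'   short for the requested layout.
#' @param gene_ids Optional custom gene ids (length `n_genes`); default
#'   `GENE0001`..
#' @return List with `genome` (named character, one chromosome `chr1`),
#'   `gff` (data.frame of gene/mRNA features, 1-based inclusive), and
#'   `truth` (data.frame `gene_id`, `planted`, `offset`).
#' @export
gen_genome_with_promoters <- function(n_genes, motif,
                                      planted_target_ids = character(0),
                                      seed = 1, upstream = 1500,
                                      downstream = 200, spacing = 4000,
                                      gene_length = 1000,
                                      genome_length = NULL,
                                      gene_ids = NULL) {
  consensus <- if (is.matrix(motif)) pwm_consensus(motif) else
    toupper(motif)
  L <- nchar(consensus)
  if (L > upstream + downstream) stop("motif longer than promoter window")
  if (spacing < 2000 + gene_length) stop("spacing too small for 2 kb gaps")
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  if (is.numeric(planted_target_ids)) {
    planted_target_ids <- gene_ids[seq_len(planted_target_ids)]
  }
  if (!all(planted_target_ids %in% gene_ids)) {
    stop("unknown planted target gene id(s)")
  }
  margin <- upstream + downstream + 100
  needed <- margin + n_genes * spacing + margin
  if (is.null(genome_length)) genome_length <- needed
  if (genome_length < needed) {
    stop("genome_length ", genome_length, " too short; need >= ", needed)
  }
  set.seed(seed)
  chrom <- sample(.NUCS, genome_length, replace = TRUE)
  # 1-based inclusive gene coordinates, alternating strands
  starts <- margin + (seq_len(n_genes) - 1L) * spacing + 1L
  strands <- rep(c("+", "-"), length.out = n_genes)
  offsets <- rep(NA_integer_, n_genes)
  for (i in seq_len(n_genes)) {
    if (!gene_ids[i] %in% planted_target_ids) next
    off <- sample(0:(upstream + downstream - L), 1)  # promoter-oriented
    if (strands[i] == "+") {
      tss1 <- starts[i]
      p0 <- (tss1 - 1L) - upstream          # 0-based promoter start
      g <- p0 + off                          # 0-based plant position
      chrom[(g + 1):(g + L)] <- strsplit(consensus, "")[[1]]
    } else {
      tss1 <- starts[i] + gene_length - 1L
      e0 <- (tss1 - 1L) + upstream + 1L      # 0-based half-open end
      g <- e0 - off - L                      # 0-based plant position
      chrom[(g + 1):(g + L)] <- strsplit(.revcomp_chr(consensus), "")[[1]]
    }
    offsets[i] <- off
  }
  mk_feature <- function(type, id, parent, i) {
    data.frame(seqid = "chr1", source = "prionet", type = type,
               start = starts[i], end = starts[i] + gene_length - 1L,
               score = ".", strand = strands[i], phase = ".",
               attributes = if (is.na(parent)) paste0("ID=", id) else
                 paste0("ID=", id, ";Parent=", parent),
               stringsAsFactors = FALSE)
  }
  gff <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    rbind(mk_feature("gene", gene_ids[i], NA, i),
          mk_feature("mRNA", paste0(gene_ids[i], ".1"), gene_ids[i], i))
  }))
  list(
    genome = stats::setNames(paste(chrom, collapse = ""), "chr1"),
    gff = gff,
    truth = data.frame(gene_id = gene_ids,
                       planted = gene_ids %in% planted_target_ids,
                       offset = offsets, strand = strands,
                       stringsAsFactors = FALSE)
  )
}

#' Write a GFF3 feature data frame to disk
#' @param gff Data frame from [gen_genome_with_promoters()].
#' @param path Output path.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate role tables (TF, Ts/RTR, stress, memory) over a gene universe
#'
#' Each role draws its members independently from `gene_ids` (roles may
#' overlap). A role size below 1 is a fraction of the pool; 1 or more is
#' an exact member count.
#'
#' @param gene_ids Character vector of gene ids.
#' @param fractions Named numeric vector, e.g.
#'   `c(TF = 12, "Ts/RTR" = 0.1, stress = 0.2, memory = 0.1)`.
#' @param seed Integer seed.
#' @return Named list of character vectors, one per role.
#' @export
gen_role_tables <- function(gene_ids,
                            fractions = c(TF = 0.1, "Ts/RTR" = 0.1,
                                          stress = 0.15, memory = 0.1),
                            seed = 1) {
  set.seed(seed)
  out <- lapply(fractions, function(f) {
    k <- if (f < 1) round(f * length(gene_ids)) else as.integer(f)
    if (k > length(gene_ids)) stop("role size exceeds gene pool")
    if (k == 0) character(0) else sort(sample(gene_ids, k))
  })
  stats::setNames(out, names(fractions))
}

#' Write role tables as one TSV per role
#' @param roles Named list from [gen_role_tables()].
#' @param dir Output directory.
#' @return Named vector of file paths.
#' @export
write_role_tsvs <- function(roles, dir) {
  paths <- vapply(names(roles), function(role) {
    fn <- file.path(dir, paste0("role_", gsub("[^A-Za-z0-9]", "_", role),
                                ".tsv"))
    utils::write.table(data.frame(gene_id = roles[[role]]), fn,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fn
  }, character(1))
  paths
}

#' Check that a truth table is consistent with its generated files
#'
#' Verifies that every planted feature references an entity that exists:
#' planted PrLD intervals lie inside their protein, planted motif offsets
#' lie inside the promoter window, module labels reference matrix rows.
#'
#' @param bundle A list with any of `proteome`+`truth` (from
#'   [gen_proteome()]), `matrix`+`truth` (from [gen_diurnal_matrix()]),
#'   `genome`+`gff`+`truth` (from [gen_genome_with_promoters()]).
#' @return `TRUE` invisibly; errors on inconsistency.
#' @export
check_truth <- function(bundle) {
  tr <- bundle$truth
  if (!is.null(bundle$proteome)) {
    stopifnot(all(tr$protein_id %in% names(bundle$proteome)))
    p <- tr[tr$planted, , drop = FALSE]
    lens <- nchar(bundle$proteome[p$protein_id])
    stopifnot(all(p$seg_start >= 1), all(p$seg_end <= lens))
  }
  if (!is.null(bundle$matrix)) {
    stopifnot(all(tr$gene_id %in% rownames(bundle$matrix)))
  }
  if (!is.null(bundle$gff)) {
    ids <- sub("^ID=([^;]+).*$", "\\1",
               bundle$gff$attributes[bundle$gff$type == "gene"])
    stopifnot(all(tr$gene_id %in% ids))
    stopifnot(all(is.na(tr$offset) | tr$offset >= 0))
  }
  invisible(TRUE)
}
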