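#' Default pipeline configuration
#'
#' All thresholds default to the study values: core window 60, alpha 50,
#' COREscore 25, correlation cutoff 0.8 with p < 0.01, promoters 1,500 bp
#' upstream + 200 bp downstream, homolog cutoffs e-value 1e-5 / coverage
#' 50% / identity 35%, MCODE vertex-weight percentage 0.2 with haircut on
#' and degree cutoff 2, hub fraction 0.05.
#'
#' @param input_dir Directory holding the pipeline inputs (as written by
#'   [simulate_bundle()]).
#' @param out_dir Directory for stage outputs.
#' @param seed Integer seed (used by simulation; analysis stages are
#'   deterministic).
#' @return Named list of paths and thresholds.
#' @export
default_config <- function(input_dir, out_dir, seed = 1) {
  list(
    seed = seed,
    input_dir = input_dir,
    out_dir = out_dir,
    proteome = file.path(input_dir, "proteome.faa"),
    annotation = file.path(input_dir, "annotation.tsv"),
    expression = file.path(input_dir, "expression.tsv"),
    genome = file.path(input_dir, "genome.fa"),
    gff3 = file.path(input_dir, "genes.gff3"),
    pwm = file.path(input_dir, "motif.pwm"),
    roles_dir = input_dir,
    lcore = 60, alpha = 50, corescore = 25,
    r_cut = 0.8, p_cut = 0.01,
    upstream = 1500, downstream = 200,
    evalue = 1e-5, coverage = 50, identity = 35,
    pwm_threshold = NA_real_,   # NA: 90% of the consensus score
    vwp = 0.2, haircut = TRUE, degree_cutoff = 2,
    hub_fraction = 0.05
  )
}

#' Validate a pipeline configuration
#'
#' Checks numeric ranges and input-file existence. Returns a character
#' vector of problems (empty when the configuration is valid); never
#' throws on bad values.
#'
#' @param config Configuration list (see [default_config()]).
#' @param check_files Also check that input files exist; default TRUE.
#' @return Character vector of error messages (length 0 = ok).
#' @export
validate_config <- function(config, check_files = TRUE) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  num <- function(x) is.numeric(config[[x]]) && length(config[[x]]) == 1 &&
    !is.na(config[[x]])
  chk(num("alpha") && config$alpha >= 0 && config$alpha <= 100,
      "alpha must be in [0, 100]")
  chk(num("lcore") && config$lcore >= 1, "lcore must be >= 1")
  chk(num("corescore"), "corescore must be numeric")
  chk(num("r_cut") && config$r_cut >= 0 && config$r_cut <= 1,
      "r_cut must be in [0, 1]")
  chk(num("p_cut") && config$p_cut > 0 && config$p_cut <= 1,
      "p_cut must be in (0, 1]")
  chk(num("upstream") && config$upstream >= 0, "upstream must be >= 0")
  chk(num("downstream") && config$downstream >= 0,
      "downstream must be >= 0")
  chk(num("vwp") && config$vwp >= 0 && config$vwp < 1,
      "vwp must be in [0, 1)")
  chk(num("hub_fraction") && config$hub_fraction > 0 &&
        config$hub_fraction <= 1, "hub_fraction must be in (0, 1]")
  if (check_files) {
    for (f in c("proteome", "annotation", "expression", "genome",
                "gff3", "pwm")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        errs <- c(errs, paste0("missing input file: ", f, " (",
                               config[[f]], ")"))
      }
    }
  }
  errs
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' @rdname read_pipeline_config
#' @param config Configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Simulate a complete input bundle for the pipeline
#'
#' Emits every file the pipeline consumes, mutually consistent:
#' a proteome with planted prion-like domains (isoform `.1` of each
#' gene), a protein -> gene annotation table whose descriptions reflect
#' the role assignments, a 48-sample diurnal expression matrix with two
#' antagonistic planted modules, a genome + GFF3 with the motif planted
#' in the promoters of the module-gene targets, a count PWM, role tables,
#' and the ground-truth tables. Deterministic in `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_proteins Proteome size; default 500.
#' @param planted_fraction Fraction of proteins with a planted domain;
#'   default 0.1.
#' @param n_genes Expression genes; default 66.
#' @param module_sizes Sizes of the two antagonistic modules; default
#'   `c(15, 15)`.
#' @param intra_r,cross_r Target intra-module and cross-module
#'   correlations; defaults 0.95 and -0.9.
#' @param n_tf,n_ts_rtr TF and Ts/RTR role counts among expression
#'   genes; defaults 12 and 5.
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
simulate_bundle <- function(dir, seed = 1, n_proteins = 500,
                            planted_fraction = 0.1, n_genes = 66,
                            module_sizes = c(15, 15), intra_r = 0.95,
                            cross_r = -0.9, n_tf = 12, n_ts_rtr = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # phase offset delivering the cross-module correlation target
  dphi <- acos(max(-1, min(1, cross_r / intra_r)))
  modules <- data.frame(size = module_sizes,
                        phase = c(0, dphi)[seq_along(module_sizes)])
  expr <- gen_diurnal_matrix(n_genes, 48, modules,
                             noise_sd = noise_sd_for_r(intra_r),
                             seed = seed)
  gene_ids <- rownames(expr$matrix)

  roles <- gen_role_tables(
    gene_ids,
    fractions = c(TF = n_tf, "Ts/RTR" = n_ts_rtr, stress = 0.15,
                  memory = 0.1),
    seed = seed + 1
  )

  prot <- gen_proteome(n_proteins, planted_fraction = planted_fraction,
                       seed = seed + 2)
  # proteins map onto genes: the first n_genes proteins are isoforms of
  # the expression genes, the rest extend the gene universe
  prot_gene <- c(gene_ids,
                 sprintf("GX%04d", seq_len(max(0, n_proteins - n_genes))))
  prot_gene <- prot_gene[seq_len(n_proteins)]
  desc <- ifelse(prot_gene %in% roles[["Ts/RTR"]],
                 "retrotransposon protein, putative",
            ifelse(prot_gene %in% roles$TF, "transcription factor",
            ifelse(prot$truth$planted, "RNA-binding protein",
                   "hypothetical protein")))
  annotation <- data.frame(protein_id = names(prot$proteome),
                           gene_id = prot_gene, description = desc,
                           stringsAsFactors = FALSE)

  motif <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- strsplit("TGACGTCA", "")[[1]]
  for (j in seq_along(consensus)) {
    motif[, j] <- 1
    motif[consensus[j], j] <- 21
  }
  # motif planted in the promoters of the module genes (the TF targets)
  n_module <- sum(module_sizes)
  planted_targets <- gene_ids[seq_len(n_module)]
  gen <- gen_genome_with_promoters(n_genes, motif,
                                   planted_target_ids = planted_targets,
                                   seed = seed + 3,
                                   gene_ids = gene_ids)

  paths <- list(
    proteome = file.path(dir, "proteome.faa"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    pwm = file.path(dir, "motif.pwm")
  )
  write_fasta(prot$proteome, paths$proteome, "AA")
  utils::write.table(annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_tsv(expr$matrix, paths$expression)
  write_fasta(gen$genome, paths$genome, "DNA")
  write_gff3(gen$gff, paths$gff3)
  writeLines(c(">motif", apply(motif, 1, paste, collapse = " ")),
             paths$pwm)
  write_role_tsvs(roles, dir)
  utils::write.table(prot$truth, file.path(dir, "truth_proteome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth, file.path(dir, "truth_modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth, file.path(dir, "truth_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(proteome = prot, expression = expr, genome = gen,
                 roles = roles, annotation = annotation, paths = paths))
}

.read_role <- function(dir, role) {
  fn <- file.path(dir, paste0("role_", gsub("[^A-Za-z0-9]", "_", role),
                              ".tsv"))
  if (!file.exists(fn)) return(character(0))
  df <- utils::read.table(fn, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df)) df$gene_id else character(0)
}

#' Run the full prionome pipeline
#'
#' Stages: scan the proteome for prion-like domains; summarize the
#' prionome at gene level; call signed co-expression edges from the
#' diurnal matrix; extract promoters; scan them for TF binding evidence;
#' assemble the three-layer network; filter TF edges by binding
#' evidence; cluster with MCODE; export SIF, node attributes, clusters
#' and a JSON manifest of per-stage counts. Deterministic: identical
#' config and inputs give byte-identical outputs.
#'
#' @param config Configuration list (see [default_config()]).
#' @return The manifest (list), invisibly; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  manifest <- list(seed = config$seed, stages = list())

  # -- scan ------------------------------------------------------------
  proteome <- read_proteome(config$proteome)
  tab <- build_llr_table(alpha = config$alpha)
  hits <- call_prlds(proteome, tab, l_core = config$lcore,
                     threshold = config$corescore)
  write_hits_tsv(hits, file.path(out, "hits.tsv"))
  log_stage("scan", nrow(hits), " PrLD hits in ", length(proteome),
            " proteins")
  manifest$stages$scan <- list(n_proteins = length(proteome),
                               n_hits = nrow(hits))

  # -- summarize -------------------------------------------------------
  annotation <- utils::read.table(config$annotation, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
  ent <- merge(hits, annotation, by = "protein_id")
  ent$category <- vapply(ent$description, categorize, character(1),
                         USE.NAMES = FALSE)
  genes_ent <- collapse_to_genes(ent)
  # empty proteomes report density over a nominal size of 1
  summ <- summarize_prionome(genes_ent[, "category", drop = FALSE],
                             proteome_size = max(1L, length(proteome)))
  write_summary_tsv(summ, file.path(out, "prionome_summary.tsv"))
  prlp_genes <- sort(unique(genes_ent$gene_id))
  log_stage("summarize", summ$n_prlps, " PrLP genes; density ",
            sprintf("%.4f", summ$density))
  manifest$stages$summarize <- list(n_prlp_genes = summ$n_prlps,
                                    density = summ$density)

  # -- coexpress -------------------------------------------------------
  mat <- read_expression_tsv(config$expression)
  mat_norm <- minmax_normalize_matrix(mat)
  edges <- pairwise_correlations(mat_norm)
  bsm <- threshold_edges(edges, r_cut = config$r_cut,
                         p_cut = config$p_cut)
  write_coexpression_tsv(edges, bsm,
                         edges_path = file.path(out, "coexpression_edges.tsv"),
                         matrix_path = file.path(out, "coexpression_matrix.tsv"))
  n_called <- sum(bsm$entries != 0) / 2
  log_stage("coexpress", n_called, " called edges among ",
            length(bsm$genes), " genes")
  manifest$stages$coexpress <- list(n_genes = length(bsm$genes),
                                    n_called_edges = n_called)

  # -- promoters -------------------------------------------------------
  promoters <- extract_promoters(config$gff3, config$genome,
                                 upstream = config$upstream,
                                 downstream = config$downstream)
  write_promoters_fasta(promoters, file.path(out, "promoters.fa"))
  log_stage("promoters", nrow(promoters), " promoters extracted")
  manifest$stages$promoters <- list(n_promoters = nrow(promoters))

  # -- binding evidence ------------------------------------------------
  roles <- list(
    PrLP = prlp_genes,
    TF = .read_role(config$roles_dir, "TF"),
    "Ts/RTR" = .read_role(config$roles_dir, "Ts/RTR"),
    stress = .read_role(config$roles_dir, "stress"),
    memory = .read_role(config$roles_dir, "memory")
  )
  counts <- read_pwm(config$pwm)
  lo <- pwm_log_odds(counts)
  thr <- config$pwm_threshold
  if (is.na(thr)) {
    thr <- 0.9 * sum(apply(lo, 2, max))  # 90% of the consensus score
  }
  tf_pwms <- stats::setNames(rep(list(lo), length(roles$TF)), roles$TF)
  evidence <- scan_evidence(promoters, tf_pwms, thr)
  utils::write.table(evidence, file.path(out, "binding_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("evidence", nrow(evidence), " TF-target binding pairs")
  manifest$stages$evidence <- list(n_pairs = nrow(evidence))

  # -- assemble --------------------------------------------------------
  nz <- which(bsm$entries != 0 & upper.tri(bsm$entries), arr.ind = TRUE)
  called <- data.frame(
    gene_a = bsm$genes[nz[, 1]], gene_b = bsm$genes[nz[, 2]],
    sign = bsm$entries[nz], stringsAsFactors = FALSE
  )
  is_tf_b <- called$gene_b %in% roles$TF & !(called$gene_a %in% roles$TF)
  called$source <- ifelse(is_tf_b, called$gene_b, called$gene_a)
  called$target <- ifelse(is_tf_b, called$gene_a, called$gene_b)
  both_prlp <- called$gene_a %in% roles$PrLP &
    called$gene_b %in% roles$PrLP
  touches_tf <- called$gene_a %in% roles$TF | called$gene_b %in% roles$TF
  touches_sm <- called$gene_a %in% c(roles$stress, roles$memory) |
    called$gene_b %in% c(roles$stress, roles$memory)
  l1 <- called[both_prlp, , drop = FALSE]
  l2 <- called[!both_prlp & touches_tf, , drop = FALSE]
  l3 <- called[!both_prlp & !touches_tf & touches_sm, , drop = FALSE]
  net <- suppressWarnings(assemble_layers(l1, l2, l3, roles))
  fedges <- filter_by_binding(net$edges, evidence, roles$TF)
  net <- grn_network(fedges, roles)
  export_sif(net, file.path(out, "network.sif"))
  write_node_attributes_tsv(net, file.path(out, "node_attributes.tsv"))
  log_stage("assemble", nrow(net$edges), " edges / ", nrow(net$nodes),
            " nodes after binding filter")
  manifest$stages$assemble <- list(
    n_layer1 = nrow(l1), n_layer2 = nrow(l2), n_layer3 = nrow(l3),
    n_edges = nrow(net$edges), n_nodes = nrow(net$nodes))

  # -- mcode + hubs ----------------------------------------------------
  clusters <- if (nrow(net$edges)) {
    predict_complexes(net, vwp = config$vwp, haircut = config$haircut,
                      degree_cutoff = config$degree_cutoff)
  } else list()
  write_clusters_tsv(clusters, file.path(out, "mcode_clusters.tsv"))
  hubs <- if (nrow(net$edges)) find_hubs(net, config$hub_fraction) else
    character(0)
  writeLines(hubs, file.path(out, "hubs.txt"))
  log_stage("mcode", length(clusters), " clusters; ", length(hubs),
            " hub nodes")
  manifest$stages$mcode <- list(n_clusters = length(clusters),
                                n_hubs = length(hubs))

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
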