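make_toy_genome <- function(seed = 101, n_genes = 6, motif = "TGACGTCATGAC") {
  gen_genome_with_promoters(n_genes, motif,
                            planted_target_ids = character(0),
                            seed = seed)
}

test_that("promoter geometry: interior promoters are upstream+downstream", {
  gen <- make_toy_genome()
  td <- withr::local_tempdir()
  write_fasta(gen$genome, file.path(td, "g.fa"), "DNA")
  write_gff3(gen$gff, file.path(td, "g.gff3"))
  pr <- extract_promoters(file.path(td, "g.gff3"), file.path(td, "g.fa"))
  expect_equal(nrow(pr), 6)
  expect_true(all(!pr$truncated))
  expect_true(all(pr$end - pr$start == 1700))
  expect_true(all(nchar(pr$sequence) == 1700))

  # plus-strand arithmetic: TSS at 1-based position t covers t-1500..t+199
  plus <- pr[pr$strand == "+", ][1, ]
  tss1 <- gen$gff$start[gen$gff$type == "gene" &
                          grepl(plus$gene_id, gen$gff$attributes)][1]
  expect_equal(plus$start, tss1 - 1 - 1500)
  expect_equal(plus$end, tss1 - 1 + 200)
})

test_that("minus-strand promoters equal a naive reverse-complement oracle", {
  gen <- make_toy_genome(seed = 7)
  td <- withr::local_tempdir()
  write_gff3(gen$gff, file.path(td, "g.gff3"))
  pr <- extract_promoters(file.path(td, "g.gff3"),
                          Biostrings::DNAStringSet(gen$genome))
  minus <- pr[pr$strand == "-", ]
  chrom <- gen$genome[["chr1"]]
  for (i in seq_len(nrow(minus))) {
    slice <- substr(chrom, minus$start[i] + 1, minus$end[i])
    expect_equal(minus$sequence[i], naive_revcomp(slice))
  }
})

test_that("promoters truncate at contig edges and round-trip FASTA", {
  gen <- make_toy_genome(seed = 9)
  # move the first gene to 100 bp (1-based TSS 101) from the contig start
  gff <- gen$gff
  g1 <- grepl("GENE0001", gff$attributes)
  gff$end[g1] <- gff$end[g1] - gff$start[g1] + 101
  gff$start[g1] <- 101
  td <- withr::local_tempdir()
  write_fasta(gen$genome, file.path(td, "g.fa"), "DNA")
  write_gff3(gff, file.path(td, "g.gff3"))
  pr <- extract_promoters(file.path(td, "g.gff3"), file.path(td, "g.fa"))
  first <- pr[pr$gene_id == "GENE0001", ]
  expect_true(first$truncated)
  expect_equal(nchar(first$sequence), 100 + 200)

  write_promoters_fasta(pr, file.path(td, "prom.fa"))
  back <- Biostrings::readDNAStringSet(file.path(td, "prom.fa"))
  expect_equal(as.character(back), stats::setNames(pr$sequence,
                                                   pr$gene_id))

  expect_error(extract_promoters(file.path(td, "g.gff3"),
                                 Biostrings::DNAStringSet(c(other = "ACGT"))),
               "chromosome absent")
})

test_that("PWM scanning finds planted sites on both strands", {
  counts <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- strsplit("TGACGTCA", "")[[1]]
  for (j in 1:8) counts[consensus[j], j] <- 21
  lo <- pwm_log_odds(counts)
  thr <- sum(apply(lo, 2, max))  # consensus-level threshold

  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  plant <- function(s, site, at) {
    paste0(substr(s, 1, at), site, substr(s, at + nchar(site) + 1,
                                          nchar(s)))
  }
  fwd <- plant(bg, "TGACGTCA", 400)
  hits <- scan_binding_sites(fwd, lo, thr)
  expect_true(any(hits$offset == 400 & hits$strand == "+"))

  rev <- plant(bg, naive_revcomp("TGACGTCA"), 250)
  hits_rev <- scan_binding_sites(rev, lo, thr)
  expect_true(any(hits_rev$strand == "-" & hits_rev$offset == 250))

  # windows spanning N are skipped
  withN <- plant(bg, "TGACNTCA", 500)
  hitsN <- scan_binding_sites(withN, lo, thr)
  expect_false(any(hitsN$offset == 500 & hitsN$strand == "+"))

  # hit count matches a naive full-enumeration scan at a loose threshold
  loose <- 0.5 * thr
  naive_count <- function(s) {
    n <- 0
    for (str in c(s, naive_revcomp(s))) {
      cv <- strsplit(str, "")[[1]]
      for (i in seq_len(nchar(str) - 7)) {
        win <- cv[i:(i + 7)]
        if (any(!win %in% c("A", "C", "G", "T"))) next
        sc <- sum(vapply(1:8, function(j) lo[win[j], j], numeric(1)))
        if (sc >= loose) n <- n + 1
      }
    }
    n
  }
  shuffled <- paste(sample(strsplit(bg, "")[[1]]), collapse = "")
  expect_equal(nrow(scan_binding_sites(shuffled, lo, loose)),
               naive_count(shuffled))
})

test_that("binding filter keeps supported TF edges and non-TF edges", {
  edges <- data.frame(
    source = c("TF1", "TF1", "gA"),
    target = c("g1", "g2", "gB"),
    sign = c(1, -1, 1), layer = c(2, 2, 1),
    stringsAsFactors = FALSE
  )
  ev <- data.frame(tf_id = "TF1", target_gene_id = "g1",
                   stringsAsFactors = FALSE)
  out <- filter_by_binding(edges, ev, tf_ids = "TF1")
  expect_equal(nrow(out), 2)
  expect_true(out$evidence_filtered[out$source == "TF1"])   # kept + flagged
  expect_false("g2" %in% out$target)                        # dropped
  expect_false(out$evidence_filtered[out$source == "gA"])   # pass-through

  # idempotent and a subset of the input
  again <- filter_by_binding(out, ev, tf_ids = "TF1")
  expect_equal(again[, names(out)], out)
  expect_true(all(paste(out$source, out$target) %in%
                    paste(edges$source, edges$target)))
})
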