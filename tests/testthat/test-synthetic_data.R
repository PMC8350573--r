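test_that("proteome generation is seed-deterministic with valid truth", {
  td <- withr::local_tempdir()
  p1 <- gen_proteome(50, seed = 7)
  p2 <- gen_proteome(50, seed = 7)
  f1 <- file.path(td, "a.faa"); f2 <- file.path(td, "b.faa")
  write_fasta(p1$proteome, f1, "AA")
  write_fasta(p2$proteome, f2, "AA")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(p1$proteome,
                         gen_proteome(50, seed = 8)$proteome))

  none <- gen_proteome(30, planted_fraction = 0, seed = 1)
  expect_equal(sum(none$truth$planted), 0)

  some <- gen_proteome(40, planted_fraction = 0.25, seed = 2)
  expect_equal(sum(some$truth$planted), 10)
  expect_true(check_truth(some))
  pl <- some$truth[some$truth$planted, ]
  expect_true(all(pl$seg_end - pl$seg_start + 1 == 80))

  expect_error(gen_proteome(10, length_range = c(60, 100),
                            planted_fraction = 0.5), "planted_length")
})

test_that("diurnal modules realize their correlation targets", {
  spec2 <- data.frame(size = c(5, 5), phase = c(0, pi))
  noiseless <- gen_diurnal_matrix(12, 48, spec2, noise_sd = 0, seed = 3)
  r <- stats::cor(t(noiseless$matrix[1:10, ]))
  expect_equal(unname(r[1:5, 1:5]), matrix(1, 5, 5))
  expect_equal(unname(r[1:5, 6:10]), matrix(-1, 5, 5), tolerance = 1e-12)

  # noisy modules land near the analytic intra-module target
  target <- expected_intra_r(1, 0.1)
  vals <- numeric(0)
  for (s in 1:10) {
    sim <- gen_diurnal_matrix(10, 48, data.frame(size = 10, phase = 0),
                              noise_sd = 0.1, seed = s)
    rr <- stats::cor(t(sim$matrix))
    vals <- c(vals, rr[upper.tri(rr)])
  }
  expect_lt(abs(mean(vals) - target), 0.1)

  expect_error(gen_diurnal_matrix(5, 48, data.frame(size = 10, phase = 0)),
               "exceed")
  expect_error(gen_diurnal_matrix(5, 48, data.frame(size = 2, phase = Inf)),
               "unattainable")
  expect_identical(gen_diurnal_matrix(12, 48, spec2, seed = 5)$matrix,
                   gen_diurnal_matrix(12, 48, spec2, seed = 5)$matrix)
  expect_true(all(gen_diurnal_matrix(12, 48, spec2, seed = 5)$matrix >= 0))
})

test_that("genomes plant motifs only where requested", {
  motif <- "TGACGTCATGAC"
  gen <- gen_genome_with_promoters(8, motif,
                                   planted_target_ids = 4, seed = 11)
  gen2 <- gen_genome_with_promoters(8, motif,
                                    planted_target_ids = 4, seed = 11)
  expect_identical(gen$gff, gen2$gff)
  expect_identical(gen$genome, gen2$genome)
  expect_true(check_truth(gen))

  td <- withr::local_tempdir()
  write_fasta(gen$genome, file.path(td, "g.fa"), "DNA")
  write_gff3(gen$gff, file.path(td, "g.gff3"))
  pr <- extract_promoters(file.path(td, "g.gff3"), file.path(td, "g.fa"))

  counts <- matrix(1, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:12) counts[substr(motif, j, j), j] <- 21
  lo <- pwm_log_odds(counts)
  thr <- sum(apply(lo, 2, max))
  detected <- vapply(pr$gene_id, function(g)
    nrow(scan_binding_sites(pr$sequence[pr$gene_id == g], lo, thr)) > 0,
    logical(1))
  planted <- gen$truth$planted[match(pr$gene_id, gen$truth$gene_id)]
  expect_true(all(detected[planted]))       # every plant detected
  expect_true(all(!detected[!planted]))     # 12-mer: no chance hits

  expect_error(gen_genome_with_promoters(8, motif, genome_length = 100),
               "too short")
  expect_error(gen_genome_with_promoters(2, strrep("A", 2000)),
               "longer than promoter")
})

test_that("role tables draw exact counts deterministically", {
  ids <- sprintf("G%04d", 1:66)
  roles <- gen_role_tables(ids, c(TF = 12, "Ts/RTR" = 5, stress = 0.15),
                           seed = 9)
  expect_equal(length(roles$TF), 12)
  expect_equal(length(roles[["Ts/RTR"]]), 5)
  expect_equal(length(roles$stress), round(0.15 * 66))
  expect_identical(roles, gen_role_tables(
    ids, c(TF = 12, "Ts/RTR" = 5, stress = 0.15), seed = 9))
  empty <- gen_role_tables(ids, c(TF = 0), seed = 1)
  expect_equal(length(empty$TF), 0)
  expect_error(gen_role_tables(ids[1:3], c(TF = 10), seed = 1), "pool")
})
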