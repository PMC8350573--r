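test_that("background blending hits its limits and the llr formula", {
  fg <- aa_composition("prion_foreground")
  sp <- aa_composition("species_background")
  df <- aa_composition("default_background")

  t100 <- build_llr_table(fg, sp, df, alpha = 100)
  expect_equal(t100$llr, log2(fg / sp))
  t0 <- build_llr_table(fg, sp, df, alpha = 0)
  expect_equal(t0$llr, log2(fg / df))

  # foreground N = 0.20 against blended background N = 0.05 -> 2 bits
  bg <- stats::setNames(rep((1 - 0.05) / 19, 20), CANONICAL_AA)
  bg[["N"]] <- 0.05
  fg2 <- stats::setNames(rep((1 - 0.20) / 19, 20), CANONICAL_AA)
  fg2[["N"]] <- 0.20
  tab <- build_llr_table(fg2, bg, bg, alpha = 50)
  expect_equal(tab$llr[["N"]], 2)

  expect_error(build_llr_table(alpha = 150), "alpha")
  expect_error(build_llr_table(alpha = -1), "alpha")
  bad <- fg; bad[["W"]] <- 0; bad <- bad / sum(bad)
  expect_error(build_llr_table(bad, species_bg = bad, default_bg = bad),
               "W")
  short <- fg[-1]
  expect_error(build_llr_table(short), "missing entries")
})

test_that("core_score finds the best fixed-length window", {
  tab <- flat_llr_table(0.5)
  seq60 <- strrep("A", 60)
  expect_equal(core_score(seq60, tab, 60),
               list(score = 30, core_start = 1L, core_end = 60L))
  expect_null(core_score(strrep("A", 59), tab, 60))

  # appending zero-llr residues does not change the score
  tab0 <- tab
  tab0$llr[["G"]] <- 0
  s <- paste0(strrep("A", 70), strrep("G", 30))
  expect_equal(core_score(s, tab0, 60)$score,
               core_score(strrep("A", 70), tab0, 60)$score)

  # ambiguity codes contribute zero
  expect_equal(core_score(paste0(strrep("A", 30), strrep("X", 30)),
                          tab, 60)$score, 15)
})

test_that("core_score equals the brute-force window oracle", {
  tab <- build_llr_table()
  set.seed(42)
  for (i in 1:60) {
    n <- sample(60:500, 1)
    s <- random_aa_seq(n)
    got <- core_score(s, tab, 60)
    exp <- oracle_core_score(s, tab, 60)
    expect_equal(got$score, exp$score, tolerance = 1e-12)
    expect_identical(got$core_start, exp$core_start)
  }
})

test_that("domain boundaries expand to the maximal-scoring segment", {
  tab <- flat_llr_table(0.5)   # everything positive
  s <- strrep("A", 100)
  cs <- core_score(s, tab, 60)
  expect_equal(domain_boundaries(s, tab, cs$core_start, cs$core_end),
               list(domain_start = 1, domain_end = 100))

  # strictly negative flanks stop the expansion at the core
  tab2 <- flat_llr_table(0.5)
  tab2$llr[["D"]] <- -1
  s2 <- paste0(strrep("D", 20), strrep("A", 60), strrep("D", 20))
  expect_equal(domain_boundaries(s2, tab2, 21, 80),
               list(domain_start = 21, domain_end = 80))

  # random sequences: equals the exhaustive segment oracle
  tab3 <- build_llr_table()
  set.seed(7)
  for (i in 1:20) {
    s3 <- random_aa_seq(sample(80:160, 1))
    cs3 <- core_score(s3, tab3, 60)
    got <- domain_boundaries(s3, tab3, cs3$core_start, cs3$core_end)
    exp <- oracle_domain(s3, tab3, cs3$core_start, cs3$core_end)
    seg_sum <- function(a, b) {
      v <- tab3$llr[strsplit(s3, "")[[1]]]; v[is.na(v)] <- 0
      sum(v[a:b])
    }
    expect_equal(seg_sum(got$domain_start, got$domain_end),
                 seg_sum(exp$domain_start, exp$domain_end),
                 tolerance = 1e-10)
  }
})

test_that("proteome-level calling filters, sorts and stays deterministic", {
  tab <- build_llr_table()
  expect_equal(nrow(call_prlds(character(0), tab)), 0)

  set.seed(11)
  prot <- gen_proteome(120, planted_fraction = 0.15, seed = 11)$proteome
  hits <- call_prlds(prot, tab)

  # oracle equivalence: naive per-protein score-then-filter loop
  naive <- Filter(Negate(is.null), lapply(names(prot), function(id) {
    cs <- oracle_core_score(prot[[id]], tab, 60)
    if (is.null(cs) || cs$score < 25) NULL else
      data.frame(protein_id = id, core_score = cs$score)
  }))
  naive <- do.call(rbind, naive)
  expect_setequal(hits$protein_id, naive$protein_id)

  # sorted by descending score, ties by id
  expect_true(all(diff(hits$core_score) <= 1e-12))
  # hit-set nesting across thresholds
  h30 <- call_prlds(prot, tab, threshold = 30)
  expect_true(all(h30$protein_id %in% hits$protein_id))
  # determinism
  expect_identical(hits, call_prlds(prot, tab))
  # invariants on reported coordinates
  expect_true(all(hits$core_end - hits$core_start + 1 == 60))
  expect_true(all(hits$domain_start <= hits$core_start &
                    hits$core_end <= hits$domain_end))

  expect_error(call_prlds(stats::setNames(c("AAA", "CCC"), c("x", "x")),
                          tab), "duplicate")
})
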