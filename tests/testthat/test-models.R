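test_that("pop-cov scores equal allele frequency and match the coverage delta", {
  wx <- worked_example_fixture()
  t10 <- wx$toy10
  st <- score_pop_cov(t10$catalog)
  expect_equal(unname(st$scores), 0.3)

  # diagnostic: removing the interior SNV (f=0.3, s=4, W=7) lowers C(G*) by
  # 4 * 0.3 / 7
  c_star <- population_coverage(t10$ref, t10$catalog, s = 4L)
  c_without <- population_coverage(t10$ref, t10$catalog, integer(0), s = 4L)
  expect_equal(c_star - c_without, 4 * 0.3 / 7, tolerance = 1e-12)
  expect_equal(c_without, (3 * 1 + 4 * 0.7) / 7, tolerance = 1e-12)
  expect_equal(c_star, 1, tolerance = 1e-12)

  # a zero-frequency variant scores zero
  zc <- t10$catalog
  zc$variants$af <- 0
  expect_equal(unname(score_pop_cov(zc)$scores), 0)
})

test_that("population coverage is monotone along inclusion chains", {
  fx <- standard_fixture(seed = 8L)
  s <- fx$spec$s
  ids <- fx$catalog$variants$id
  set.seed(8)
  s1 <- sort(sample(ids, 50))
  s2 <- sort(union(s1, sample(ids, 80)))
  c0 <- population_coverage(fx$ref, fx$catalog, integer(0), s = s)
  c1 <- population_coverage(fx$ref, fx$catalog, s1, s = s)
  c2 <- population_coverage(fx$ref, fx$catalog, s2, s = s)
  c_all <- population_coverage(fx$ref, fx$catalog, s = s)
  expect_lte(c0, c1); expect_lte(c1, c2); expect_lte(c2, c_all + 1e-12)
  expect_equal(c_all, 1, tolerance = 1e-9)
})

test_that("uniqueness equals the number of distinct s-mer sequences", {
  expect_equal(uniqueness(count_smers(ref_genome(c(c1 = "AAAA")), NULL, 2L)), 1)
  wx <- worked_example_fixture()
  expect_equal(uniqueness(count_smers(wx$gatyaca$ref, NULL, 3L)), 5)
  fx <- standard_fixture(seed = 9L)
  cs <- count_smers(fx$ref, fx$catalog, fx$spec$s)
  expect_equal(uniqueness(cs), length(cs$counts))
  # repeats make uniqueness fall below the occurrence count
  expect_lt(uniqueness(cs), cs$total)
})

test_that("average probabilities match the worked length-10 example", {
  wx <- worked_example_fixture()
  t10 <- wx$toy10
  pb <- compute_p_bars(t10$ref, t10$catalog, s = 4L)
  expect_equal(pb$p_bar_star, (0.3 / 7), tolerance = 1e-12)
  expect_equal(pb$p_bar_ref, (5.8 / 7) / 7, tolerance = 1e-12)
  # no variants: p_bar_ref = 1/W, p_bar_star warned to 0
  empty <- t10$catalog
  empty$variants <- empty$variants[0, ]
  expect_warning(pb0 <- compute_p_bars(t10$ref, empty, s = 4L), "undefined")
  expect_equal(pb0$p_bar_ref, 1 / 7)
  expect_equal(pb0$p_bar_star, 0)
})

test_that("hybrid deltas follow the averaged-approximation formula", {
  wx <- worked_example_fixture()
  t10 <- wx$toy10
  ctx <- hybrid_context(t10$ref, t10$catalog, model_config(s = 4L))
  # unique smer: delta = p
  expect_equal(hybrid_delta(0.001, "ATGG", ctx), 0.001)
  expect_error(hybrid_delta(0.001, "ZZZZ", ctx), "absent")

  # crafted two-occurrence sequence: ref AAAA...TTTT with an SNV making a
  # duplicate of an existing ref smer
  fa <- write_test_fasta(tempfile(fileext = ".fa"),
                         c(c1 = "ACGTGGGGACTTACGT"))
  ref <- read_reference(fa)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = "c1", pos1 = 11, ref = "T", alt = "G",
                        af = "0.2")
  cat <- read_variants(vcf, ref)
  ctx2 <- hybrid_context(ref, cat, model_config(s = 4L))
  # the T>G SNV turns ACTT into ACGT, colliding with the two reference
  # copies of ACGT; verify the printed formula on that multiplicity
  f_star <- ctx2$counts_star
  dup <- "ACGT"
  fs <- unname(f_star[dup])
  expect_gte(fs, 2)
  f_ref <- ctx2$counts_ref[dup]
  f_ref <- if (is.na(f_ref)) 0 else unname(f_ref)
  abar <- ((fs - f_ref) * ctx2$p_bar_star + f_ref * ctx2$p_bar_ref) / fs
  p <- 0.004
  expect_equal(hybrid_delta(p, dup, ctx2), (p - abar) / fs, tolerance = 1e-12)
  # negative when the average exceeds p
  expect_lt(hybrid_delta(abar - 0.002, dup, ctx2), 0)
})

test_that("hybrid scores equal the exact oracle in the unique-smer regime", {
  wx <- worked_example_fixture()
  t10 <- wx$toy10
  cfg <- model_config(s = 4L)
  approx <- score_hybrid(t10$ref, t10$catalog, cfg)$scores
  exact <- score_hybrid_exact(t10$ref, t10$catalog, cfg)$scores
  expect_equal(unname(approx), 4 * 0.3 / 7, tolerance = 1e-9)
  expect_equal(unname(approx), unname(exact), tolerance = 1e-9)
  # single-variant catalog: exact = H(G*) - H(G_ref), via the naive oracle
  v <- t10$catalog$variants
  h_star <- naive_hybrid_H(t10$ref$chroms[[1]], v$pos, v$alt, v$af, TRUE, 4L)
  h_lin <- naive_hybrid_H(t10$ref$chroms[[1]], v$pos, v$alt, v$af, FALSE, 4L)
  expect_equal(unname(exact), h_star - h_lin, tolerance = 1e-9)
})

test_that("exact hybrid scoring matches a naive full-enumeration oracle", {
  # small random genome with a handful of SNVs, including planted repeats
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  seq <- paste0(base, substr(base, 1, 20))  # planted repeat
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = seq))
  ref <- read_reference(fa)
  pos1 <- c(10, 25, 41, 70)
  refal <- substring(seq, pos1, pos1)
  altal <- vapply(refal, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = rep("c1", 4), pos1 = pos1,
                        ref = refal, alt = altal,
                        af = c("0.1", "0.45", "0.3", "0.25"))
  cat <- read_variants(vcf, ref)
  cfg <- model_config(s = 8L)
  exact <- score_hybrid_exact(ref, cat, cfg)$scores
  v <- cat$variants
  for (i in seq_len(nrow(v))) {
    inc_all <- rep(TRUE, nrow(v))
    inc_wo <- inc_all; inc_wo[i] <- FALSE
    h_star <- naive_hybrid_H(seq, v$pos, v$alt, v$af, inc_all, 8L)
    h_wo <- naive_hybrid_H(seq, v$pos, v$alt, v$af, inc_wo, 8L)
    expect_equal(unname(exact[as.character(v$id[i])]), h_star - h_wo,
                 tolerance = 1e-9)
  }
})

test_that("repeat-inducing variants score below AF-matched unique ones", {
  # two SNVs with identical AF: the one at 1-based 17 (A->C) turns CCAC
  # into CCCC, duplicating the CCCC already present near the start; the
  # one at 1-based 7 (A->T) creates only genome-wide-unique 4-mers
  seq <- "GCCCCTAGGATCGACCACGT"
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = seq))
  ref <- read_reference(fa)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("c1", "c1"), pos1 = c(7, 17),
                        ref = c("A", "A"), alt = c("T", "C"),
                        af = c("0.3", "0.3"))
  cat <- read_variants(vcf, ref)
  cfg <- model_config(s = 4L)
  # precondition: the duplicate really exists in G*
  cs_star <- count_smers(ref, cat, 4L)
  expect_gte(unname(cs_star$counts["CCCC"]), 2L)
  exact <- score_hybrid_exact(ref, cat, cfg)$scores
  approx <- score_hybrid(ref, cat, cfg)$scores
  uniq_id <- as.character(cat$variants$id[cat$variants$pos == 6])
  dup_id <- as.character(cat$variants$id[cat$variants$pos == 16])
  expect_lt(exact[dup_id], exact[uniq_id])
  expect_lt(approx[dup_id], approx[uniq_id])
})

test_that("hybrid scoring refuses indels", {
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = "ACGTACGGTCAA"))
  ref <- read_reference(fa)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = "c1", pos1 = 4, ref = "TA", alt = "T",
                        af = "0.4")
  cat <- read_variants(vcf, ref)
  expect_error(score_hybrid(ref, cat, model_config(s = 4L)), "SNV")
  expect_error(score_hybrid_exact(ref, cat, model_config(s = 4L)), "SNV")
  # pop cov handles the same catalog without enumeration
  expect_equal(unname(score_pop_cov(cat)$scores), 0.4)
})
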