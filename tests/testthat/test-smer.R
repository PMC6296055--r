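test_that("window offsets clip at chromosome ends and cover indel spans", {
  fa <- write_test_fasta(tempfile(fileext = ".fa"),
                         c(c1 = "ACGTACGGTC"))  # length 10
  ref <- read_reference(fa)
  mkvar <- function(pos, refal = "A", altal = "C")
    data.frame(id = 1L, chrom = "c1", pos = pos, ref = refal, alt = altal)
  expect_equal(window_offsets(mkvar(5L), 4L, ref), 2:5)
  expect_equal(window_offsets(mkvar(0L), 4L, ref), 0L)
  expect_equal(window_offsets(mkvar(9L), 4L, ref), 6L)
  # deletion anchored at 4 deleting bases 5..6: offsets overlap the deleted
  # bases, not the anchor
  del <- mkvar(4L, refal = "ACG", altal = "A")
  expect_equal(window_offsets(del, 4L, ref), 2:6)
  # chromosome shorter than s
  tiny <- ref_genome(c(c1 = "ACG"))
  expect_warning(off <- window_offsets(mkvar(1L), 4L, tiny), "shorter")
  expect_length(off, 0)
})

test_that("localized s-mer enumeration reproduces the GATYACA example", {
  wx <- worked_example_fixture()
  g <- wx$gatyaca
  e <- enumerate_smers(g$ref, g$catalog, "toy", 2L, 3L)
  expect_setequal(e$seq, c("TTA", "TCA"))
  expect_equal(sum(e$p_s), 1)
  # window with no variants: single reference smer with p_s = 1
  e0 <- enumerate_smers(g$ref, g$catalog, "toy", 0L, 3L)
  expect_equal(e0$seq, "GAT")
  expect_equal(e0$p_s, 1)
  # two variants in window -> 4 combinations
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = "ACGTACGGTC"))
  ref <- read_reference(fa)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("c1", "c1"), pos1 = c(3, 5),
                        ref = c("G", "A"), alt = c("A", "G"),
                        af = c("0.2", "0.5"))
  cat2 <- read_variants(vcf, ref)
  e2 <- enumerate_smers(ref, cat2, "c1", 2L, 4L)
  expect_equal(nrow(e2), 4)
  expect_setequal(e2$seq, c("GTAC", "ATAC", "GTGC", "ATGC"))
  expect_equal(sum(e2$p_s), 1)
  # unphased probability is the independence product
  expect_equal(sort(e2$p_s), sort(c(0.8 * 0.5, 0.2 * 0.5, 0.8 * 0.5, 0.2 * 0.5)))
})

test_that("phased probabilities count haplotype co-occurrence", {
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = "ACGTACGGTC"))
  ref <- read_reference(fa)
  # 4 haplotypes, per-site alleles (R,R),(A,R),(A,A),(A,A); combo (A,A) -> 2/4
  hap <- matrix(c(0, 0,
                  1, 0,
                  1, 1,
                  1, 1), nrow = 4, byrow = TRUE)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("c1", "c1"), pos1 = c(3, 5),
                        ref = c("G", "A"), alt = c("A", "G"), hap = hap)
  cat <- read_variants(vcf, ref, use_gt = TRUE)
  e <- enumerate_smers(ref, cat, "c1", 2L, 4L, k_cap = 15L,
                       panel = cat$panel)
  both_alt <- e$p_s[e$seq == "ATGC"]
  expect_equal(both_alt, 0.5)
  expect_equal(sum(e$p_s), 1)
})

test_that("phased and unphased probabilities agree on an equilibrium panel", {
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = "ACGTACGGTC"))
  ref <- read_reference(fa)
  # co-occurrence counts equal products: af 0.5 and 0.5, combos 1/4 each
  hap <- matrix(c(0, 0,
                  0, 1,
                  1, 0,
                  1, 1), nrow = 4, byrow = TRUE)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = c("c1", "c1"), pos1 = c(3, 5),
                        ref = c("G", "A"), alt = c("A", "G"), hap = hap)
  cat <- read_variants(vcf, ref, use_gt = TRUE)
  e_ph <- enumerate_smers(ref, cat, "c1", 2L, 4L, panel = cat$panel)
  e_un <- enumerate_smers(ref, cat, "c1", 2L, 4L, panel = NULL)
  expect_equal(e_ph$p_s[order(e_ph$seq)], e_un$p_s[order(e_un$seq)])
})

test_that("s-mer counting matches a naive substring oracle", {
  # plain reference counting
  r <- ref_genome(c(c1 = "AAAA"))
  cs <- count_smers(r, NULL, 2L)
  expect_equal(unname(cs$counts["AA"]), 3L)
  expect_equal(length(cs$counts), 1)

  wx <- worked_example_fixture()
  cs3 <- count_smers(wx$gatyaca$ref, wx$gatyaca$catalog, 3L)
  expect_equal(length(cs3$counts), 8)
  expect_true(all(cs3$counts == 1L))
  expect_equal(unname(cs3$counts["TCA"]), 1L)

  # seeded fixture vs the naive oracle on the linear reference
  fx <- standard_fixture(seed = 2L)
  s <- fx$spec$s
  got <- count_smers(fx$ref, NULL, s)
  want <- naive_count(fx$ref$chroms, s)
  expect_equal(length(got$counts), length(want))
  expect_equal(got$counts[names(want)], stats::setNames(as.integer(want), names(want)))
})

test_that("probabilities over all combinations at every offset sum to one", {
  fx <- standard_fixture(seed = 4L)
  s <- fx$spec$s
  set.seed(7)
  offs <- sample(0:(total_length(fx$ref) - s), 50)
  for (l in offs) {
    e_un <- enumerate_smers(fx$ref, fx$catalog, "chr1", l, s)
    expect_equal(sum(e_un$p_s), 1, tolerance = 1e-9)
    e_ph <- enumerate_smers(fx$ref, fx$catalog, "chr1", l, s,
                            panel = fx$catalog$panel)
    expect_equal(sum(e_ph$p_s), 1, tolerance = 1e-9)
  }
})

test_that("N-containing windows are excluded from the offset denominator", {
  r <- ref_genome(c(c1 = "ACGTNACGT"))
  # offsets 0..5 for s=4; windows touching the N at 0-based pos 4 are
  # 1,2,3,4 -> valid offsets are 0 and 5
  expect_equal(n_window_offsets(r, 4L), 2L)
  cs <- count_smers(r, NULL, 4L)
  expect_equal(sort(names(cs$counts)), c("ACGT"))
  expect_equal(unname(cs$counts["ACGT"]), 2L)
})

test_that("adding a variant never decreases the G* occurrence total", {
  fx <- standard_fixture(seed = 5L)
  s <- fx$spec$s
  ids <- fx$catalog$variants$id
  sub1 <- fx$catalog
  sub1$variants <- sub1$variants[1:50, ]
  sub2 <- fx$catalog
  sub2$variants <- sub2$variants[1:51, ]
  t1 <- count_smers(fx$ref, sub1, s)$total
  t2 <- count_smers(fx$ref, sub2, s)$total
  expect_gte(t2, t1)
})

test_that("augmented FASTA export reproduces count_smers through an external-style recount", {
  wx <- worked_example_fixture()
  g <- wx$gatyaca
  out <- tempfile(fileext = ".fa")
  write_augmented_fasta(g$ref, g$catalog, 3L, out = out)
  aug <- read_reference(out)
  # one record per ALT-containing (offset, combo): SNV at pos 3, s=3 -> 3
  expect_equal(length(aug$chroms), 3)
  recount <- naive_count(c(g$ref$chroms, aug$chroms), 3L)
  direct <- count_smers(g$ref, g$catalog, 3L)
  expect_equal(length(recount), length(direct$counts))
  expect_equal(direct$counts[names(recount)],
               stats::setNames(as.integer(recount), names(recount)))

  # empty catalog -> empty export
  empty <- g$catalog
  empty$variants <- empty$variants[0, ]
  out2 <- tempfile(fileext = ".fa")
  write_augmented_fasta(g$ref, empty, 3L, out = out2)
  expect_equal(length(readLines(out2)), 0)

  # fixture-scale equivalence
  fx <- standard_fixture(seed = 6L)
  s <- fx$spec$s
  out3 <- tempfile(fileext = ".fa")
  write_augmented_fasta(fx$ref, fx$catalog, s, out = out3)
  aug3 <- Biostrings::readDNAStringSet(out3)
  recount3 <- naive_count(c(fx$ref$chroms, as.character(aug3)), s)
  direct3 <- count_smers(fx$ref, fx$catalog, s)
  expect_equal(length(recount3), length(direct3$counts))
  expect_equal(direct3$counts[names(recount3)],
               stats::setNames(as.integer(recount3), names(recount3)))
})

test_that("the per-window cap keeps the leftmost variant plus top AF others", {
  fa <- write_test_fasta(tempfile(fileext = ".fa"),
                         c(c1 = strrep("ACGT", 10)))
  ref <- read_reference(fa)
  # 5 SNVs within one s=20 window; cap at 3
  # reference ACGTACGT...: 1-based odd positions 11..19 are G,A,G,A,G
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = rep("c1", 5), pos1 = c(11, 13, 15, 17, 19),
                        ref = c("G", "A", "G", "A", "G"),
                        alt = rep("C", 5),
                        af = c("0.1", "0.9", "0.2", "0.8", "0.3"))
  cat <- read_variants(vcf, ref)
  e <- enumerate_smers(ref, cat, "c1", 10L, 20L, k_cap = 3L)
  # 2^3 combos: leftmost (af 0.1) + the two highest-AF others (0.9, 0.8)
  expect_equal(nrow(e), 8)
  in_combos <- sort(unique(unlist(e$alt_ids)))
  v <- cat$variants
  expect_equal(in_combos, v$id[v$af %in% c(0.1, 0.9, 0.8)])
  expect_equal(sum(e$p_s), 1, tolerance = 1e-12)
})
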