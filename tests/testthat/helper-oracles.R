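# Independent brute-force oracles, kept deliberately naive and separate
# from the package's own code paths.

# all length-s substrings of a character string (forward strand)
naive_smers <- function(seq, s) {
  L <- nchar(seq)
  if (L < s) return(character(0))
  substring(seq, 1:(L - s + 1), s:L)
}

# naive s-mer count table over a set of sequences
naive_count <- function(seqs, s) {
  all <- unlist(lapply(seqs, naive_smers, s = s))
  table(all)
}

# brute-force greedy selection: recompute argmax each step
naive_select <- function(score, chrom, pos, budget, w, s) {
  n <- length(score)
  cur <- score
  chrom_rank <- match(chrom, unique(chrom))
  selected <- logical(n)
  picked <- integer(0)
  while (length(picked) < min(budget, n)) {
    avail <- which(!selected)
    best <- max(cur[avail])
    cand <- avail[cur[avail] == best]
    cand <- cand[order(chrom_rank[cand], pos[cand])]
    i <- cand[1]
    selected[i] <- TRUE
    picked <- c(picked, i)
    nb <- which(!selected & chrom == chrom[i] & abs(pos - pos[i]) <= s)
    cur[nb] <- cur[nb] * w
  }
  picked
}

# brute-force hybrid statistic H(G) for a toy genome with SNVs only:
# enumerate every (offset, allele-combination), sum p/f over occurrences.
# `include` marks the variants present in G; probabilities use the full
# population AFs regardless.
naive_hybrid_H <- function(seq, pos0, alt, af, include, s) {
  L <- nchar(seq)
  offs <- 0:(L - s)
  occ_seq <- character(0); occ_p <- numeric(0)
  W <- length(offs)
  for (l in offs) {
    win <- which(pos0 >= l & pos0 < l + s & include)
    m <- length(win)
    for (ci in 0:(2^m - 1)) {
      mask <- as.logical(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), ci))
      smer <- substr(seq, l + 1, l + s)
      p <- 1 / W
      for (t in seq_len(m)) {
        i <- win[t]
        if (mask[t]) {
          rel <- pos0[i] - l
          substr(smer, rel + 1, rel + 1) <- alt[i]
          p <- p * af[i]
        } else p <- p * (1 - af[i])
      }
      # excluded variants in the window keep REF: their probability factor
      exc <- which(pos0 >= l & pos0 < l + s & !include)
      p <- p * prod(1 - af[exc])
      occ_seq <- c(occ_seq, smer); occ_p <- c(occ_p, p)
    }
  }
  f <- table(occ_seq)
  sum(occ_p / as.integer(f[occ_seq]))
}

# write a small VCF with AF INFO (and optional phased GT matrix of
# haplotypes, H x n) for fixture construction inside tests
write_test_vcf <- function(path, chrom, pos1, ref, alt, af = NULL,
                           hap = NULL) {
  n <- length(pos1)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(hap)) cols <- c(cols, "FORMAT",
                               sprintf("s%d", seq_len(nrow(hap) / 2)))
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  body <- vapply(seq_len(n), function(i) {
    info <- if (is.null(af)) "." else paste0("AF=", af[i])
    f <- c(chrom[i], pos1[i], ".", ref[i], alt[i], ".", "PASS", info)
    if (!is.null(hap)) {
      gts <- sprintf("%s|%s", hap[seq(1, nrow(hap), 2), i],
                     hap[seq(2, nrow(hap), 2), i])
      f <- c(f, "GT", gts)
    }
    paste(f, collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

write_test_fasta <- function(path, seqs) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# a cluster of n mutually co-windowed SNVs with random AFs, spacing bases
# apart, on a random background genome
make_cluster <- function(n, spacing, L = 400L, r = 50L, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(c1 = seq))
  ref <- read_reference(fa)
  pos1 <- 100 + spacing * (seq_len(n) - 1)
  refal <- substring(seq, pos1, pos1)
  altal <- vapply(refal, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  af <- round(stats::runif(n, 0.05, 0.95), 3)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        chrom = rep("c1", n), pos1 = pos1,
                        ref = refal, alt = altal, af = format(af))
  list(ref = ref, catalog = read_variants(vcf, ref), r = r)
}

# standard seeded fixture used by several suites (10 kb, 200 SNVs, 20%
# planted repeats, H = 20, s = 25)
standard_fixture <- function(seed = 1L) {
  spec <- fixture_spec(seed = seed)
  ref <- generate_reference(spec)
  catalog <- generate_panel(spec, ref,
                            file.path(tempdir(),
                                      sprintf("std_fix_%d.vcf", seed)))
  list(spec = spec, ref = ref, catalog = catalog)
}
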