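#' Specification for a synthetic fixture
#'
#' Describes a seeded synthetic dataset: a random reference genome with
#' tunable repeat content, a phased haplotype panel, and a variant catalog
#' with controllable allele-frequency spectrum and clustering. All
#' generators are pure functions of this spec (seed included).
#'
#' @param seed integer RNG seed.
#' @param genome_length total reference length in bp (default 10000).
#' @param n_chromosomes number of chromosomes, lengths split evenly
#'   (default 1).
#' @param repeat_fraction fraction of the genome overwritten by copies of
#'   earlier blocks (block length >= 2s), creating non-unique s-mers
#'   (default 0.2).
#' @param n_variants number of variant sites (default 200).
#' @param n_haplotypes panel size H, even (default 20).
#' @param af_distribution `"uniform"`, `"spiked"` (90% Beta(1, 9) rare
#'   alleles plus a 10% common spike Uniform(0.5, 1)), or
#'   `list("beta", alpha, beta)`.
#' @param cluster_rate probability a variant is placed within `s` of the
#'   previous one (default 0.1).
#' @param indel_fraction fraction of variants generated as short (1-3 bp)
#'   indels (default 0).
#' @param s window size used for repeat block sizing and clustering
#'   (default 25).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 10000L,
                         n_chromosomes = 1L, repeat_fraction = 0.2,
                         n_variants = 200L, n_haplotypes = 20L,
                         af_distribution = "uniform", cluster_rate = 0.1,
                         indel_fraction = 0, s = 25L) {
  if (genome_length < 10 * s) stop("genome_length must be >= 10*s")
  if (n_variants >= genome_length) stop("n_variants must be < genome_length")
  if (n_haplotypes < 2 || n_haplotypes %% 2 != 0)
    stop("n_haplotypes must be even and >= 2")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 repeat_fraction = repeat_fraction,
                 n_variants = as.integer(n_variants),
                 n_haplotypes = as.integer(n_haplotypes),
                 af_distribution = af_distribution,
                 cluster_rate = cluster_rate,
                 indel_fraction = indel_fraction,
                 s = as.integer(s)),
            class = "fixture_spec")
}

#' Generate a synthetic reference genome
#'
#' I.i.d. uniform bases, then `repeat_fraction` of each chromosome is
#' overwritten by copies of earlier blocks (block length >= 2s) so that a
#' controllable fraction of s-mers is non-unique. Deterministic given the
#' spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return A [ref_genome].
#' @export
generate_reference <- function(spec) {
  set.seed(spec$seed)
  .generate_reference_impl(spec)
}

.generate_reference_impl <- function(spec) {
  per <- floor(spec$genome_length / spec$n_chromosomes)
  lens <- rep(per, spec$n_chromosomes)
  lens[spec$n_chromosomes] <- spec$genome_length - per * (spec$n_chromosomes - 1L)
  block <- max(2L * spec$s, 50L)
  seqs <- character(spec$n_chromosomes)
  for (ci in seq_len(spec$n_chromosomes)) {
    L <- lens[ci]
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    target <- round(spec$repeat_fraction * L)
    planted <- 0L
    while (planted < target && L > 2L * block) {
      dst <- sample.int(L - block, 1L)
      src <- sample.int(L - block, 1L)
      if (abs(dst - src) < block) next  # avoid trivial self-copy
      bases[dst:(dst + block - 1L)] <- bases[src:(src + block - 1L)]
      planted <- planted + block
    }
    seqs[ci] <- paste(bases, collapse = "")
  }
  names(seqs) <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  ref_genome(seqs)
}

.draw_af <- function(spec, n) {
  d <- spec$af_distribution
  if (identical(d, "uniform")) stats::runif(n)
  else if (identical(d, "spiked")) {
    common <- stats::runif(n) < 0.1
    ifelse(common, stats::runif(n, 0.5, 1), stats::rbeta(n, 1, 9))
  } else if (is.list(d) && identical(d[[1]], "beta")) {
    stats::rbeta(n, d[[2]], d[[3]])
  } else stop("unknown af_distribution")
}

#' Generate a variant catalog and phased haplotype panel
#'
#' Variant positions follow the clustering process (with probability
#' `cluster_rate` a variant lands within `s` of the previous one, else
#' uniformly at random; collisions re-drawn). A target allele frequency is
#' drawn per site from `af_distribution`; each of the H haplotypes then
#' carries the ALT independently with that probability, and the *realized*
#' panel fraction is recorded as the AF (so phased and unphased marginals
#' agree by construction). Phased GTs pair haplotypes (2i-1, 2i).
#'
#' @param spec a [fixture_spec()].
#' @param ref the reference from [generate_reference()].
#' @param vcf_path output VCF path (AF INFO + phased GT columns).
#' @return The `variant_catalog` re-read from the written VCF against
#'   `ref`, with `vcf_path` in `$source`.
#' @export
generate_panel <- function(spec, ref, vcf_path = tempfile(fileext = ".vcf")) {
  set.seed(spec$seed + 1L)
  .generate_panel_impl(spec, ref, vcf_path)
}

.generate_panel_impl <- function(spec, ref, vcf_path) {
  nv <- spec$n_variants
  H <- spec$n_haplotypes
  chroms <- names(ref$chroms)
  # allocate variants to chromosomes proportional to length
  chrom_of <- sample(chroms, nv, replace = TRUE,
                     prob = ref$lengths / sum(ref$lengths))
  chrom_of <- sort(factor(chrom_of, levels = chroms))
  pos <- integer(nv); chrom <- as.character(chrom_of)
  used <- lapply(chroms, function(x) integer(0))
  names(used) <- chroms
  prev <- -1L; prev_chrom <- ""
  for (i in seq_len(nv)) {
    nm <- chrom[i]; L <- ref$lengths[[nm]]
    repeat {
      p <- if (nm == prev_chrom && prev >= 0 &&
               stats::runif(1) < spec$cluster_rate) {
        prev + sample.int(spec$s, 1L)
      } else {
        sample.int(L, 1L) - 1L  # 0-based
      }
      clear <- if (spec$indel_fraction > 0) {
        # keep indel REF spans from touching a neighboring record
        length(used[[nm]]) == 0 || min(abs(used[[nm]] - p)) > 4L
      } else !(p %in% used[[nm]])
      if (p >= 0 && p < L - 4L && clear) break
    }
    pos[i] <- p
    used[[nm]] <- c(used[[nm]], p)
    prev <- p; prev_chrom <- nm
  }
  o <- order(match(chrom, chroms), pos)
  chrom <- chrom[o]; pos <- pos[o]

  is_indel <- stats::runif(nv) < spec$indel_fraction
  ref_al <- character(nv); alt_al <- character(nv)
  for (i in seq_len(nv)) {
    base <- substr(ref$chroms[[chrom[i]]], pos[i] + 1L, pos[i] + 1L)
    if (!is_indel[i]) {
      ref_al[i] <- base
      alt_al[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (stats::runif(1) < 0.5) {  # insertion
      ins <- paste(sample(c("A", "C", "G", "T"),
                          sample.int(3L, 1L), replace = TRUE), collapse = "")
      ref_al[i] <- base
      alt_al[i] <- paste0(base, ins)
    } else {                             # deletion
      dlen <- sample.int(3L, 1L)
      ref_al[i] <- substr(ref$chroms[[chrom[i]]], pos[i] + 1L,
                          pos[i] + 1L + dlen)
      alt_al[i] <- base
    }
  }

  target_af <- .draw_af(spec, nv)
  carriers <- matrix(stats::rbinom(H * nv, 1L, rep(target_af, each = H)),
                     nrow = H)
  realized <- colMeans(carriers)

  gt_cols <- vapply(seq_len(H / 2L), function(sm) {
    sprintf("%d|%d", carriers[2L * sm - 1L, ], carriers[2L * sm, ])
  }, character(nv))
  if (nv == 1) gt_cols <- matrix(gt_cols, nrow = 1)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=varprior_fixture",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"ALT allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sprintf("hap%02d", seq_len(H / 2L))),
                 collapse = "\t"))
  body <- vapply(seq_len(nv), function(i) {
    paste(c(chrom[i], pos[i] + 1L, sprintf("var%d", i), ref_al[i], alt_al[i],
            ".", "PASS", sprintf("AF=%.10g", realized[i]), "GT",
            gt_cols[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), vcf_path)
  read_variants(vcf_path, ref)
}

#' Generate a complete fixture bundle on disk
#'
#' Writes `<prefix>.fa`, `<prefix>.vcf` and a `<prefix>.json` sidecar
#' recording the spec, where the prefix embeds the seed. Byte-identical
#' across repeated invocations with the same spec.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `ref`, `catalog`, and the three file `paths`.
#' @export
generate_fixture <- function(spec, dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, sprintf("fixture_seed%d", spec$seed))
  ref <- generate_reference(spec)
  write_reference(ref, paste0(prefix, ".fa"))
  catalog <- generate_panel(spec, ref, paste0(prefix, ".vcf"))
  jsonlite::write_json(unclass(spec), paste0(prefix, ".json"),
                       auto_unbox = TRUE)
  list(ref = ref, catalog = catalog,
       paths = list(fasta = paste0(prefix, ".fa"),
                    vcf = paste0(prefix, ".vcf"),
                    json = paste0(prefix, ".json")))
}

#' Load the worked-example toy bundles
#'
#' Two tiny datasets shipped with the package: the GATTACA toy (one SNV
#' T>C at 0-based position 3, whose s=3 localized s-mers include <GAT,0>,
#' <TTA,2> and <TCA,2>) and a length-10 single-chromosome genome with one
#' SNV of frequency 0.3 at 0-based position 5, used throughout the
#' documentation's worked examples.
#'
#' @return list of two bundles (`gatyaca`, `toy10`), each with `ref`,
#'   `catalog`, `fasta`, `vcf`.
#' @export
worked_example_fixture <- function() {
  load1 <- function(stem) {
    fa <- system.file("extdata", paste0(stem, ".fa"), package = "varprior")
    vcf <- system.file("extdata", paste0(stem, ".vcf"), package = "varprior")
    ref <- read_reference(fa)
    list(ref = ref, catalog = read_variants(vcf, ref), fasta = fa, vcf = vcf)
  }
  list(gatyaca = load1("gatyaca"), toy10 = load1("toy10"))
}
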