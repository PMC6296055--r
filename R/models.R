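#' Population-coverage score of a variant
#'
#' Under the complete-graph assumption (all other catalog variants assumed
#' present), the decrease in population coverage C(G) caused by removing a
#' variant is proportional to its ALT allele frequency, so the Pop Cov model
#' scores each variant by its raw allele frequency. Phasing is irrelevant
#' here: the complete graph covers every haplotype regardless of allele
#' co-occurrence.
#'
#' @param catalog a `variant_catalog`.
#' @return A `score_table`: list with `model = "pop_cov"`, `scores` (numeric
#'   vector named by variant id), and `config = NULL`.
#' @export
score_pop_cov <- function(catalog) {
  v <- catalog$variants
  structure(list(model = "pop_cov",
                 scores = stats::setNames(v$af, v$id),
                 config = NULL),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", x$model, "model,", length(x$scores), "variant(s)\n")
  invisible(x)
}

#' Population coverage of an augmented genome
#'
#' C(G) = sum over valid window offsets l and over allele combinations
#' realizable with the included variants (excluded variants held at REF) of
#' p(<s,l>) = p_s / W, where p_s is computed against the full population
#' frequencies (independence product, or haplotype co-occurrence when a
#' panel is supplied) and W is the number of valid window offsets. Satisfies
#' C(G_ref) <= C(G) <= C(G*) = 1. Computed by full per-offset enumeration;
#' no sequence content is needed, only probabilities.
#'
#' @param ref a [ref_genome].
#' @param catalog the full `variant_catalog` (defines the population).
#' @param included_ids ids of the variants included in G (default: all).
#' @param s window size.
#' @param phased use the catalog's haplotype panel if available.
#' @return C(G), a real in [0, 1].
#' @export
population_coverage <- function(ref, catalog, included_ids = NULL, s,
                                phased = TRUE) {
  vars <- catalog$variants
  if (is.null(included_ids)) included_ids <- vars$id
  panel <- if (phased) catalog$panel else NULL
  n_hap <- catalog$n_haplotypes
  W <- n_window_offsets(ref, s)
  if (W == 0) stop("no valid window offsets at s = ", s)
  total <- 0
  for (nm in names(ref$chroms)) {
    chrom_seq <- ref$chroms[[nm]]
    L <- nchar(chrom_seq)
    if (L < s) next
    valid <- .valid_offsets(chrom_seq, s)
    cv <- which(vars$chrom == nm)
    pos <- vars$pos[cv]
    for (l in which(valid) - 1L) {
      win <- cv[.vars_in_window(pos, l, s)]
      inc <- win[vars$id[win] %in% included_ids]
      exc <- setdiff(win, inc)
      m <- length(inc)
      if (m > 20) stop("window at ", nm, ":", l, " would enumerate 2^", m,
                       " combinations")
      off_sum <- 0
      for (ci in seq_len(bitwShiftL(1L, m))) {
        mask_inc <- as.logical(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L),
                                       ci - 1L))
        ord <- c(inc, exc)
        mask <- c(mask_inc, rep(FALSE, length(exc)))
        off_sum <- off_sum + .mask_prob(vars, ord, mask, panel, n_hap)
      }
      total <- total + off_sum
    }
  }
  total / W
}

#' Uniqueness of a genome from its s-mer counts
#'
#' U(G) = sum over (offset, combination) occurrences of 1 / f_G(seq), the
#' reciprocal of each occurrence's multiplicity. The sum telescopes to the
#' number of distinct s-mer sequences, which serves as a self-test of the
#' counting; it decreases (relative to the occurrence total) as the genome
#' becomes more repetitive. Exposed as a genome statistic, not a standalone
#' per-variant ranking model.
#'
#' @param counts an `smer_counts` object.
#' @return U(G).
#' @export
uniqueness <- function(counts) {
  f <- counts$counts
  sum(f * (1 / f))  # occurrence sum grouped by sequence
}

#' Pre-compute average probabilities for the hybrid approximation
#'
#' p_bar_ref is the mean of p over the all-REF localized s-mers (one per
#' valid offset); p_bar_star is the mean of p over the ALT-containing
#' localized s-mers of the complete augmented genome, i.e. those in G* but
#' not in G_ref. Means are taken over (offset, combination) occurrences,
#' globally across chromosomes.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @param s window size.
#' @param k_cap per-window variant cap.
#' @param panel optional haplotype panel (columns named by id).
#' @return list(p_bar_ref, p_bar_star); p_bar_star is 0 (with a warning)
#'   when the catalog is empty.
#' @export
compute_p_bars <- function(ref, catalog, s, k_cap = 15L, panel = NULL) {
  occ <- .smer_occurrences(ref, catalog, s, k_cap, panel)
  is_alt <- occ$n_alt > 0L
  p_bar_ref <- mean(occ$p[!is_alt])
  p_bar_star <- if (any(is_alt)) mean(occ$p[is_alt]) else {
    warning("no ALT-containing s-mers; p_bar_star undefined, returning 0")
    0
  }
  list(p_bar_ref = p_bar_ref, p_bar_star = p_bar_star)
}

#' Build the shared context for hybrid scoring
#'
#' Counts s-mers of the linear reference and of the complete augmented
#' genome, pre-computes the average probabilities, and aggregates per-
#' sequence probability mass (used by the exact-oracle mode).
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @param config a [model_config()].
#' @return An object of class `hybrid_context`.
#' @export
hybrid_context <- function(ref, catalog, config = model_config()) {
  s <- config$s; k_cap <- config$k_cap
  panel <- if (config$phased) catalog$panel else NULL
  cr <- count_smers(ref, NULL, s, k_cap)
  occ <- .smer_occurrences(ref, catalog, s, k_cap, panel)
  tab <- table(occ$seq)
  counts_star <- stats::setNames(as.integer(tab), names(tab))
  p_sum <- vapply(split(occ$p, occ$seq), sum, 0)
  is_alt <- occ$n_alt > 0L
  p_bar_ref <- mean(occ$p[!is_alt])
  p_bar_star <- if (any(is_alt)) mean(occ$p[is_alt]) else 0
  structure(list(s = s, k_cap = k_cap,
                 counts_ref = cr$counts, counts_star = counts_star,
                 p_bar_ref = p_bar_ref, p_bar_star = p_bar_star,
                 seq_p_sum = p_sum,
                 H_star = sum(p_sum / counts_star[names(p_sum)]),
                 W = attr(occ, "W"),
                 phased = !is.null(panel)),
            class = "hybrid_context")
}

#' @export
print.hybrid_context <- function(x, ...) {
  cat(sprintf(
    "hybrid_context: s=%d, %d distinct s-mers in G*, p_bar_ref=%.3g, p_bar_star=%.3g\n",
    x$s, length(x$counts_star), x$p_bar_ref, x$p_bar_star))
  invisible(x)
}

#' Change in hybrid score from one added localized s-mer
#'
#' For an ALT-containing s-mer with probability `p` and sequence `seq`, let
#' n = f_G*(seq) - 1 be the number of other occurrences of the same
#' sequence in the complete graph. The exact change is
#' (p - mean of the other occurrences' probabilities) / (n + 1); the mean is
#' approximated by the pre-computed weighted average
#' [(f_star - f_ref) * p_bar_star + f_ref * p_bar_ref] / f_star. A unique
#' s-mer (n = 0) contributes exactly p; a repetitive one can contribute a
#' negative amount.
#'
#' @param p probability of the s-mer.
#' @param seq its sequence.
#' @param ctx a [hybrid_context()].
#' @param avg_denom `"f_star"` applies the averaged approximation exactly as
#'   printed (denominator includes the candidate occurrence); `"n"` excludes
#'   it. Switchable for sensitivity analysis.
#' @return The approximate delta-H (may be negative).
#' @export
hybrid_delta <- function(p, seq, ctx, avg_denom = c("f_star", "n")) {
  avg_denom <- match.arg(avg_denom)
  f_star <- ctx$counts_star[seq]
  if (is.na(f_star)) stop("s-mer absent from the G* count table: ", seq)
  f_star <- unname(f_star)
  n <- f_star - 1L
  if (n == 0L) return(p)
  f_ref <- ctx$counts_ref[seq]
  f_ref <- if (is.na(f_ref)) 0L else unname(f_ref)
  denom <- if (avg_denom == "f_star") f_star else n
  abar <- (max(f_star - f_ref, 0) * ctx$p_bar_star +
             min(f_ref, f_star) * ctx$p_bar_ref) / denom
  (p - abar) / (n + 1)
}

# all (offset, combo) ALT s-mers carrying variant v's ALT allele:
# data.frame(seq, p), enumerated over capped windows of G*
.variant_alt_smers <- function(ref, catalog, v_row, s, k_cap, panel) {
  vars <- catalog$variants
  chrom_seq <- ref$chroms[[v_row$chrom]]
  L <- nchar(chrom_seq)
  offs <- window_offsets(v_row, s, ref)
  if (length(offs) == 0)
    return(data.frame(seq = character(), p = numeric()))
  valid <- .valid_offsets(chrom_seq, s)
  W <- n_window_offsets(ref, s)
  cv <- which(vars$chrom == v_row$chrom)
  pos <- vars$pos[cv]
  chunks <- list()
  for (l in offs) {
    if (!valid[l + 1L]) next
    win <- cv[.vars_in_window(pos, l, s)]
    win <- .cap_window(win, vars, k_cap)
    if (!any(vars$id[win] == v_row$id)) next  # capped out of this window
    e <- .enumerate_offset(chrom_seq, l, s, vars, win, panel,
                           catalog$n_haplotypes)
    hit <- vapply(e$alt_ids, function(x) v_row$id %in% x, TRUE) & !is.na(e$seq)
    if (any(hit))
      chunks[[length(chunks) + 1L]] <- data.frame(
        seq = e$seq[hit], p = e$p_s[hit] / W, stringsAsFactors = FALSE)
  }
  if (length(chunks)) do.call(rbind, chunks)
  else data.frame(seq = character(), p = numeric())
}

#' Hybrid scores for all variants (averaged approximation)
#'
#' The hybrid score of a variant is the sum of [hybrid_delta()] over every
#' localized s-mer that overlaps the variant and carries its ALT allele
#' (all window offsets times capped combinations of neighboring variants).
#' Phased window probabilities are used when the catalog has a panel and
#' `config$phased` is TRUE. SNVs only: an indel in the catalog is an error.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @param config a [model_config()].
#' @param ctx optional pre-built [hybrid_context()] (rebuilt if missing).
#' @param avg_denom passed to [hybrid_delta()].
#' @return A `score_table` with `model = "hybrid"`.
#' @export
score_hybrid <- function(ref, catalog, config = model_config(), ctx = NULL,
                         avg_denom = "f_star") {
  vars <- catalog$variants
  if (any(!vars$is_snv))
    stop("hybrid model supports SNVs only; indel at ",
         vars$chrom[!vars$is_snv][1], ":", vars$pos[!vars$is_snv][1] + 1L)
  if (is.null(ctx)) ctx <- hybrid_context(ref, catalog, config)
  panel <- if (config$phased) catalog$panel else NULL
  scores <- numeric(nrow(vars))
  for (r in seq_len(nrow(vars))) {
    sm <- .variant_alt_smers(ref, catalog, vars[r, ], config$s,
                             config$k_cap, panel)
    scores[r] <- if (nrow(sm) == 0) 0 else
      sum(vapply(seq_len(nrow(sm)), function(i)
        hybrid_delta(sm$p[i], sm$seq[i], ctx, avg_denom), 0))
  }
  structure(list(model = "hybrid",
                 scores = stats::setNames(scores, vars$id),
                 config = config),
            class = "score_table")
}

#' Exact hybrid scores (brute-force oracle)
#'
#' Computes H(G*) - H(G* minus v) for each variant by direct enumeration:
#' H(G) is the sum over (offset, combination) occurrences of p / f_G(seq).
#' Removing v deletes its ALT-carrying occurrences and decrements the
#' multiplicity of their sequences, which also re-weights the surviving
#' occurrences of those sequences. The per-window variant cap of G* is held
#' fixed for both genomes. Intended as the oracle for [score_hybrid()] at
#' fixture scale.
#'
#' @inheritParams score_hybrid
#' @return A `score_table` with `model = "hybrid_exact"`.
#' @export
score_hybrid_exact <- function(ref, catalog, config = model_config(),
                               ctx = NULL) {
  vars <- catalog$variants
  if (any(!vars$is_snv)) stop("hybrid model supports SNVs only")
  if (is.null(ctx)) ctx <- hybrid_context(ref, catalog, config)
  if (sum(ctx$counts_star) > 1e6)
    stop("enumeration bound exceeded (", sum(ctx$counts_star),
         " occurrences); exact mode is fixture-scale only")
  panel <- if (config$phased) catalog$panel else NULL
  f <- ctx$counts_star
  P <- ctx$seq_p_sum
  scores <- numeric(nrow(vars))
  for (r in seq_len(nrow(vars))) {
    sm <- .variant_alt_smers(ref, catalog, vars[r, ], config$s,
                             config$k_cap, panel)
    if (nrow(sm) == 0) { scores[r] <- 0; next }
    p_rm <- vapply(split(sm$p, sm$seq), sum, 0)
    c_rm <- vapply(split(sm$p, sm$seq), length, 0L)
    sq <- names(p_rm)
    f0 <- unname(f[sq]); P0 <- unname(P[sq])
    f1 <- f0 - c_rm
    kept <- ifelse(f1 > 0, (P0 - p_rm) / f1, 0)
    # H(G* \ v) = H_star - sum(P0/f0) + sum(kept); score = H_star - H(G*\v)
    scores[r] <- sum(P0 / f0) - sum(kept)
  }
  structure(list(model = "hybrid_exact",
                 scores = stats::setNames(scores, vars$id),
                 config = config),
            class = "score_table")
}
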