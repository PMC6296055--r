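#' Model configuration
#'
#' Bundles the tunable parameters shared by the s-mer engine, the variant
#' models, and the enhanced-segment builder.
#'
#' @param s window size (localized s-mer length); typically the maximum read
#'   length. Default 100.
#' @param k_cap per-window variant cap: windows containing more variants are
#'   restricted to the leftmost variant plus the `k_cap - 1` highest-AF
#'   others (ties to the leftmost), all remaining variants held at REF.
#'   Default 15; must be <= 24 (enumeration bound).
#' @param phased use haplotype co-occurrence probabilities when a panel is
#'   available. Default TRUE.
#' @param w blowup-avoidance penalty in (0, 1]; `w = 0` is additionally
#'   accepted as a diagnostic mode. Default 0.5.
#' @param erg_r enhanced-segment context window; defaults to `s`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(s = 100L, k_cap = 15L, phased = TRUE, w = 0.5,
                         erg_r = NULL) {
  s <- as.integer(s); k_cap <- as.integer(k_cap)
  if (s < 2) stop("window size s must be >= 2")
  if (k_cap < 1 || k_cap > 24) stop("k_cap must be in [1, 24]")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (is.null(erg_r)) erg_r <- s
  structure(list(s = s, k_cap = k_cap, phased = isTRUE(phased), w = w,
                 erg_r = as.integer(erg_r)),
            class = "model_config")
}

#' Window offsets overlapping a variant
#'
#' All 0-based offsets `l` such that the length-`s` window `[l, l+s)`
#' overlaps the variant's affected reference interval, clipped to valid
#' offsets `[0, chrom_len - s]`. For an SNV the affected interval is the
#' substituted base (an interior SNV has exactly `s` offsets); for a
#' deletion, the deleted bases; for an insertion, the anchor base.
#'
#' @param variant one row of a catalog's `variants` data.frame.
#' @param s window size.
#' @param ref a [ref_genome].
#' @return Integer vector of 0-based offsets (empty, with a warning, if the
#'   chromosome is shorter than `s`).
#' @export
window_offsets <- function(variant, s, ref) {
  L <- ref$lengths[[variant$chrom]]
  if (L < s) {
    warning("chromosome ", variant$chrom, " shorter than window size ", s)
    return(integer(0))
  }
  iv <- .affected_interval(variant$pos, variant$ref, variant$alt)
  lo <- max(0L, iv[1] - s + 1L)
  hi <- min(iv[2] - 1L, L - s)
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

# affected reference interval [a, b), 0-based half-open
.affected_interval <- function(pos, ref_allele, alt_allele) {
  rl <- nchar(ref_allele); al <- nchar(alt_allele)
  if (rl > al) c(pos + al, pos + rl)          # deletion: the deleted bases
  else if (rl == 1L && al == 1L) c(pos, pos + 1L)  # SNV
  else if (al > rl) c(pos, pos + rl)          # insertion: anchor base(s)
  else c(pos, pos + rl)                       # MNV
}

# variants (row indices into vars) whose start lies in [l, l+s)
.vars_in_window <- function(vars_pos, l, s) {
  which(vars_pos >= l & vars_pos < l + s)
}

# apply the per-window cap: keep leftmost + (k_cap-1) highest-AF others,
# ties broken by leftmost position; returns indices sorted by position
.cap_window <- function(win, vars, k_cap) {
  if (length(win) <= k_cap) return(win)
  left <- win[which.min(vars$pos[win])]
  others <- setdiff(win, left)
  o <- others[order(-vars$af[others], vars$pos[others])]
  sort(c(left, o[seq_len(k_cap - 1L)]))
}

# build the edited length-s window sequence at offset l for a given ALT mask
# over the (capped) window variants; edits applied left-to-right in
# reference coordinates, extending rightward for deletions; returns the
# length-s prefix (NA if the sequence runs off the chromosome end).
.window_seq <- function(chrom_seq, l, s, vars, win, mask) {
  if (!any(mask)) return(substr(chrom_seq, l + 1L, l + s))
  out <- ""
  cur <- l  # 0-based cursor in reference coordinates
  L <- nchar(chrom_seq)
  for (t in seq_along(win)) {
    if (!mask[t]) next
    i <- win[t]
    p <- vars$pos[i]
    if (p > cur) out <- paste0(out, substr(chrom_seq, cur + 1L, p))
    if (p >= cur) {
      out <- paste0(out, vars$alt[i])
      cur <- p + nchar(vars$ref[i])
    }
    if (nchar(out) >= s) break
  }
  if (nchar(out) < s) {
    need <- s - nchar(out)
    if (cur + need > L) return(NA_character_)
    out <- paste0(out, substr(chrom_seq, cur + 1L, cur + need))
  }
  substr(out, 1L, s)
}

# probability of an ALT mask over the capped window variants: independence
# product from allele frequencies, or haplotype co-occurrence fraction when
# a panel is supplied. Marginal over the capped set (variants dropped by the
# cap are held at REF in the sequence but marginalized out), so the masks at
# any offset sum to exactly 1.
.mask_prob <- function(vars, win, mask, panel, n_hap) {
  if (length(win) == 0) return(1)
  if (is.null(panel)) {
    af <- vars$af[win]
    prod(ifelse(mask, af, 1 - af))
  } else {
    sub <- panel[, as.character(vars$id[win]), drop = FALSE]
    target <- as.integer(mask)
    sum(colSums(t(sub) == target) == length(win)) / n_hap
  }
}

#' Enumerate the localized s-mers at one offset
#'
#' One s-mer per combination of REF/ALT alleles of the (capped) variants
#' starting in `[l, l+s)`, including the all-REF combination. Probabilities
#' are haplotype co-occurrence fractions when `panel` is supplied, else
#' independence products of allele frequencies.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @param chrom chromosome name.
#' @param l 0-based window offset.
#' @param s window size.
#' @param k_cap per-window variant cap (see [model_config()]).
#' @param panel optional haplotype panel matrix (columns named by id).
#' @return data.frame with columns `seq`, `p_s`, `p`, `n_alt` and a
#'   list-column `alt_ids`; attribute `valid` is FALSE when the reference
#'   window contains N (such windows are excluded from counting).
#' @export
enumerate_smers <- function(ref, catalog, chrom, l, s, k_cap = 15L,
                            panel = NULL) {
  vars <- catalog$variants
  chrom_seq <- ref$chroms[[chrom]]
  on_chrom <- which(vars$chrom == chrom)
  win <- on_chrom[.vars_in_window(vars$pos[on_chrom], l, s)]
  win <- .cap_window(win, vars, k_cap)
  W <- n_window_offsets(ref, s)
  res <- .enumerate_offset(chrom_seq, l, s, vars, win, panel,
                           catalog$n_haplotypes)
  res$p <- res$p_s / W
  attr(res, "valid") <- !grepl("N", substr(chrom_seq, l + 1L, l + s), fixed = TRUE)
  res
}

.enumerate_offset <- function(chrom_seq, l, s, vars, win, panel, n_hap) {
  m <- length(win)
  if (m > 20) stop("window at offset ", l, " would enumerate 2^", m,
                   " allele combinations; raise the cap bound deliberately")
  n_combo <- bitwShiftL(1L, m)
  seqs <- character(n_combo); ps <- numeric(n_combo)
  n_alt <- integer(n_combo); ids <- vector("list", n_combo)
  for (ci in seq_len(n_combo)) {
    mask <- as.logical(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), ci - 1L))
    seqs[ci] <- .window_seq(chrom_seq, l, s, vars, win, mask)
    ps[ci] <- .mask_prob(vars, win, mask, panel, n_hap)
    n_alt[ci] <- sum(mask)
    ids[[ci]] <- vars$id[win][mask]
  }
  out <- data.frame(seq = seqs, p_s = ps, n_alt = n_alt,
                    stringsAsFactors = FALSE)
  out$alt_ids <- ids
  out
}

#' Number of valid window offsets
#'
#' The denominator W of the uniform window-offset prior: the number of
#' offsets `l` with `l + s <= chrom_len`, summed over chromosomes, excluding
#' offsets whose reference window contains N.
#'
#' @param ref a [ref_genome].
#' @param s window size.
#' @return integer W.
#' @export
n_window_offsets <- function(ref, s) {
  W <- 0L
  for (nm in names(ref$chroms)) {
    L <- ref$lengths[[nm]]
    if (L < s) next
    W <- W + L - s + 1L - sum(!.valid_offsets(ref$chroms[[nm]], s))
  }
  W
}

# logical vector over offsets 0..L-s: TRUE if window free of N
.valid_offsets <- function(chrom_seq, s) {
  L <- nchar(chrom_seq)
  n_off <- L - s + 1L
  npos <- which(strsplit(chrom_seq, "", fixed = TRUE)[[1]] == "N")
  ok <- rep(TRUE, n_off)
  for (p in npos) {  # 1-based N position touches offsets (p-s)..(p-1) 0-based
    lo <- max(1L, p - s + 1L); hi <- min(n_off, p)
    if (lo <= hi) ok[lo:hi] <- FALSE
  }
  ok
}

# Occurrence table of the augmented genome: one row per (offset, combo)
# over all valid (N-free) offsets, with sequence, probability and an
# ALT-containing flag. The workhorse behind count_smers, compute_p_bars and
# the hybrid context.
.smer_occurrences <- function(ref, catalog, s, k_cap, panel = NULL) {
  vars <- if (is.null(catalog)) .empty_variants() else catalog$variants
  n_hap <- if (is.null(catalog)) 0L else catalog$n_haplotypes
  W <- n_window_offsets(ref, s)
  chunks <- list()
  for (nm in names(ref$chroms)) {
    chrom_seq <- ref$chroms[[nm]]
    L <- nchar(chrom_seq)
    if (L < s) next
    valid <- .valid_offsets(chrom_seq, s)
    offs <- which(valid) - 1L  # 0-based
    cv <- which(vars$chrom == nm)
    pos <- vars$pos[cv]
    # offsets whose window contains >=1 variant start
    has_var <- rep(FALSE, L - s + 1L)
    for (p in pos) {
      lo <- max(0L, p - s + 1L); hi <- min(p, L - s)
      if (lo <= hi) has_var[(lo:hi) + 1L] <- TRUE
    }
    plain <- offs[!has_var[offs + 1L]]
    if (length(plain)) {
      chunks[[length(chunks) + 1L]] <- data.frame(
        seq = substring(chrom_seq, plain + 1L, plain + s),
        p_s = 1, n_alt = 0L, stringsAsFactors = FALSE)
    }
    for (l in offs[has_var[offs + 1L]]) {
      win <- cv[.vars_in_window(pos, l, s)]
      win <- .cap_window(win, vars, k_cap)
      e <- .enumerate_offset(chrom_seq, l, s, vars, win, panel, n_hap)
      chunks[[length(chunks) + 1L]] <- e[!is.na(e$seq),
                                         c("seq", "p_s", "n_alt")]
    }
  }
  occ <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(seq = character(), p_s = numeric(), n_alt = integer())
  occ$p <- occ$p_s / W
  attr(occ, "W") <- W
  occ
}

#' Count localized s-mers of an augmented genome
#'
#' Counts every localized s-mer of the augmented genome exactly once per
#' (offset, allele-combination) pair: with an empty catalog this is plain
#' forward-strand s-mer counting of the linear reference. Windows whose
#' reference sequence contains N are excluded.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`, or NULL for the linear reference.
#' @param s window size.
#' @param k_cap per-window variant cap.
#' @return An object of class `smer_counts`: list with `s`, `counts` (named
#'   integer vector, sequence -> multiplicity) and `total`.
#' @export
count_smers <- function(ref, catalog = NULL, s, k_cap = 15L) {
  occ <- .smer_occurrences(ref, catalog, s, k_cap, panel = NULL)
  tab <- table(occ$seq)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(s = as.integer(s), counts = counts,
                 total = sum(counts)),
            class = "smer_counts")
}

#' @export
print.smer_counts <- function(x, ...) {
  cat("smer_counts: s =", x$s, ",", length(x$counts), "distinct,",
      x$total, "total occurrences\n")
  invisible(x)
}

#' Write an s-mer count table as TSV
#' @param counts an `smer_counts` object.
#' @param out output path (two columns: seq, count).
#' @return `out`, invisibly.
#' @export
write_smer_counts <- function(counts, out) {
  df <- data.frame(seq = names(counts$counts),
                   count = unname(counts$counts))
  df <- df[order(df$seq), ]
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Export ALT-containing windows as an augmented FASTA
#'
#' Writes one length-`s` record per (offset, ALT-containing combination), so
#' that the set of length-`s` substrings of this file together with the
#' linear reference reproduces [count_smers()] exactly once per occurrence —
#' suitable as input to an external exact k-mer counter. Records are named
#' `chrom:l:mask` where `mask` is the hyphen-joined list of ALT variant ids.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @param s window size.
#' @param k_cap per-window variant cap.
#' @param out output FASTA path.
#' @return `out`, invisibly.
#' @export
write_augmented_fasta <- function(ref, catalog, s, k_cap = 15L, out) {
  vars <- catalog$variants
  recs <- character(); nms <- character()
  for (nm in names(ref$chroms)) {
    chrom_seq <- ref$chroms[[nm]]
    L <- nchar(chrom_seq)
    if (L < s) next
    valid <- .valid_offsets(chrom_seq, s)
    cv <- which(vars$chrom == nm)
    pos <- vars$pos[cv]
    touched <- sort(unique(unlist(lapply(pos, function(p) {
      lo <- max(0L, p - s + 1L); hi <- min(p, L - s)
      if (lo <= hi) lo:hi else integer(0)
    }))))
    for (l in touched) {
      if (!valid[l + 1L]) next
      win <- cv[.vars_in_window(pos, l, s)]
      win <- .cap_window(win, vars, k_cap)
      e <- .enumerate_offset(chrom_seq, l, s, vars, win, panel = NULL,
                             n_hap = 0L)
      alt <- e[e$n_alt > 0L & !is.na(e$seq), , drop = FALSE]
      if (nrow(alt)) {
        recs <- c(recs, alt$seq)
        nms <- c(nms, sprintf("%s:%d:%s", nm, l,
                              vapply(alt$alt_ids, paste, "", collapse = "-")))
      }
    }
  }
  dss <- Biostrings::DNAStringSet(recs)
  names(dss) <- nms
  Biostrings::writeXStringSet(dss, out, width = 70L)
  invisible(out)
}
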