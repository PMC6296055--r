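#' Build enhanced reference segments
#'
#' An enhanced segment is a reference substring carrying a combination of
#' ALT alleles plus flanking context, so that a linear aligner can match any
#' length-`r` read overlapping those ALTs. Segments are anchored at their
#' leftmost ALT variant: for each variant v, the co-window set is v plus the
#' variants starting within `r - 1` bases to v's right; if that set exceeds
#' `k` it is restricted to v plus the `k - 1` highest-AF members (AF ties to
#' the leftmost), and one segment is emitted per ALT subset containing v.
#' Each distinct ALT combination within any length-`r` window is therefore
#' emitted exactly once, so a cluster of n <= k mutually co-windowed
#' variants yields exactly 2^n - 1 segments, and every variant's ALT is
#' covered by at least one segment (via its own anchor) for every k >= 1.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog` (typically the selected subset).
#' @param r context window length, typically the maximum read length.
#' @param k per-window variant cap (default 15, max 24).
#' @return data.frame with columns chrom, start, end (0-based half-open
#'   reference span, clipped at chromosome ends), anchor_id, seq, mask, and
#'   a list-column alt_ids.
#' @export
build_enhanced_segments <- function(ref, catalog, r, k = 15L) {
  if (r < 2) stop("context window r must be >= 2")
  if (k > 24) stop("k must be <= 24 (enumeration bound)")
  vars <- catalog$variants
  segs <- list()
  for (nm in unique(vars$chrom)) {
    cv <- which(vars$chrom == nm)
    cv <- cv[order(vars$pos[cv])]
    chrom_seq <- ref$chroms[[nm]]
    L <- nchar(chrom_seq)
    for (a in cv) {
      pv <- vars$pos[a]
      right <- cv[vars$pos[cv] > pv & vars$pos[cv] <= pv + r - 1L]
      if (length(right) + 1L > k) {
        o <- right[order(-vars$af[right], vars$pos[right])]
        right <- sort(o[seq_len(k - 1L)])
      }
      m <- length(right)
      n_seg <- bitwShiftL(1L, m)
      start <- max(0L, pv - (r - 1L))
      snv_only <- all(vars$is_snv[c(a, right)])
      # span for the widest subset; per-mask spans are truncations of it
      max_end <- min(L, max(vars$pos[c(a, right)] +
                              nchar(vars$ref[c(a, right)])) + r - 1L)
      base_chars <- if (snv_only)
        strsplit(substr(chrom_seq, start + 1L, max_end), "")[[1]] else NULL
      seq_v <- character(n_seg); end_v <- integer(n_seg)
      mask_v <- character(n_seg)
      for (ci in seq_len(n_seg)) {
        sel <- as.logical(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), ci - 1L))
        members <- c(a, right[sel])
        right_end <- max(vars$pos[members] + nchar(vars$ref[members]))
        end <- min(L, right_end + r - 1L)
        if (snv_only) {
          ch <- base_chars
          ch[vars$pos[members] - start + 1L] <- vars$alt[members]
          seq_v[ci] <- paste(ch[seq_len(end - start)], collapse = "")
        } else {
          seq_v[ci] <- .apply_edits(chrom_seq, start, end, vars, members)
        }
        end_v[ci] <- end
        mask_v[ci] <- paste(vars$id[sort(members)], collapse = "-")
      }
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = nm, start = start, end = end_v, anchor_id = vars$id[a],
        seq = seq_v, mask = mask_v, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               anchor_id = integer(), seq = character(), mask = character(),
               stringsAsFactors = FALSE)
  out$alt_ids <- lapply(strsplit(out$mask, "-", fixed = TRUE), as.integer)
  out
}

# edited sequence of reference span [start, end) with the given variant rows
# set to ALT; edits applied left-to-right with coordinate bookkeeping
.apply_edits <- function(chrom_seq, start, end, vars, members) {
  members <- members[order(vars$pos[members])]
  out <- ""
  cur <- start
  for (i in members) {
    p <- vars$pos[i]
    if (p < cur) next  # overlap with a previous edit; leftmost wins
    if (p > cur) out <- paste0(out, substr(chrom_seq, cur + 1L, p))
    out <- paste0(out, vars$alt[i])
    cur <- p + nchar(vars$ref[i])
  }
  if (cur < end) out <- paste0(out, substr(chrom_seq, cur + 1L, end))
  out
}

#' Write an enhanced reference FASTA
#'
#' The original reference records followed by one record per enhanced
#' segment, named `chrom:start:mask` where `mask` is the hyphen-joined list
#' of ALT variant ids; segment records are emitted in deterministic
#' (chromosome, anchor position, start, mask) order.
#'
#' @param segments output of [build_enhanced_segments()].
#' @param ref a [ref_genome].
#' @param out output FASTA path.
#' @return `out`, invisibly.
#' @export
write_erg_fasta <- function(segments, ref, out) {
  seqs <- ref$chroms
  if (nrow(segments)) {
    o <- order(match(segments$chrom, names(ref$chroms)),
               segments$anchor_id, segments$start, segments$mask)
    seg <- segments[o, ]
    seqs <- c(seqs, stats::setNames(
      seg$seq, sprintf("%s:%d:%s", seg$chrom, seg$start, seg$mask)))
  }
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, out, width = 70L)
  invisible(out)
}

#' Build the major-allele baseline reference
#'
#' A linear reference in which every variant site carries its most frequent
#' allele: a site's ALT is applied when it is strictly more frequent than
#' the reference allele — for a biallelic site, AF > 0.5, with ties keeping
#' REF; for multi-allelic sites (split into biallelic records) the single
#' most frequent allele among REF and all ALTs wins. Indels are applied with
#' the coordinate shift tracked in an offset map. Records whose REF no
#' longer matches the input genome are skipped with a warning, which makes
#' the transform idempotent. Overlapping winning ALTs: leftmost applied,
#' conflict warned.
#'
#' @param ref a [ref_genome].
#' @param catalog a `variant_catalog`.
#' @return list with `ref` (the edited [ref_genome]) and `offset_map`
#'   (data.frame chrom, ref_pos, shifted_pos; 1-based positions of each
#'   applied edit).
#' @export
build_major_allele_reference <- function(ref, catalog) {
  vars <- catalog$variants
  winners <- integer(0)
  if (nrow(vars)) {
    key <- paste(vars$chrom, vars$pos, vars$ref, sep = ":")
    for (kk in unique(key)) {
      rows <- which(key == kk)
      ref_freq <- 1 - sum(vars$af[rows])
      best <- rows[which.max(vars$af[rows])]
      # strict majority over REF: a biallelic ALT wins iff af > 0.5 (ties
      # keep REF); at multi-split sites the single most frequent allele
      # among REF and the ALTs wins
      if (vars$af[best] > ref_freq) winners <- c(winners, best)
    }
  }
  out_seqs <- ref$chroms
  map <- list()
  for (nm in names(ref$chroms)) {
    w <- winners[vars$chrom[winners] == nm]
    w <- w[order(vars$pos[w])]
    chrom_seq <- ref$chroms[[nm]]
    out <- ""
    cur <- 0L
    shift <- 0L
    for (i in w) {
      p <- vars$pos[i]
      if (p < cur) {
        warning("overlapping major alleles at ", nm, ":", p + 1L,
                "; leftmost applied")
        next
      }
      if (substr(chrom_seq, p + 1L, p + nchar(vars$ref[i])) != vars$ref[i]) {
        warning("REF mismatch at ", nm, ":", p + 1L, "; edit skipped")
        next
      }
      out <- paste0(out, substr(chrom_seq, cur + 1L, p), vars$alt[i])
      cur <- p + nchar(vars$ref[i])
      map[[length(map) + 1L]] <- data.frame(
        chrom = nm, ref_pos = p + 1L, shifted_pos = p + 1L + shift,
        stringsAsFactors = FALSE)
      shift <- shift + nchar(vars$alt[i]) - nchar(vars$ref[i])
    }
    out <- paste0(out, substr(chrom_seq, cur + 1L, nchar(chrom_seq)))
    out_seqs[[nm]] <- out
  }
  offset_map <- if (length(map)) do.call(rbind, map) else
    data.frame(chrom = character(), ref_pos = integer(),
               shifted_pos = integer(), stringsAsFactors = FALSE)
  list(ref = ref_genome(out_seqs), offset_map = offset_map)
}

#' Write a major-allele offset map as TSV
#' @param offset_map the `offset_map` from [build_major_allele_reference()].
#' @param out output path (columns chrom, ref_pos, shifted_pos).
#' @return `out`, invisibly.
#' @export
write_offset_map <- function(offset_map, out) {
  utils::write.table(offset_map, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
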