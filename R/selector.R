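#' Rank variants by score with positional tie-breaking
#'
#' Descending score; ties broken by lower-numbered chromosome (order of
#' appearance in the catalog), then smaller offset. Stable and
#' deterministic.
#'
#' @param scores a `score_table` or a numeric vector named by variant id.
#' @param catalog the `variant_catalog` the ids refer to.
#' @return Integer vector of variant ids in rank order.
#' @export
rank_variants <- function(scores, catalog) {
  sc <- if (inherits(scores, "score_table")) scores$scores else scores
  v <- catalog$variants
  val <- unname(sc[as.character(v$id)])
  chrom_rank <- match(v$chrom, unique(v$chrom))
  v$id[order(-val, chrom_rank, v$pos)]
}

# tie-break key (chromosome rank, position) as a single ordering index
.tie_order <- function(catalog) {
  v <- catalog$variants
  chrom_rank <- match(v$chrom, unique(v$chrom))
  order(order(chrom_rank, v$pos))  # rank of each row under the tie-break
}

# --- lazy binary max-heap keyed by (score desc, tie-rank asc) -------------
# Scores only decrease during selection, so stale heap entries (pushed
# before a penalty) float to the top no earlier than their refreshed score
# warrants; on pop we compare against the current score and re-push if
# stale. Plain R vectors; sufficient for catalog-scale inputs.
.heap_new <- function(n) {
  e <- new.env(parent = emptyenv())
  e$score <- numeric(0); e$tie <- integer(0); e$row <- integer(0)
  e
}
.heap_less <- function(h, i, j) {  # TRUE if entry i has LOWER priority
  h$score[i] < h$score[j] ||
    (h$score[i] == h$score[j] && h$tie[i] > h$tie[j])
}
.heap_swap <- function(h, i, j) {
  tmp <- c(h$score[i], h$tie[i], h$row[i])
  h$score[i] <- h$score[j]; h$tie[i] <- h$tie[j]; h$row[i] <- h$row[j]
  h$score[j] <- tmp[1]; h$tie[j] <- tmp[2]; h$row[j] <- tmp[3]
}
.heap_push <- function(h, score, tie, row) {
  i <- length(h$score) + 1L
  h$score[i] <- score; h$tie[i] <- tie; h$row[i] <- row
  while (i > 1L) {
    par <- i %/% 2L
    if (.heap_less(h, par, i)) { .heap_swap(h, par, i); i <- par } else break
  }
}
.heap_pop <- function(h) {
  n <- length(h$score)
  top <- c(h$score[1], h$tie[1], h$row[1])
  h$score[1] <- h$score[n]; h$tie[1] <- h$tie[n]; h$row[1] <- h$row[n]
  h$score <- h$score[-n]; h$tie <- h$tie[-n]; h$row <- h$row[-n]
  n <- n - 1L; i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; big <- i
    if (l <= n && .heap_less(h, big, l)) big <- l
    if (r <= n && .heap_less(h, big, r)) big <- r
    if (big == i) break
    .heap_swap(h, i, big); i <- big
  }
  top
}

#' Greedy variant selection with blowup avoidance
#'
#' Repeatedly selects the variant with the maximum current score (ties by
#' [rank_variants()] order); after each selection, the current score of
#' every unselected variant within `s` nt (between start positions, same
#' chromosome, symmetric) is multiplied by the penalty `w`. Penalties
#' accumulate multiplicatively across multiple selected neighbors. With
#' `w = 1` the result equals the static top-`budget` prefix of the ranking;
#' `w = 0` is accepted as a diagnostic mode in which no neighbor of a
#' selected variant is chosen while any positive-score isolated variant
#' remains (zero-score candidates stay selectable afterwards, in tie-break
#' order). Implemented with a lazy priority heap; since penalties only ever
#' decrease scores, stale heap entries are safe to re-push on pop.
#'
#' @param scores a `score_table` or numeric vector named by variant id.
#' @param catalog the `variant_catalog`.
#' @param n number of variants to select (mutually exclusive with
#'   `fraction`).
#' @param fraction fraction of the catalog to select, in (0, 1]; rounded to
#'   the nearest integer, minimum 1 for a non-empty catalog.
#' @param w penalty factor in [0, 1] (see [model_config()]).
#' @param s penalty neighborhood radius in nt, typically the window size.
#' @return An object of class `selection_result`: list with `ordered_ids`
#'   (selection order), `final_scores`, `original_scores`, `n_penalties`
#'   (all named by id), `budget`, `w`, `s`.
#' @export
select_variants <- function(scores, catalog, n = NULL, fraction = NULL,
                            w = 0.5, s = 100L) {
  if (is.null(n) == is.null(fraction))
    stop("exactly one of n and fraction must be given")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  sc <- if (inherits(scores, "score_table")) scores$scores else scores
  v <- catalog$variants
  ncat <- nrow(v)
  budget <- if (!is.null(n)) min(as.integer(n), ncat) else {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    if (ncat == 0) 0L else max(1L, min(ncat, as.integer(round(fraction * ncat))))
  }
  cur <- unname(sc[as.character(v$id)])
  if (any(is.na(cur))) stop("missing score for some catalog variant")
  orig <- cur
  tie <- .tie_order(catalog)
  npen <- integer(ncat)
  selected <- logical(ncat)

  # neighbor lookup: rows within s nt on the same chromosome
  neighbors <- function(i) {
    same <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= s)
    setdiff(same, i)
  }

  h <- .heap_new(ncat)
  for (i in seq_len(ncat)) .heap_push(h, cur[i], tie[i], i)
  picked <- integer(0)
  while (length(picked) < budget && length(h$score) > 0) {
    top <- .heap_pop(h)
    i <- as.integer(top[3])
    if (selected[i]) next
    if (top[1] != cur[i]) { .heap_push(h, cur[i], tie[i], i); next }
    selected[i] <- TRUE
    picked <- c(picked, i)
    if (w < 1) {
      for (j in neighbors(i)) {
        if (!selected[j]) {
          cur[j] <- cur[j] * w
          npen[j] <- npen[j] + 1L
        }
      }
    }
  }
  ids <- as.character(v$id)
  structure(list(ordered_ids = v$id[picked],
                 final_scores = stats::setNames(cur, ids),
                 original_scores = stats::setNames(orig, ids),
                 n_penalties = stats::setNames(npen, ids),
                 budget = budget, w = w, s = as.integer(s)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$ordered_ids), "of", length(x$final_scores),
      "variant(s) selected (w =", x$w, ", s =", x$s, ")\n")
  invisible(x)
}

#' Per-variant selection report
#'
#' One row per selected variant, in selection order: selection rank, locus,
#' original score, final (possibly penalized) score, and the number of
#' penalties received before selection.
#'
#' @param result a [select_variants()] result.
#' @param catalog the `variant_catalog`.
#' @param out optional TSV output path.
#' @return The report data.frame (invisibly if `out` is given).
#' @export
selection_report <- function(result, catalog, out = NULL) {
  v <- catalog$variants
  idx <- match(result$ordered_ids, v$id)
  ids <- as.character(result$ordered_ids)
  df <- data.frame(rank = seq_along(idx),
                   chrom = v$chrom[idx], pos = v$pos[idx] + 1L,
                   ref = v$ref[idx], alt = v$alt[idx],
                   original_score = unname(result$original_scores[ids]),
                   final_score = unname(result$final_scores[ids]),
                   n_penalties = unname(result$n_penalties[ids]),
                   stringsAsFactors = FALSE)
  if (!is.null(out)) {
    dfw <- df
    dfw$original_score <- sprintf("%.12g", dfw$original_score)
    dfw$final_score <- sprintf("%.12g", dfw$final_score)
    utils::write.table(dfw, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write selected SNVs as a graph-aligner SNP list
#'
#' One line per selected SNV: id, the literal type `single`, chromosome,
#' 0-based position, ALT base — the common dialect accepted by
#' graph-genome indexers. Non-SNV selections are skipped.
#'
#' @param result a [select_variants()] result.
#' @param catalog the `variant_catalog`.
#' @param out output path.
#' @return `out`, invisibly.
#' @export
write_snp_list <- function(result, catalog, out) {
  v <- catalog$variants
  idx <- match(result$ordered_ids, v$id)
  idx <- idx[v$is_snv[idx]]
  lines <- sprintf("v%d\tsingle\t%s\t%d\t%s",
                   v$id[idx], v$chrom[idx], v$pos[idx], v$alt[idx])
  writeLines(lines, out)
  invisible(out)
}
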