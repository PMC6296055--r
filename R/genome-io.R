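#' Reference genome container
#'
#' A thin container holding named chromosome sequences over the alphabet
#' {A,C,G,T,N}. All internal coordinates in the package are 0-based,
#' half-open; conversion to/from 1-based happens only at the VCF/TSV
#' boundaries.
#'
#' @param chroms named character vector of uppercase sequences.
#' @return An object of class `ref_genome` with fields `chroms` (named
#'   character vector) and `lengths` (named integer vector).
#' @export
ref_genome <- function(chroms) {
  if (!is.character(chroms) || length(chroms) == 0)
    stop("reference must contain at least one sequence")
  nm <- names(chroms)
  if (is.null(nm) || any(nm == ""))
    stop("all reference sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1])
  if (any(nchar(chroms) == 0))
    stop("empty chromosome sequence: ", nm[nchar(chroms) == 0][1])
  structure(list(chroms = chroms, lengths = stats::setNames(nchar(chroms), nm)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$chroms), "sequence(s),",
      total_length(x), "bp total\n")
  invisible(x)
}

#' Total reference length
#' @param ref a [ref_genome].
#' @return integer, sum of chromosome lengths.
#' @export
total_length <- function(ref) sum(ref$lengths)

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masked lowercase becomes uppercase) and any
#' IUPAC ambiguity code other than A/C/G/T is stored as N. Record order is
#' preserved; record names are truncated at the first whitespace.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A [ref_genome].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  ref_genome(seqs)
}

#' Write a reference genome to FASTA
#' @param ref a [ref_genome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  dss <- Biostrings::DNAStringSet(ref$chroms)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Read a variant catalog from VCF
#'
#' Parses a VCF 4.x file into a catalog of biallelic records: each ALT of a
#' multi-allelic record becomes a separate record scored independently. ALT
#' frequencies come from the per-ALT `AF` INFO field, or, with
#' `use_gt = TRUE`, are computed as the fraction of ALT-carrying haplotypes
#' in the phased GT columns. Records whose REF allele disagrees with the
#' reference sequence are dropped with a warning (and counted), as are
#' symbolic ALTs and indels overlapping a previously kept record. Zero-AF
#' records are retained (they simply score 0).
#'
#' When phased GT columns are present, a haplotype panel (H x n 0/1 matrix,
#' one column per kept record) is extracted; any unphased ("/") genotype
#' disables the panel genome-wide with a warning.
#'
#' @param path path to a VCF file.
#' @param ref a [ref_genome] used to validate REF alleles.
#' @param use_gt compute allele frequencies from GT columns instead of the
#'   AF INFO field.
#' @return An object of class `variant_catalog`: list with `variants` (a
#'   data.frame with columns id, chrom, pos (0-based), ref, alt, af,
#'   source_line, alt_index, is_snv), `panel` (H x n matrix or NULL),
#'   `n_haplotypes`, `n_rejected`, and `source` (the input path).
#' @export
read_variants <- function(path, ref, use_gt = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # always a character matrix, one row per record
  if (is.null(fix) || nrow(fix) == 0) {
    return(structure(list(variants = .empty_variants(), panel = NULL,
                          n_haplotypes = 0L, n_rejected = 0L, source = path),
                     class = "variant_catalog"))
  }

  # haplotype alleles: one integer matrix (H x n_records), NA if no GT
  hap <- NULL
  phased <- FALSE
  if (ncol(vcf@gt) > 1) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (any(grepl("/", gt, fixed = TRUE))) {
      warning("unphased genotypes present; phasing disabled genome-wide")
    } else {
      parts <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
      plo <- lengths(parts)
      if (length(unique(plo)) != 1)
        stop("inconsistent ploidy in GT columns")
      al <- suppressWarnings(as.integer(unlist(parts)))
      # row i of hap = one haplotype; columns follow VCF record order
      hap <- matrix(al, ncol = nrow(fix))
      phased <- TRUE
    }
  }
  H <- if (phased) nrow(hap) else 0L

  af_info <- if (!use_gt) .info_field(fix[, "INFO"], "AF") else rep(NA_character_, nrow(fix))

  rows <- list()
  panel_cols <- list()
  n_rejected <- 0L
  kept_spans <- list()  # per chrom: matrix of (start, end) 0-based half-open, indel flag

  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos1 <- as.integer(fix[i, "POS"])
    refal <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    pos0 <- pos1 - 1L

    if (!chrom %in% names(ref$chroms)) {
      warning("record on unknown chromosome ", chrom, " rejected")
      n_rejected <- n_rejected + length(alts)
      next
    }
    obs <- substr(ref$chroms[[chrom]], pos1, pos1 + nchar(refal) - 1L)
    if (obs != refal) {
      warning("REF mismatch at ", chrom, ":", pos1, " (VCF ", refal,
              ", reference ", obs, "); record rejected")
      n_rejected <- n_rejected + length(alts)
      next
    }

    afs <- if (!use_gt) {
      v <- af_info[i]
      if (is.na(v)) {
        if (phased) rep(NA_real_, length(alts))  # recomputed from panel below
        else stop("record ", chrom, ":", pos1,
                  " has no AF INFO field and use_gt is not set")
      } else {
        as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
      }
    } else {
      if (!phased) stop("use_gt requires phased GT columns")
      rep(NA_real_, length(alts))
    }

    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (grepl("[<>\\[\\]]", alt)) {
        warning("symbolic ALT ", alt, " at ", chrom, ":", pos1, " rejected")
        n_rejected <- n_rejected + 1L
        next
      }
      is_snv <- nchar(refal) == 1L && nchar(alt) == 1L
      span <- c(pos0, pos0 + nchar(refal))
      if (!is_snv && .overlaps_kept(kept_spans[[chrom]], span)) {
        warning("overlapping indel at ", chrom, ":", pos1, " rejected")
        n_rejected <- n_rejected + 1L
        next
      }
      if (is_snv && .overlaps_kept_indel(kept_spans[[chrom]], span)) {
        warning("record at ", chrom, ":", pos1,
                " overlaps a kept indel; rejected")
        n_rejected <- n_rejected + 1L
        next
      }
      af <- afs[j]
      col <- NULL
      if (phased) {
        col <- as.integer(hap[, i] == j)
        if (is.na(af)) af <- mean(col)
      }
      if (is.na(af)) stop("no AF available at ", chrom, ":", pos1)
      if (af < 0 || af > 1) stop("AF out of [0,1] at ", chrom, ":", pos1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos0, ref = refal, alt = alt, af = af,
        source_line = i, alt_index = j, is_snv = is_snv,
        stringsAsFactors = FALSE)
      if (phased) panel_cols[[length(panel_cols) + 1L]] <- col
      kept_spans[[chrom]] <- rbind(kept_spans[[chrom]],
                                   c(span, as.integer(!is_snv)))
    }
  }

  if (length(rows) == 0) {
    variants <- .empty_variants()
    panel <- NULL
  } else {
    variants <- do.call(rbind, rows)
    rownames(variants) <- NULL
    variants$id <- seq_len(nrow(variants))
    variants <- variants[, c("id", "chrom", "pos", "ref", "alt", "af",
                             "source_line", "alt_index", "is_snv")]
    panel <- if (phased) do.call(cbind, panel_cols) else NULL
    if (!is.null(panel)) colnames(panel) <- variants$id
  }
  structure(list(variants = variants, panel = panel,
                 n_haplotypes = H, n_rejected = n_rejected, source = path),
            class = "variant_catalog")
}

.empty_variants <- function() {
  data.frame(id = integer(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), af = numeric(),
             source_line = integer(), alt_index = integer(),
             is_snv = logical(), stringsAsFactors = FALSE)
}

.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

.overlaps_kept <- function(spans, span) {
  if (is.null(spans)) return(FALSE)
  any(spans[, 1] < span[2] & spans[, 2] > span[1])
}

.overlaps_kept_indel <- function(spans, span) {
  if (is.null(spans)) return(FALSE)
  idx <- spans[, 3] == 1L
  any(spans[idx, 1] < span[2] & spans[idx, 2] > span[1])
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("variant_catalog:", nrow(x$variants), "record(s)",
      if (!is.null(x$panel)) sprintf("(phased, H=%d)", x$n_haplotypes) else "(no panel)",
      "\n")
  invisible(x)
}

#' Write the selected subset of a VCF
#'
#' Emits a valid VCF containing exactly the selected records in original
#' (chromosome, position) order. A multi-allelic source record is re-emitted
#' verbatim only if all of its ALTs were selected; otherwise one body line
#' per selected ALT is written with the ALT and per-ALT AF INFO value
#' subset accordingly. The source header is copied unchanged.
#'
#' @param selection a [select_variants()] result (or an integer vector of
#'   catalog ids).
#' @param catalog the `variant_catalog` the ids refer to.
#' @param source path to the VCF the catalog was read from.
#' @param out output VCF path.
#' @return `out`, invisibly.
#' @export
write_selected_vcf <- function(selection, catalog, source, out) {
  ids <- if (inherits(selection, "selection_result")) selection$ordered_ids else selection
  v <- catalog$variants
  if (!all(ids %in% v$id)) stop("selection contains unknown variant id(s)")
  lines <- readLines(source)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  sel <- v[match(ids, v$id), , drop = FALSE]

  out_lines <- character()
  for (li in sort(unique(sel$source_line))) {
    here <- sel[sel$source_line == li, , drop = FALSE]
    all_alts <- v[v$source_line == li, , drop = FALSE]  # kept alts of that line
    fields <- strsplit(body[li], "\t", fixed = TRUE)[[1]]
    n_source_alts <- length(strsplit(fields[5], ",", fixed = TRUE)[[1]])
    if (nrow(here) == n_source_alts) {
      out_lines <- c(out_lines, body[li])
    } else {
      for (k in order(here$alt_index)) {
        f <- fields
        f[5] <- here$alt[k]
        f[8] <- .subset_af_info(fields[8], here$alt_index[k])
        out_lines <- c(out_lines, paste(f, collapse = "\t"))
      }
    }
  }
  writeLines(c(lines[hdr], out_lines), out)
  invisible(out)
}

.subset_af_info <- function(info, alt_index) {
  af <- .info_field(info, "AF")
  if (is.na(af)) return(info)
  one <- strsplit(af, ",", fixed = TRUE)[[1]][alt_index]
  sub("(^|;)AF=[^;]*", paste0("\\1AF=", one), info)
}

#' Write a per-variant score table as TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, alt_freq, score; rows ordered by
#' chromosome (reference order), position, then ALT allele. Scores are
#' written with 12 significant digits so a round-trip through
#' [read_scores()] is lossless at that precision.
#'
#' @param scores a `score_table` from [score_pop_cov()] / [score_hybrid()],
#'   or a numeric vector named by catalog id.
#' @param catalog the `variant_catalog` scored.
#' @param out output TSV path.
#' @return `out`, invisibly.
#' @export
write_scores <- function(scores, catalog, out) {
  sc <- if (inherits(scores, "score_table")) scores$scores else scores
  v <- catalog$variants
  val <- unname(sc[as.character(v$id)])
  if (any(!is.finite(val))) stop("non-finite score for variant id ",
                                 v$id[which(!is.finite(val))[1]])
  chrom_rank <- match(v$chrom, unique(v$chrom))
  o <- order(chrom_rank, v$pos, v$alt)
  df <- data.frame(chrom = v$chrom[o], pos = v$pos[o] + 1L,
                   ref = v$ref[o], alt = v$alt[o],
                   alt_freq = sprintf("%.12g", v$af[o]),
                   score = sprintf("%.12g", val[o]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a score table written by [write_scores()]
#' @param path TSV path.
#' @return data.frame with columns chrom, pos (1-based), ref, alt, alt_freq,
#'   score.
#' @export
read_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character", "numeric", "numeric"),
                    stringsAsFactors = FALSE)
}
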