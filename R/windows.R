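# Junction windows and GC metrics.
#
# A junction window is the sense-strand sequence of length 2*flank + 1
# centered on the junction base (the first intronic base for donors, the
# last intronic base for acceptors). In sense orientation the exonic half
# sits LEFT of center for donors and RIGHT of center for acceptors. The
# center (junction) base is intronic under both conventions and is counted
# with the intronic half. Windows are cut from raw genomic sequence and may
# run past annotated feature boundaries.

# 1-based substring of a genomic span [start0, end0) with strand handling
.extract_span <- function(chrom_seq, start0, end0, strand) {
  s <- substr(chrom_seq, start0 + 1L, end0)
  if (strand == "-") revcomp(s) else s
}

#' Extract the junction window for a single splice site
#'
#' @param genome genome (named character vector, `DNAStringSet`, or FASTA
#'   path; see [as_genome()]).
#' @param site one-row splice-site `data.frame` (needs `seqname, strand,
#'   side, junction_pos`).
#' @param flank bases added on each side of the junction base (default 70,
#'   i.e. a 141-nt window; 30 gives the 61-nt variant).
#' @return one-row `data.frame` with `sequence`, `exonic_half`,
#'   `intronic_half`, `gc_number`, `gc_fraction`, `gc_exonic`,
#'   `gc_intronic` joined to the site columns.
#' @export
extract_window <- function(genome, site, flank = 70L) {
  out <- extract_windows(genome, site, flank = flank, warn_oob = FALSE)
  if (nrow(out) == 0) stop("window out of sequence bounds")
  out
}

#' Extract junction windows for a table of splice sites
#'
#' Batch variant of [extract_window()]: sites whose window would run past
#' the sequence ends are dropped with a warning.
#'
#' @inheritParams extract_window
#' @param sites splice-site `data.frame`.
#' @param warn_oob warn about dropped out-of-bounds sites.
#' @return `data.frame`: input site columns plus window sequence and GC
#'   metrics, one row per retained site.
#' @export
extract_windows <- function(genome, sites, flank = 70L, warn_oob = TRUE) {
  genome <- as_genome(genome)
  stopifnot(flank >= 1L)
  flank <- as.integer(flank)
  n <- nrow(sites)
  keep <- logical(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chrom <- sites$seqname[i]
    if (!chrom %in% names(genome)) next
    jp <- sites$junction_pos[i]
    start0 <- jp - flank
    end0 <- jp + flank + 1L
    if (start0 < 0L || end0 > nchar(genome[[chrom]])) next
    seqs[i] <- .extract_span(genome[[chrom]], start0, end0, sites$strand[i])
    keep[i] <- TRUE
  }
  if (warn_oob && any(!keep)) {
    warning(sum(!keep), " site(s) dropped: window out of sequence bounds")
  }
  out <- sites[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  out <- cbind(out, .window_gc_metrics(out$sequence, out$side, flank))
  rownames(out) <- NULL
  attr(out, "flank") <- flank
  out
}

# GC metrics for sense-strand windows; exonic half is left of center for
# donors and right of center for acceptors; center base goes with the
# intronic half
.window_gc_metrics <- function(sequences, sides, flank) {
  L <- 2L * flank + 1L
  exonic <- character(length(sequences))
  intronic <- character(length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (nchar(s) != L) stop("window length != 2*flank+1")
    if (sides[i] == "donor") {
      exonic[i] <- substr(s, 1L, flank)
      intronic[i] <- substr(s, flank + 1L, L)
    } else {
      intronic[i] <- substr(s, 1L, flank + 1L)
      exonic[i] <- substr(s, flank + 2L, L)
    }
  }
  gc_ex <- vapply(exonic, gc_count, integer(1), USE.NAMES = FALSE)
  gc_in <- vapply(intronic, gc_count, integer(1), USE.NAMES = FALSE)
  data.frame(
    exonic_half = exonic,
    intronic_half = intronic,
    gc_number = gc_ex + gc_in,
    gc_fraction = (gc_ex + gc_in) / L,
    gc_exonic = gc_ex / flank,
    gc_intronic = gc_in / (flank + 1L),
    stringsAsFactors = FALSE
  )
}

#' Recompute GC metrics for window sequences
#'
#' Validates the alphabet and (re)populates `gc_number`, `gc_fraction`,
#' `gc_exonic`, `gc_intronic` on a window table.
#'
#' @param windows window `data.frame` with `sequence` and `side` columns.
#' @param flank window flank; taken from the table attribute if absent.
#' @return the updated window table.
#' @export
gc_metrics <- function(windows, flank = NULL) {
  if (is.null(flank)) flank <- attr(windows, "flank")
  if (is.null(flank)) flank <- (nchar(windows$sequence[1]) - 1L) %/% 2L
  for (s in windows$sequence) normalize_seq(s)
  m <- .window_gc_metrics(windows$sequence, windows$side, as.integer(flank))
  for (col in names(m)) windows[[col]] <- m[[col]]
  attr(windows, "flank") <- as.integer(flank)
  windows
}

#' Per-position mean GC profile of aligned windows
#'
#' Windows are aligned on the junction; offsets are negative on the exonic
#' side, 0 at the junction base, positive on the intronic side. All windows
#' must share `flank` and `side`.
#'
#' @param windows window `data.frame` (from [extract_windows()] or the
#'   synthetic cohort generator).
#' @param flank window flank (recovered from the table if `NULL`).
#' @return `data.frame` with `offset`, `mean_gc`, `n`.
#' @export
positional_gc_profile <- function(windows, flank = NULL) {
  if (nrow(windows) == 0) stop("no windows")
  if (is.null(flank)) flank <- attr(windows, "flank")
  if (is.null(flank)) flank <- (nchar(windows$sequence[1]) - 1L) %/% 2L
  flank <- as.integer(flank)
  side <- unique(windows$side)
  if (length(side) != 1) stop("all windows must share the same side")
  L <- 2L * flank + 1L
  mat <- vapply(windows$sequence, function(s) {
    ch <- seq_chars(toupper(s))
    as.numeric(ch == "G" | ch == "C")
  }, numeric(L), USE.NAMES = FALSE)
  mean_gc <- rowMeans(mat)
  pos <- seq_len(L)
  offset <- if (side == "donor") pos - (flank + 1L) else (flank + 1L) - pos
  out <- data.frame(offset = offset, mean_gc = mean_gc, n = nrow(windows))
  out[order(out$offset), ]
}

#' Junction-proximal GC normalized by the wider exonic region
#'
#' GC fraction of the 50-bp exonic region adjacent to the junction divided
#' by the GC fraction of the 100-bp exonic region from the junction. Sites
#' whose regions run out of bounds, or with a zero denominator, yield `NA`
#' with a warning.
#'
#' @param genome genome (see [as_genome()]).
#' @param sites splice-site `data.frame` (real or decoy records).
#' @param near,wide region widths in bp.
#' @return numeric vector of ratios, one per site (`NA` where undefined).
#' @export
normalized_junction_gc <- function(genome, sites, near = 50L, wide = 100L) {
  genome <- as_genome(genome)
  n <- nrow(sites)
  out <- rep(NA_real_, n)
  dropped <- 0L
  for (i in seq_len(n)) {
    chrom <- sites$seqname[i]
    jp <- sites$junction_pos[i]
    strand <- sites$strand[i]
    side <- sites$side[i]
    # genomic direction of the exon from the junction
    exon_right <- (side == "acceptor") == (strand == "+")
    if (exon_right) {
      near_span <- c(jp + 1L, jp + 1L + near)
      wide_span <- c(jp + 1L, jp + 1L + wide)
    } else {
      near_span <- c(jp - near, jp)
      wide_span <- c(jp - wide, jp)
    }
    if (!chrom %in% names(genome) || wide_span[1] < 0L ||
        wide_span[2] > nchar(genome[[chrom]])) {
      dropped <- dropped + 1L
      next
    }
    near_seq <- .extract_span(genome[[chrom]], near_span[1], near_span[2], "+")
    wide_seq <- .extract_span(genome[[chrom]], wide_span[1], wide_span[2], "+")
    num <- gc_count(near_seq) / near
    den <- gc_count(wide_seq) / wide
    if (den == 0) {
      dropped <- dropped + 1L
      next
    }
    out[i] <- num / den
  }
  if (dropped > 0) {
    warning(dropped, " site(s) dropped in normalized_junction_gc")
  }
  out
}

#' Write a window table to TSV
#' @param windows window `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  cols <- intersect(c("seqname", "strand", "side", "junction_pos",
                      "category", "gene_id", "sequence", "gc_number",
                      "gc_fraction", "gc_exonic", "gc_intronic"),
                    names(windows))
  write.table(windows[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
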