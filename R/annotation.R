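# Transcript models and splice-site categorization.
#
# Internal coordinates are 0-based half-open (BED-native); all exported
# tables report 1-based inclusive positions. Junction convention: a donor's
# junction_pos is the genomic coordinate of the FIRST intronic base, an
# acceptor's the LAST intronic base (0-based). This pins the GT/AG
# consensus dinucleotide deterministically relative to the record.

#' Load transcript models from GTF or BED12
#'
#' Parses exon features into a flat exon table (one row per exon), the
#' package's transcript-model representation. GTF requires `gene_id` and
#' `transcript_id` attributes on exon features. BED12 has no gene field:
#' a `name` of the form `"gene|transcript"` is split on the bar, otherwise
#' `gene_id = name`.
#'
#' @param path file path.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return a `data.frame` of class `transcript_models` with columns
#'   `seqname, strand, start, end` (0-based half-open), `gene_id`,
#'   `transcript_id`, sorted 5'-to-3' in genomic coordinates within each
#'   transcript.
#' @export
load_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gtf") {
    content <- readLines(path, warn = FALSE)
    if (!any(nzchar(content) & !startsWith(content, "#"))) {
      warning("no exon records in ", path)
      return(empty_transcript_models())
    }
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("GTF parse error: ",
                                            conditionMessage(e)))
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
    if (length(gr) == 0) {
      warning("no exon records in ", path)
      return(empty_transcript_models())
    }
    df <- data.frame(
      seqname = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("BED12 parse error: ",
                                            conditionMessage(e)))
    if (length(gr) == 0) {
      warning("no records in ", path)
      return(empty_transcript_models())
    }
    blocks <- rtracklayer::blocks(gr)
    nm <- if (!is.null(gr$name)) gr$name else paste0("tx", seq_along(gr))
    pieces <- strsplit(nm, "|", fixed = TRUE)
    gene <- vapply(pieces, `[`, character(1), 1L)
    tx <- vapply(pieces, function(p) if (length(p) > 1) p[2] else p[1],
                 character(1))
    reps <- S4Vectors::elementNROWS(blocks)
    flat <- unlist(blocks, use.names = FALSE)
    df <- data.frame(
      seqname = rep(as.character(GenomicRanges::seqnames(gr)), reps),
      strand = rep(as.character(GenomicRanges::strand(gr)), reps),
      start = GenomicRanges::start(flat) - 1L,
      end = GenomicRanges::end(flat),
      gene_id = rep(gene, reps),
      transcript_id = rep(tx, reps),
      stringsAsFactors = FALSE
    )
  }
  as_transcript_models(df)
}

empty_transcript_models <- function() {
  as_transcript_models(data.frame(
    seqname = character(0), strand = character(0),
    start = integer(0), end = integer(0),
    gene_id = character(0), transcript_id = character(0),
    stringsAsFactors = FALSE
  ), validate = FALSE)
}

#' Construct/validate a transcript-model exon table
#'
#' @param df data.frame with columns `seqname, strand, start, end,
#'   gene_id, transcript_id` (0-based half-open exons).
#' @param validate check exon invariants (non-overlap within transcript,
#'   consistent seqname/strand).
#' @return the sorted table with class `transcript_models`.
#' @export
as_transcript_models <- function(df, validate = TRUE) {
  need <- c("seqname", "strand", "start", "end", "gene_id", "transcript_id")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[order(df$gene_id, df$transcript_id, df$start, df$end), need,
           drop = FALSE]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  if (validate && nrow(df) > 0) {
    if (any(df$end <= df$start)) stop("exon with end <= start")
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    for (tx in split(df, df$transcript_id)) {
      if (length(unique(tx$seqname)) > 1 || length(unique(tx$strand)) > 1) {
        stop("transcript ", tx$transcript_id[1],
             " mixes seqnames or strands")
      }
      if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
        stop("transcript ", tx$transcript_id[1], " has overlapping exons")
      }
    }
  }
  class(df) <- c("transcript_models", "data.frame")
  df
}

# split a single-gene exon table into per-isoform exon data.frames,
# each sorted by genomic start
.isoforms <- function(gene_df) {
  lapply(split(seq_len(nrow(gene_df)), gene_df$transcript_id), function(idx) {
    iso <- gene_df[idx, , drop = FALSE]
    iso[order(iso$start), , drop = FALSE]
  })
}

# genomic junction positions for an exon on a strand (0-based):
# donor = first intronic base downstream of the exon in the direction of
# transcription; acceptor = last intronic base upstream of the exon
.exon_junctions <- function(start, end, strand) {
  if (strand == "+") {
    list(donor = end, acceptor = start - 1L)
  } else {
    list(donor = start - 1L, acceptor = end)
  }
}

.site_row <- function(seqname, strand, side, junction_pos, category,
                      gene_id, exon_start, exon_end,
                      long_threshold = 200L) {
  len <- exon_end - exon_start
  data.frame(
    seqname = seqname, strand = strand, side = side,
    junction_pos = as.integer(junction_pos), category = category,
    gene_id = gene_id, exon_start = as.integer(exon_start),
    exon_end = as.integer(exon_end), exon_length = as.integer(len),
    exon_length_class = exon_length_class(len, long_threshold),
    stringsAsFactors = FALSE
  )
}

empty_sites <- function() {
  data.frame(seqname = character(0), strand = character(0),
             side = character(0), junction_pos = integer(0),
             category = character(0), gene_id = character(0),
             exon_start = integer(0), exon_end = integer(0),
             exon_length = integer(0), exon_length_class = character(0),
             stringsAsFactors = FALSE)
}

.dedup_sites <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$seqname, sites$strand, sites$side, sites$junction_pos,
               sites$category)
  out <- sites[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exon length class
#'
#' Long exons are those strictly longer than the threshold (default 200 bp).
#' @param length exon length(s) in bp.
#' @param long_threshold class boundary.
#' @return `"long"` or `"short"` per element.
#' @export
exon_length_class <- function(length, long_threshold = 200L) {
  ifelse(length > long_threshold, "long", "short")
}

# helper: is exon (start,end) internal (neither first nor last) in isoform?
.internal_rank <- function(iso, start, end) {
  hit <- which(iso$start == start & iso$end == end)
  if (length(hit) == 0) return(NA)
  hit > 1 & hit < nrow(iso)
}

#' Constitutive splice sites of one gene
#'
#' An internal exon is constitutive when it appears with identical start and
#' end as an internal exon in every isoform of the gene that has at least
#' three exons, overlaps no other distinct exon of the gene, and the gene
#' has at least `min_isoforms` (default 4) isoforms. Both its donor and
#' acceptor are reported.
#'
#' @param gene_models `transcript_models` rows of a single gene.
#' @param min_isoforms minimum isoform count for the gene.
#' @return splice-site `data.frame` (possibly empty).
#' @export
find_constitutive_sites <- function(gene_models, min_isoforms = 4L) {
  isos <- .isoforms(gene_models)
  if (length(isos) < min_isoforms) return(empty_sites())
  iso3 <- isos[vapply(isos, nrow, integer(1)) >= 3L]
  if (length(iso3) == 0) return(empty_sites())
  all_exons <- unique(gene_models[, c("start", "end")])
  first <- iso3[[1]]
  out <- list()
  for (m in seq_len(nrow(first))[-c(1, nrow(first))]) {
    s <- first$start[m]; e <- first$end[m]
    internal_everywhere <- all(vapply(iso3, function(iso) {
      r <- .internal_rank(iso, s, e)
      isTRUE(r)
    }, logical(1)))
    if (!internal_everywhere) next
    others <- all_exons[!(all_exons$start == s & all_exons$end == e), ,
                        drop = FALSE]
    if (any(others$start < e & others$end > s)) next
    j <- .exon_junctions(s, e, first$strand[1])
    out[[length(out) + 1]] <- rbind(
      .site_row(first$seqname[1], first$strand[1], "donor", j$donor,
                "constitutive", first$gene_id[1], s, e),
      .site_row(first$seqname[1], first$strand[1], "acceptor", j$acceptor,
                "constitutive", first$gene_id[1], s, e)
    )
  }
  if (length(out) == 0) return(empty_sites())
  .dedup_sites(do.call(rbind, out))
}

#' Alternative splice sites of one gene
#'
#' Internal exons that share one boundary but differ at the other define
#' competing splice sites; all variants are reported, subject to the
#' minimum-distance filters: at least `min_acceptor_dist` (default 8) bp
#' between two acceptors of the same exon and at least `min_donor_dist`
#' (default 5) bp between two donors. A variant group in which any pair of
#' sites violates the filter is dropped entirely.
#'
#' @param gene_models `transcript_models` rows of a single gene.
#' @param min_donor_dist,min_acceptor_dist distance filters in bp.
#' @return splice-site `data.frame`.
#' @export
find_alternative_sites <- function(gene_models, min_donor_dist = 5L,
                                   min_acceptor_dist = 8L) {
  isos <- .isoforms(gene_models)
  strand <- gene_models$strand[1]
  # internal exons across isoforms (unique coordinates)
  internal <- list()
  for (iso in isos) {
    if (nrow(iso) < 3) next
    for (m in 2:(nrow(iso) - 1)) {
      internal[[paste(iso$start[m], iso$end[m])]] <-
        c(iso$start[m], iso$end[m])
    }
  }
  if (length(internal) == 0) return(empty_sites())
  ex <- do.call(rbind, internal)
  colnames(ex) <- c("start", "end")
  ex <- as.data.frame(ex)
  gene_id <- gene_models$gene_id[1]
  seqname <- gene_models$seqname[1]
  out <- list()
  emit_group <- function(rows, side, min_dist) {
    jp <- vapply(seq_len(nrow(rows)), function(r) {
      .exon_junctions(rows$start[r], rows$end[r], strand)[[side]]
    }, integer(1))
    keep <- !duplicated(jp)
    rows <- rows[keep, , drop = FALSE]
    jp <- jp[keep]
    if (length(jp) < 2) return(NULL)
    d <- abs(outer(jp, jp, "-"))
    if (min(d[upper.tri(d)]) < min_dist) return(NULL)
    do.call(rbind, lapply(seq_along(jp), function(r) {
      .site_row(seqname, strand, side, jp[r], "alternative", gene_id,
                rows$start[r], rows$end[r])
    }))
  }
  # donors vary, acceptor shared: group by the acceptor-side boundary
  acc_key <- if (strand == "+") ex$start else ex$end
  for (g in split(ex, acc_key)) {
    out[[length(out) + 1]] <- emit_group(g, "donor", min_donor_dist)
  }
  # acceptors vary, donor shared
  don_key <- if (strand == "+") ex$end else ex$start
  for (g in split(ex, don_key)) {
    out[[length(out) + 1]] <- emit_group(g, "acceptor", min_acceptor_dist)
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) return(empty_sites())
  .dedup_sites(do.call(rbind, out))
}

#' Skipped (cassette-exon) splice sites of one gene
#'
#' An internal exon is a cassette exon when some other isoform retains both
#' of its flanking exons (identical coordinates) while containing no exon
#' overlapping the candidate region. Both boundaries of the cassette exon
#' are reported as skipped splice sites.
#'
#' @param gene_models `transcript_models` rows of a single gene.
#' @return splice-site `data.frame`.
#' @export
find_skipped_sites <- function(gene_models) {
  isos <- .isoforms(gene_models)
  if (length(isos) < 2) return(empty_sites())
  out <- list()
  for (ii in seq_along(isos)) {
    iso <- isos[[ii]]
    if (nrow(iso) < 3) next
    for (m in 2:(nrow(iso) - 1)) {
      s <- iso$start[m]; e <- iso$end[m]
      ps <- iso$start[m - 1]; pe <- iso$end[m - 1]
      ns <- iso$start[m + 1]; ne <- iso$end[m + 1]
      skipped <- FALSE
      for (jj in seq_along(isos)) {
        if (jj == ii) next
        other <- isos[[jj]]
        has_prev <- any(other$start == ps & other$end == pe)
        has_next <- any(other$start == ns & other$end == ne)
        overlaps <- any(other$start < e & other$end > s)
        if (has_prev && has_next && !overlaps) {
          skipped <- TRUE
          break
        }
      }
      if (skipped) {
        j <- .exon_junctions(s, e, iso$strand[1])
        out[[length(out) + 1]] <- rbind(
          .site_row(iso$seqname[1], iso$strand[1], "donor", j$donor,
                    "skipped", iso$gene_id[1], s, e),
          .site_row(iso$seqname[1], iso$strand[1], "acceptor", j$acceptor,
                    "skipped", iso$gene_id[1], s, e)
        )
      }
    }
  }
  if (length(out) == 0) return(empty_sites())
  .dedup_sites(do.call(rbind, out))
}

#' First-exon donor sites of one gene
#'
#' Considers genes whose isoforms (at least `min_isoforms`, each with at
#' least three exons) all share the same transcription start site. The
#' donor of the first exon is `first_constitutive` when identical across
#' all such isoforms and `first_alternative` otherwise (each distinct
#' variant reported).
#'
#' @param gene_models `transcript_models` rows of a single gene.
#' @param min_isoforms minimum number of (>= 3 exon) isoforms.
#' @return splice-site `data.frame`.
#' @export
classify_first_donor_sites <- function(gene_models, min_isoforms = 3L) {
  isos <- .isoforms(gene_models)
  iso3 <- isos[vapply(isos, nrow, integer(1)) >= 3L]
  if (length(iso3) < min_isoforms) return(empty_sites())
  strand <- gene_models$strand[1]
  tss <- vapply(iso3, function(iso) {
    if (strand == "+") iso$start[1] else iso$end[nrow(iso)]
  }, integer(1))
  if (length(unique(tss)) > 1) return(empty_sites())
  firsts <- lapply(iso3, function(iso) {
    if (strand == "+") iso[1, , drop = FALSE] else iso[nrow(iso), , drop = FALSE]
  })
  donors <- vapply(firsts, function(fx) {
    .exon_junctions(fx$start, fx$end, strand)$donor
  }, integer(1))
  category <- if (length(unique(donors)) == 1) "first_constitutive"
              else "first_alternative"
  keep <- !duplicated(donors)
  out <- do.call(rbind, lapply(which(keep), function(r) {
    fx <- firsts[[r]]
    .site_row(fx$seqname, fx$strand, "donor", donors[r], category,
              fx$gene_id, fx$start, fx$end)
  }))
  .dedup_sites(out)
}

#' Classify all splice sites of an annotation
#'
#' Runs the per-category classifiers gene by gene and concatenates their
#' independent lists (a site may legitimately appear in more than one
#' category; overlaps are reported, not resolved).
#'
#' @param models a `transcript_models` table.
#' @param min_isoforms_constitutive,min_isoforms_first,min_donor_dist,min_acceptor_dist
#'   classifier parameters (see the per-category functions).
#' @return splice-site `data.frame` with a `category` column covering
#'   `alternative`, `constitutive`, `skipped`, `first_alternative`,
#'   `first_constitutive`.
#' @export
classify_splice_sites <- function(models, min_isoforms_constitutive = 4L,
                                  min_isoforms_first = 3L,
                                  min_donor_dist = 5L,
                                  min_acceptor_dist = 8L) {
  out <- lapply(split(models, models$gene_id), function(g) {
    g <- as_transcript_models(as.data.frame(g), validate = FALSE)
    rbind(
      find_constitutive_sites(g, min_isoforms_constitutive),
      find_alternative_sites(g, min_donor_dist, min_acceptor_dist),
      find_skipped_sites(g),
      classify_first_donor_sites(g, min_isoforms_first)
    )
  })
  res <- do.call(rbind, c(out, list(empty_sites())))
  rownames(res) <- NULL
  res
}

#' Write a splice-site table (1-based positions) to TSV
#' @param sites splice-site `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  out$junction_pos_1based <- out$junction_pos + 1L
  out$junction_pos <- NULL
  cols <- c("seqname", "strand", "side", "junction_pos_1based", "category",
            "gene_id", "exon_length", "exon_length_class")
  write.table(out[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
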