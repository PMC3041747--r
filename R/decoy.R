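# Splice-site strength scoring and decoy-site selection.
#
# Scorer: a position log-odds (weight matrix) model over the conventional
# site windows: donors score a 9-mer (3 exonic + 6 intronic bases, the
# intronic part starting with GT), acceptors a 23-mer (20 intronic bases
# ending with AG + 3 exonic). Scores are sums of per-position
# log2(foreground/background) weights, in bits; 0 means
# background-indistinguishable. Decoys are GT/AG dinucleotides in the
# intron flanking the real site, 150-300 nt from the real junction, scoring
# at least the threshold; the nearest qualifier wins.

#' Site window definition for a side
#' @param side `"donor"` or `"acceptor"`.
#' @return list with `exonic`, `intronic`, `width` (bases) and the 1-based
#'   positions of the consensus dinucleotide within the window.
#' @export
site_window_def <- function(side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (side == "donor") {
    list(side = side, exonic = 3L, intronic = 6L, width = 9L,
         dinuc_at = c(4L, 5L), dinuc = "GT")
  } else {
    list(side = side, exonic = 3L, intronic = 20L, width = 23L,
         dinuc_at = c(19L, 20L), dinuc = "AG")
  }
}

#' Extract the scoring window sequence of a splice site
#'
#' Sense-strand: donors yield (last 3 exonic) + (first 6 intronic) bases;
#' acceptors (last 20 intronic) + (first 3 exonic).
#'
#' @param genome genome (see [as_genome()]).
#' @param sites splice-site `data.frame`.
#' @return character vector of window sequences (`NA` if out of bounds).
#' @export
extract_site_sequence <- function(genome, sites) {
  genome <- as_genome(genome)
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    chrom <- sites$seqname[i]
    if (!chrom %in% names(genome)) next
    jp <- sites$junction_pos[i]
    strand <- sites$strand[i]
    side <- sites$side[i]
    def <- site_window_def(side)
    # span in sense coordinates around the junction base
    if (side == "donor") {
      # junction base = first intronic: 3 exonic before, 6 intronic from jp
      upstream <- def$exonic; downstream <- def$intronic
    } else {
      # junction base = last intronic: 19 intronic before, 3 exonic after
      upstream <- def$intronic - 1L; downstream <- def$exonic + 1L
    }
    if (strand == "+") {
      span <- c(jp - upstream, jp + downstream)
    } else {
      span <- c(jp - downstream + 1L, jp + upstream + 1L)
    }
    if (span[1] < 0L || span[2] > nchar(genome[[chrom]])) next
    out[i] <- .extract_span(genome[[chrom]], span[1], span[2], strand)
  }
  out
}

#' Train a position log-odds splice-site scoring model
#'
#' @param sequences aligned site sequences (all of the side's window
#'   width; at least `min_n`).
#' @param side `"donor"` or `"acceptor"`.
#' @param pseudocount added per position and nucleotide.
#' @param min_n minimum training-set size.
#' @return object of class `site_model`: per-position x nucleotide weights
#'   (bits), foreground probabilities, background frequencies.
#' @export
train_site_model <- function(sequences, side = c("donor", "acceptor"),
                             pseudocount = 0.5, min_n = 50L) {
  side <- match.arg(side)
  def <- site_window_def(side)
  sequences <- toupper(chartr("U", "T", sequences))
  sequences <- sequences[!is.na(sequences)]
  if (length(sequences) < min_n) {
    stop("need at least ", min_n, " training sequences, got ",
         length(sequences))
  }
  if (any(nchar(sequences) != def$width)) {
    stop("training sequences must all have width ", def$width)
  }
  stopifnot(pseudocount > 0)
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- sapply(seq_len(def$width), function(p) {
    vapply(bases, function(b) sum(mat[, p] == b), numeric(1))
  })  # 4 x width
  fg <- (counts + pseudocount)
  fg <- sweep(fg, 2, colSums(fg), "/")
  bg_counts <- rowSums(counts) + pseudocount
  bg <- bg_counts / sum(bg_counts)
  weights <- log2(fg / bg)
  dimnames(weights) <- list(bases, NULL)
  structure(list(side = side, window_def = def, weights = weights,
                 foreground = fg, background = bg,
                 pseudocount = pseudocount, n_train = length(sequences)),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat("<site_model>", x$side, "width", x$window_def$width,
      "trained on", x$n_train, "sequences\n")
  invisible(x)
}

#' Score a site sequence (bits)
#'
#' Sum over positions of the trained log-odds weights. Higher scores mean
#' greater similarity to the training consensus.
#'
#' @param model a `site_model`.
#' @param sequences character vector of window-width sequences.
#' @return numeric scores in bits (`NA` propagates; `N` scores as the
#'   background-expected 0 at that position).
#' @export
score_site <- function(model, sequences) {
  stopifnot(inherits(model, "site_model"))
  w <- model$window_def$width
  vapply(sequences, function(s) {
    if (is.na(s)) return(NA_real_)
    s <- toupper(chartr("U", "T", s))
    if (nchar(s) != w) stop("sequence length must be ", w)
    ch <- seq_chars(s)
    sum(vapply(seq_len(w), function(p) {
      if (ch[p] == "N") return(0)
      model$weights[ch[p], p]
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Serialize a site scoring model to a plain-text file
#'
#' Format: `# key value` header lines (side, pseudocount, n_train,
#' background frequencies), then a TSV matrix of per-position log-odds
#' weights (rows A/C/G/T, one column per window position).
#'
#' @param model a `site_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_model <- function(model, path) {
  stopifnot(inherits(model, "site_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# side", model$side),
    paste("# pseudocount", model$pseudocount),
    paste("# n_train", model$n_train),
    paste("# background", paste(signif(model$background, 10),
                                collapse = " "))
  ), con)
  write.table(model$weights, con, sep = "\t", quote = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a site scoring model written by [write_site_model()]
#' @param path input path.
#' @return a `site_model` (weights, background, and metadata; foreground
#'   probabilities are not round-tripped).
#' @export
read_site_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  val <- function(key) {
    sub(paste0("^# ", key, " "), "", hdr[startsWith(hdr, paste0("# ", key))])
  }
  side <- val("side")
  w <- read.table(text = lines[!startsWith(lines, "# ")], sep = "\t",
                  row.names = 1)
  weights <- as.matrix(w)
  dimnames(weights) <- list(rownames(w), NULL)
  structure(list(side = side, window_def = site_window_def(side),
                 weights = weights,
                 foreground = NULL,
                 background = as.numeric(strsplit(val("background"),
                                                  " ")[[1]]),
                 pseudocount = as.numeric(val("pseudocount")),
                 n_train = as.integer(val("n_train"))),
            class = "site_model")
}

#' Find the decoy splice site paired to a real site
#'
#' Scans the intron flanking the real junction (downstream for donors,
#' upstream for acceptors) for consensus dinucleotides (GT for donors, AG
#' for acceptors, in sense orientation) whose junction lies `zone[1]` to
#' `zone[2]` nt from the real junction. Candidates scoring at least
#' `threshold` bits qualify; the nearest qualifier is returned.
#'
#' @param genome genome (see [as_genome()]).
#' @param real one-row splice-site `data.frame`.
#' @param model trained `site_model` matching the site's side.
#' @param zone distance range (nt) searched, default `c(150, 300)`.
#' @param threshold minimum qualifying score in bits.
#' @param max_distance optional clamp on the search (e.g. the flanking
#'   intron length); scanning past it returns `NULL` candidates only.
#' @return one-row `data.frame` (`decoy_pair`): real and decoy junction,
#'   distance, both scores; or `NULL` when no qualifier exists.
#' @export
find_decoy <- function(genome, real, model, zone = c(150L, 300L),
                       threshold = 0, max_distance = Inf) {
  genome <- as_genome(genome)
  stopifnot(nrow(real) == 1, inherits(model, "site_model"))
  side <- real$side
  if (model$side != side) stop("model side does not match site side")
  if (!real$seqname %in% names(genome)) {
    stop("unknown seqname: ", real$seqname)
  }
  chrom <- genome[[real$seqname]]
  jp <- real$junction_pos
  strand <- real$strand
  hi <- min(zone[2], max_distance)
  if (hi < zone[1]) {
    warning("decoy zone outside flanking intron; no decoy")
    return(NULL)
  }
  dists <- seq.int(zone[1], hi)
  # intronic direction along the genome: donors extend with transcription,
  # acceptors against it
  dir_sign <- if ((side == "donor") == (strand == "+")) 1L else -1L
  cand_pos <- jp + dir_sign * dists
  ok <- cand_pos - 1L >= 0L & cand_pos + 2L <= nchar(chrom)
  if (!any(ok)) {
    warning("decoy zone outside sequence bounds; no decoy")
    return(NULL)
  }
  cand <- real[rep(1L, sum(ok)), , drop = FALSE]
  cand$junction_pos <- cand_pos[ok]
  cand$category <- "decoy"
  cand_d <- dists[ok]
  # consensus dinucleotide in sense orientation at the candidate junction
  def <- model$window_def
  dinuc <- vapply(cand$junction_pos, function(p) {
    if (side == "donor") span <- c(p, p + 2L) else span <- c(p - 1L, p + 1L)
    if (strand == "-") {
      span <- if (side == "donor") c(p - 1L, p + 1L) else c(p, p + 2L)
    }
    .extract_span(chrom, span[1], span[2], strand)
  }, character(1))
  hit <- dinuc == def$dinuc
  cand <- cand[hit, , drop = FALSE]
  cand_d <- cand_d[hit]
  if (nrow(cand) == 0) return(NULL)
  seqs <- extract_site_sequence(setNames(chrom, real$seqname), cand)
  scores <- score_site(model, seqs)
  qual <- !is.na(scores) & scores >= threshold
  if (!any(qual)) return(NULL)
  cand <- cand[qual, , drop = FALSE]
  cand_d <- cand_d[qual]
  scores <- scores[qual]
  pick <- which.min(cand_d)  # nearest; distances are unique within a side
  real_seq <- extract_site_sequence(setNames(chrom, real$seqname), real)
  data.frame(
    seqname = real$seqname, strand = strand, side = side,
    real_junction = jp, decoy_junction = cand$junction_pos[pick],
    distance = cand_d[pick],
    real_score = score_site(model, real_seq),
    decoy_score = scores[pick],
    stringsAsFactors = FALSE
  )
}

#' Batch decoy selection
#'
#' @inheritParams find_decoy
#' @param sites splice-site `data.frame` (one side).
#' @return `data.frame` of decoy pairs (sites without a qualifier are
#'   omitted).
#' @export
find_decoys <- function(genome, sites, model, zone = c(150L, 300L),
                        threshold = 0, max_distance = Inf) {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    suppressWarnings(find_decoy(genome, sites[i, , drop = FALSE], model,
                                zone, threshold, max_distance))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    return(data.frame(seqname = character(0), strand = character(0),
                      side = character(0), real_junction = integer(0),
                      decoy_junction = integer(0), distance = integer(0),
                      real_score = numeric(0), decoy_score = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# turn decoy-pair rows into site tables for window extraction
.pairs_to_sites <- function(pairs, which = c("real", "decoy")) {
  which <- match.arg(which)
  jp <- if (which == "real") pairs$real_junction else pairs$decoy_junction
  data.frame(seqname = pairs$seqname, strand = pairs$strand,
             side = pairs$side, junction_pos = jp,
             category = which, stringsAsFactors = FALSE)
}

#' Paired real-vs-decoy comparison of GC and folding stability
#'
#' For each real/decoy pair, extracts both junction windows, computes GC
#' fractions and MFEs, and runs paired Wilcoxon signed-rank tests on GC,
#' on MFE, and on the normalized junction GC ([normalized_junction_gc()]).
#'
#' @param genome genome (see [as_genome()]).
#' @param pairs decoy-pair `data.frame` from [find_decoys()] (>= 10 rows).
#' @param model an `energy_model` for folding.
#' @param flank window flank.
#' @return list with `windows` (real and decoy window tables, aligned) and
#'   `comparisons` (one `comparison_result` row per metric).
#' @export
paired_decoy_comparison <- function(genome, pairs, model = make_model(37),
                                    flank = 70L) {
  if (nrow(pairs) < 10) stop("need at least 10 decoy pairs")
  real_sites <- .pairs_to_sites(pairs, "real")
  decoy_sites <- .pairs_to_sites(pairs, "decoy")
  wr <- extract_windows(genome, real_sites, flank, warn_oob = FALSE)
  wd <- extract_windows(genome, decoy_sites, flank, warn_oob = FALSE)
  keyr <- paste(real_sites$seqname, real_sites$junction_pos)
  keyd <- paste(decoy_sites$seqname, decoy_sites$junction_pos)
  okr <- keyr %in% paste(wr$seqname, wr$junction_pos)
  okd <- keyd %in% paste(wd$seqname, wd$junction_pos)
  keep <- okr & okd
  wr <- wr[match(keyr[keep], paste(wr$seqname, wr$junction_pos)), ]
  wd <- wd[match(keyd[keep], paste(wd$seqname, wd$junction_pos)), ]
  if (nrow(wr) < 10) stop("fewer than 10 extractable pairs")
  wr$mfe <- fold_mfe_many(wr$sequence, model)
  wd$mfe <- fold_mfe_many(wd$sequence, model)
  norm_r <- suppressWarnings(normalized_junction_gc(genome, wr))
  norm_d <- suppressWarnings(normalized_junction_gc(genome, wd))
  cmp <- rbind(
    signed_rank_test(wr$gc_fraction - wd$gc_fraction,
                     label_a = "real_gc", label_b = "decoy_gc",
                     mean_a = mean(wr$gc_fraction),
                     mean_b = mean(wd$gc_fraction)),
    signed_rank_test(wr$mfe - wd$mfe,
                     label_a = "real_mfe", label_b = "decoy_mfe",
                     mean_a = mean(wr$mfe), mean_b = mean(wd$mfe)),
    signed_rank_test((norm_r - norm_d)[complete.cases(norm_r, norm_d)],
                     label_a = "real_norm_gc", label_b = "decoy_norm_gc",
                     mean_a = mean(norm_r, na.rm = TRUE),
                     mean_b = mean(norm_d, na.rm = TRUE))
  )
  list(windows = list(real = wr, decoy = wd), comparisons = cmp)
}
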