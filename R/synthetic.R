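# Synthetic genomes, annotations, and tissue tables with planted effects.
#
# Every gene follows a fixed six-exon template on its own sequence, with
# four isoforms realizing one constitutive exon (identical in all four),
# one cassette exon (skipped by an isoform that retains both flanking
# exons), a pair of alternative donors (>= 5 bp apart) and a pair of
# alternative acceptors (>= 9 bp apart), plus a shared-TSS first exon
# whose donor is constitutive or alternative. Junction windows are
# composition-sampled to hit per-category GC targets; GT/AG consensus
# dinucleotides (with a noisy consensus motif) mark every real junction,
# and decoy motifs can be planted 150-300 nt into flanking introns.

DONOR_CONSENSUS <- "CAGGTAAGT"                 # 3 exonic + 6 intronic
ACCEPTOR_CONSENSUS <- "TTTCTTTTTTTTTTTCTCAGGCA"  # 20 intronic + 3 exonic

#' Configuration for the synthetic generators
#'
#' Defaults encode the planted world: per-category mean GC fractions of
#' 0.52 / 0.48 / 0.47 for alternative / constitutive / skipped sites (sd
#' 0.05), 0.62 / 0.64 for first-exon alternative / constitutive donors,
#' 0.56 vs 0.52 for tissue-specific vs non-specific sites, a 0.45-GC
#' background, introns long enough (>= 400 nt) to host the 150-300 nt
#' decoy zone, and threshold-clear tissue tables.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param n_genes number of genes (one sequence each).
#' @param gc_background background GC fraction away from junctions.
#' @param gc_means named per-category mean GC fractions.
#' @param gc_sd per-site standard deviation of the GC target.
#' @param frac_first_alternative fraction of genes whose first-exon donor
#'   varies across isoforms.
#' @param frac_long_exon fraction of genes whose constitutive exon is long
#'   (> 200 bp).
#' @param frac_minus_strand fraction of genes placed on the minus strand.
#' @param site_noise per-position mutation probability applied to the
#'   consensus motifs at real junctions (consensus GT/AG kept fixed).
#' @param decoy_rate fraction of genes receiving planted decoy motifs.
#' @param flank junction-window flank (70 gives 141-nt windows).
#' @param n_tissues tissues per event in the tissue table.
#' @param fraction_tissue_specific planted tissue-specific event fraction.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 30L,
                             gc_background = 0.45,
                             gc_means = c(alternative = 0.52,
                                          constitutive = 0.48,
                                          skipped = 0.47,
                                          first_alternative = 0.62,
                                          first_constitutive = 0.64,
                                          tissue_specific = 0.56,
                                          non_tissue_specific = 0.52),
                             gc_sd = 0.05,
                             frac_first_alternative = 0.3,
                             frac_long_exon = 0.5,
                             frac_minus_strand = 0.5,
                             site_noise = 0.1,
                             decoy_rate = 1.0,
                             flank = 70L,
                             n_tissues = 48L,
                             fraction_tissue_specific = 0.25) {
  stopifnot(all(gc_means > 0 & gc_means < 1), n_genes >= 1, flank >= 1,
            gc_background > 0, gc_background < 1)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gc_background = gc_background, gc_means = gc_means,
              gc_sd = gc_sd,
              frac_first_alternative = frac_first_alternative,
              frac_long_exon = frac_long_exon,
              frac_minus_strand = frac_minus_strand,
              site_noise = site_noise, decoy_rate = decoy_rate,
              flank = as.integer(flank), n_tissues = as.integer(n_tissues),
              fraction_tissue_specific = fraction_tissue_specific)
  class(cfg) <- "synthetic_config"
  cfg
}

# draw a GC target around a category mean, truncated away from degeneracy
.draw_gc_target <- function(mean, sd) {
  min(max(rnorm(1, mean, sd), 0.1), 0.9)
}

# random sequence with exact GC count round(target * len)
.seq_exact_gc <- function(len, target) {
  n_gc <- max(0L, min(len, round(target * len)))
  is_gc <- rep(FALSE, len)
  if (n_gc > 0) is_gc[sample.int(len, n_gc)] <- TRUE
  ch <- character(len)
  ch[is_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
  ch[!is_gc] <- sample(c("A", "T"), len - n_gc, replace = TRUE)
  ch
}

# random sequence with per-base GC probability p
.seq_random_gc <- function(len, p) {
  gc <- runif(len) < p
  ch <- character(len)
  ch[gc] <- sample(c("G", "C"), sum(gc), replace = TRUE)
  ch[!gc] <- sample(c("A", "T"), sum(!gc), replace = TRUE)
  ch
}

# apply per-position noise to a motif, keeping `keep` positions intact
.noisy_motif <- function(motif, noise, keep = integer(0)) {
  ch <- seq_chars(motif)
  hit <- which(runif(length(ch)) < noise)
  hit <- setdiff(hit, keep)
  if (length(hit) > 0) {
    ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
  }
  ch
}

# fixed local (sense-strand) gene template; all coordinates 0-based
# half-open on a sequence of length 3900
.gene_layout <- function(long_e2, first_alt, donor_shift = 6L,
                         acceptor_shift = 9L) {
  e2_end <- if (long_e2) 1150L else 1050L
  list(
    len = 3900L,
    e1a = c(200L, 350L), e1b = c(200L, 356L),
    e2 = c(900L, e2_end),
    e3 = c(1550L, 1700L),
    e4a = c(2200L, 2350L), e4b = c(2200L, 2350L + donor_shift),
    e5a = c(2900L, 3050L), e5b = c(2900L + acceptor_shift, 3050L),
    e6 = c(3550L, 3700L),
    first_alt = first_alt
  )
}

# isoform exon lists (local coordinates) for the template
.gene_isoforms <- function(ly) {
  e1_iso4 <- if (ly$first_alt) ly$e1b else ly$e1a
  list(
    iso1 = rbind(ly$e1a, ly$e2, ly$e3, ly$e4a, ly$e5a, ly$e6),
    iso2 = rbind(ly$e1a, ly$e2, ly$e3, ly$e4b, ly$e5a, ly$e6),
    iso3 = rbind(ly$e1a, ly$e2, ly$e3, ly$e4a, ly$e5b, ly$e6),
    iso4 = rbind(e1_iso4, ly$e2, ly$e4a, ly$e5a, ly$e6)
  )
}

# all real junctions of the template in local coordinates:
# donor junction = exon end, acceptor junction = exon start - 1
.gene_junctions <- function(ly) {
  j <- list(
    list(side = "donor", jp = ly$e1a[2], category =
           if (ly$first_alt) "first_alternative" else "first_constitutive",
         truth = TRUE),
    list(side = "acceptor", jp = ly$e2[1] - 1L, category = "constitutive",
         truth = TRUE),
    list(side = "donor", jp = ly$e2[2], category = "constitutive",
         truth = TRUE),
    list(side = "acceptor", jp = ly$e3[1] - 1L, category = "skipped",
         truth = TRUE),
    list(side = "donor", jp = ly$e3[2], category = "skipped", truth = TRUE),
    list(side = "acceptor", jp = ly$e4a[1] - 1L, category = "other",
         truth = FALSE),
    list(side = "donor", jp = ly$e4a[2], category = "alternative",
         truth = TRUE),
    list(side = "donor", jp = ly$e4b[2], category = "alternative",
         truth = TRUE),
    list(side = "acceptor", jp = ly$e5a[1] - 1L, category = "alternative",
         truth = TRUE),
    list(side = "acceptor", jp = ly$e5b[1] - 1L, category = "alternative",
         truth = TRUE),
    list(side = "donor", jp = ly$e5a[2], category = "other", truth = FALSE),
    list(side = "acceptor", jp = ly$e6[1] - 1L, category = "other",
         truth = FALSE)
  )
  if (ly$first_alt) {
    j[[length(j) + 1]] <- list(side = "donor", jp = ly$e1b[2],
                               category = "first_alternative", truth = TRUE)
  }
  j
}

#' Generate a synthetic genome, annotation, and truth table
#'
#' @param config a [synthetic_config()].
#' @param fasta_path,gtf_path,truth_path optional output files (FASTA,
#'   GTF, TSV).
#' @return list with `genome` (named character vector), `models`
#'   (`transcript_models`), `truth` (one row per planted splice site:
#'   category, GC target, planted decoy junction/distance where present),
#'   and `config`.
#' @export
generate_genome_annotation <- function(config = synthetic_config(),
                                       fasta_path = NULL, gtf_path = NULL,
                                       truth_path = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  flank <- config$flank
  if (flank > 150L) {
    stop("infeasible config: flank > 150 does not fit the intron template")
  }
  set.seed(config$seed)
  genome <- character(config$n_genes)
  names(genome) <- paste0("synth_seq", seq_len(config$n_genes))
  exon_rows <- list()
  truth_rows <- list()
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    seqname <- names(genome)[g]
    strand <- if (runif(1) < config$frac_minus_strand) "-" else "+"
    long_e2 <- runif(1) < config$frac_long_exon
    first_alt <- runif(1) < config$frac_first_alternative
    ly <- .gene_layout(long_e2, first_alt)
    L <- ly$len
    ch <- .seq_random_gc(L, config$gc_background)
    juncs <- .gene_junctions(ly)
    # per-category GC target, one draw per category per gene so the two
    # members of an alternative pair share a target
    cats <- unique(vapply(juncs, function(j) j$category, character(1)))
    targets <- vapply(cats, function(cat) {
      if (cat == "other") config$gc_background
      else .draw_gc_target(config$gc_means[[cat]], config$gc_sd)
    }, numeric(1))
    names(targets) <- cats
    # 1) composition-sample each junction window to its target
    for (j in juncs) {
      span <- seq.int(j$jp - flank, j$jp + flank) + 1L  # 1-based
      ch[span] <- .seq_exact_gc(length(span), targets[[j$category]])
    }
    # 2) noisy consensus motifs at every real junction (ascending jp)
    ord <- order(vapply(juncs, function(j) j$jp, integer(1)))
    for (j in juncs[ord]) {
      if (j$side == "donor") {
        span <- seq.int(j$jp - 3L, j$jp + 5L) + 1L
        ch[span] <- .noisy_motif(DONOR_CONSENSUS, config$site_noise,
                                 keep = c(4L, 5L))
      } else {
        span <- seq.int(j$jp - 19L, j$jp + 3L) + 1L
        ch[span] <- .noisy_motif(ACCEPTOR_CONSENSUS, config$site_noise,
                                 keep = c(19L, 20L))
      }
    }
    # 3) restore the invariant consensus dinucleotides (overlapping motif
    # writes may have clobbered a neighbor's GT/AG)
    for (j in juncs) {
      if (j$side == "donor") {
        ch[j$jp + 1L] <- "G"; ch[j$jp + 2L] <- "T"
      } else {
        ch[j$jp] <- "A"; ch[j$jp + 1L] <- "G"
      }
    }
    # 4) plant decoy motifs: exact consensus in the decoy zone of the
    # constitutive donor (downstream intron) and skipped acceptor
    # (upstream intron); zones are disjoint by construction
    decoy_donor_jp <- NA_integer_; decoy_donor_d <- NA_integer_
    decoy_acc_jp <- NA_integer_; decoy_acc_d <- NA_integer_
    if (runif(1) < config$decoy_rate) {
      decoy_donor_d <- sample(155:175, 1L)
      decoy_donor_jp <- ly$e2[2] + decoy_donor_d
      span <- seq.int(decoy_donor_jp - 3L, decoy_donor_jp + 5L) + 1L
      ch[span] <- seq_chars(DONOR_CONSENSUS)
      # the planted decoy must be the nearest qualifier: scrub competing
      # GT dinucleotides from the preemption stretch [150, d) of the zone
      for (p in seq.int(ly$e2[2] + 150L, decoy_donor_jp - 1L)) {
        if (ch[p + 1L] == "G" && ch[p + 2L] == "T") ch[p + 2L] <- "A"
      }
      decoy_acc_d <- sample(175:195, 1L)
      decoy_acc_jp <- (ly$e3[1] - 1L) - decoy_acc_d
      span <- seq.int(decoy_acc_jp - 19L, decoy_acc_jp + 3L) + 1L
      ch[span] <- seq_chars(ACCEPTOR_CONSENSUS)
      for (p in seq.int(decoy_acc_jp + 1L, (ly$e3[1] - 1L) - 150L)) {
        if (ch[p] == "A" && ch[p + 1L] == "G") ch[p + 1L] <- "C"
      }
    }
    seq_sense <- paste(ch, collapse = "")
    # strand transform: local sense position p -> genomic L - 1 - p;
    # local exon [s, e) -> genomic [L - e, L - s)
    flip_jp <- function(p) if (strand == "+") p else L - 1L - p
    if (strand == "+") {
      genome[g] <- seq_sense
    } else {
      genome[g] <- revcomp(seq_sense)
    }
    isos <- .gene_isoforms(ly)
    for (iso_name in names(isos)) {
      ex <- isos[[iso_name]]
      st <- ex[, 1]; en <- ex[, 2]
      if (strand == "-") {
        st2 <- L - ex[, 2]; en2 <- L - ex[, 1]
        st <- st2; en <- en2
      }
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        seqname = seqname, strand = strand, start = as.integer(st),
        end = as.integer(en), gene_id = gene_id,
        transcript_id = paste0(gene_id, ".", iso_name),
        stringsAsFactors = FALSE
      )
    }
    for (j in juncs) {
      if (!j$truth) next
      is_decoy_host_donor <- j$side == "donor" && j$category == "constitutive"
      is_decoy_host_acc <- j$side == "acceptor" && j$category == "skipped"
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        gene_id = gene_id, seqname = seqname, strand = strand,
        side = j$side, junction_pos = flip_jp(j$jp), category = j$category,
        gc_target = targets[[j$category]],
        decoy_junction = flip_jp(
          if (is_decoy_host_donor) decoy_donor_jp
          else if (is_decoy_host_acc) decoy_acc_jp else NA_integer_),
        decoy_distance =
          if (is_decoy_host_donor) decoy_donor_d
          else if (is_decoy_host_acc) decoy_acc_d else NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  models <- as_transcript_models(do.call(rbind, exon_rows))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(fasta_path)) write_genome_fasta(genome, fasta_path)
  if (!is.null(gtf_path)) write_gtf(models, gtf_path)
  if (!is.null(truth_path)) {
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(genome = genome, models = models, truth = truth, config = config)
}

#' Write transcript models to GTF
#' @param models a `transcript_models` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$seqname,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand,
    type = "exon",
    source = "spliceGC",
    gene_id = models$gene_id,
    transcript_id = models$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Generate a labelled junction-window cohort directly
#'
#' Bypasses genome assembly: draws per-window GC targets from the
#' configured category means and emits composition-exact window sequences,
#' for fast statistical testing.
#'
#' @param config a [synthetic_config()].
#' @param n_per_category windows per category.
#' @param categories which categories to draw (defaults to the internal
#'   exon trio).
#' @param side window side label.
#' @param seed optional override of `config$seed`.
#' @return window `data.frame`: `category`, `side`, `sequence`,
#'   `gc_target`, `gc_number`, `gc_fraction`.
#' @export
generate_windows_cohort <- function(config = synthetic_config(),
                                    n_per_category = 400L,
                                    categories = c("alternative",
                                                   "constitutive",
                                                   "skipped"),
                                    side = "donor", seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(if (is.null(seed)) config$seed + 1L else as.integer(seed))
  L <- 2L * config$flank + 1L
  out <- list()
  for (cat in categories) {
    if (!cat %in% names(config$gc_means)) stop("unknown category: ", cat)
    targets <- vapply(seq_len(n_per_category), function(i) {
      .draw_gc_target(config$gc_means[[cat]], config$gc_sd)
    }, numeric(1))
    seqs <- vapply(targets, function(t) {
      paste(.seq_exact_gc(L, t), collapse = "")
    }, character(1))
    out[[cat]] <- data.frame(
      category = cat, side = side, sequence = seqs, gc_target = targets,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$gc_number <- vapply(res$sequence, gc_count, integer(1),
                          USE.NAMES = FALSE)
  res$gc_fraction <- res$gc_number / L
  attr(res, "flank") <- config$flank
  res
}

#' Generate windows with first-order (dinucleotide) structure
#'
#' Draws window sequences from a stationary first-order Markov chain whose
#' transition kernel mixes base persistence with the composition target:
#' `P(b | prev) = persistence * I(b == prev) + (1 - persistence) * pi(b)`,
#' where `pi` is the base distribution implied by the GC target. The
#' stationary distribution is exactly `pi`, and — crucially — conditional
#' on its dinucleotide counts a realization is uniform over all
#' arrangements with those counts, so dinucleotide-preserving shuffles are
#' the exact null for these windows while mononucleotide shuffles destroy
#' the planted order structure. `persistence = 0` recovers iid sampling.
#'
#' @param n number of windows.
#' @param length window length (141 default).
#' @param gc_range GC-fraction targets drawn uniformly from this range.
#' @param persistence probability mass on repeating the previous base.
#' @param seed integer seed.
#' @return window `data.frame` with `sequence`, `gc_target`, `gc_number`.
#' @export
markov_windows <- function(n, length = 141L, gc_range = c(0.3, 0.7),
                           persistence = 0.4, seed = 1L) {
  stopifnot(persistence >= 0, persistence < 1, length >= 2)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  targets <- runif(n, gc_range[1], gc_range[2])
  for (i in seq_len(n)) {
    p <- targets[i]
    pi_b <- c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)
    ch <- character(length)
    ch[1] <- sample(bases, 1, prob = pi_b)
    for (k in 2:length) {
      if (runif(1) < persistence) {
        ch[k] <- ch[k - 1]
      } else {
        ch[k] <- sample(bases, 1, prob = pi_b)
      }
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  out <- data.frame(sequence = seqs, gc_target = targets,
                    stringsAsFactors = FALSE)
  out$gc_number <- vapply(out$sequence, gc_count, integer(1),
                          USE.NAMES = FALSE)
  out
}

#' Generate a tissue-level event table with planted specificity
#'
#' Planted tissue-specific events get one tissue with delta in
#' (0.12, 0.4) and p in (0, 0.25) — clear of the rule thresholds — while
#' all other entries (and all entries of non-specific events) have delta
#' in (0, 0.04), so the delta >= 0.10 & p < 0.3 rule recovers the planted
#' flags exactly.
#'
#' @param config a [synthetic_config()].
#' @param n_events number of events.
#' @param seed optional override of `config$seed`.
#' @return list with `events` (`event_id`, `tissue`, `delta`, `p_value`)
#'   and `truth` (`event_id`, `tissue_specific` flag).
#' @export
generate_tissue_table <- function(config = synthetic_config(),
                                  n_events = 1000L, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(if (is.null(seed)) config$seed + 2L else as.integer(seed))
  nt <- config$n_tissues
  spec <- runif(n_events) < config$fraction_tissue_specific
  rows <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    delta <- runif(nt, 0, 0.04)
    p <- runif(nt, 0, 1)
    if (spec[i]) {
      t0 <- sample.int(nt, 1L)
      delta[t0] <- runif(1, 0.12, 0.4)
      p[t0] <- runif(1, 0, 0.25)
    }
    rows[[i]] <- data.frame(
      event_id = sprintf("event%05d", i),
      tissue = paste0("tissue", seq_len(nt)),
      delta = delta, p_value = p, stringsAsFactors = FALSE
    )
  }
  list(events = do.call(rbind, rows),
       truth = data.frame(event_id = sprintf("event%05d", seq_len(n_events)),
                          tissue_specific = spec, stringsAsFactors = FALSE))
}
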