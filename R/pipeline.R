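# End-to-end orchestration: run every analysis stage on a genome +
# annotation (synthetic by default) and collect per-stage tables.

#' Run configuration for the full analysis
#'
#' @param synthetic a [synthetic_config()] used to generate the inputs
#'   (file-based inputs can be supplied instead via `fasta`, `gtf`,
#'   `tissue_tsv`).
#' @param fasta,gtf,tissue_tsv optional input files; when given they
#'   replace the synthetic genome/annotation/tissue table.
#' @param flank window flank (70 default; 30 gives the 61-nt variant).
#' @param temperature_c folding temperature.
#' @param decoy_zone decoy search distances (nt).
#' @param pair_max_dist distance-controlled pairing radius (nt).
#' @param n_shuffle shuffles per order per window.
#' @param n_order_windows windows entering the order-effect stage.
#' @param n_cohort windows per category for the cohort-based stages.
#' @param min_train minimum training-set size for the decoy site scorer
#'   (lower it for very small synthetic runs).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       fasta = NULL, gtf = NULL, tissue_tsv = NULL,
                       flank = 70L, temperature_c = 37,
                       decoy_zone = c(150L, 300L), pair_max_dist = 3000L,
                       n_shuffle = 10L, n_order_windows = 50L,
                       n_cohort = 400L, min_train = 50L, seed = 1L) {
  stopifnot(flank >= 1, pair_max_dist > 0, n_shuffle >= 1)
  for (f in c(fasta, gtf, tissue_tsv)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  }
  structure(list(synthetic = synthetic, fasta = fasta, gtf = gtf,
                 tissue_tsv = tissue_tsv, flank = as.integer(flank),
                 temperature_c = temperature_c, decoy_zone = decoy_zone,
                 pair_max_dist = as.integer(pair_max_dist),
                 n_shuffle = as.integer(n_shuffle),
                 n_order_windows = as.integer(n_order_windows),
                 n_cohort = as.integer(n_cohort),
                 min_train = as.integer(min_train),
                 seed = as.integer(seed)),
            class = "run_config")
}

# fold a window table, attaching an `mfe` column
.fold_windows <- function(windows, model) {
  windows$mfe <- fold_mfe_many(windows$sequence, model)
  windows
}

.category_comparisons <- function(windows, side_label) {
  pairs <- list(c("alternative", "constitutive"),
                c("alternative", "skipped"))
  out <- list()
  for (pr in pairs) {
    wa <- windows[windows$category == pr[1], ]
    wb <- windows[windows$category == pr[2], ]
    if (nrow(wa) < 2 || nrow(wb) < 2) next
    out[[length(out) + 1]] <- rank_sum_test(
      wa$gc_fraction, wb$gc_fraction,
      label_a = paste0(side_label, ":", pr[1], ":gc"),
      label_b = paste0(side_label, ":", pr[2], ":gc"))
    out[[length(out) + 1]] <- rank_sum_test(
      wa$mfe, wb$mfe,
      label_a = paste0(side_label, ":", pr[1], ":mfe"),
      label_b = paste0(side_label, ":", pr[2], ":mfe"))
  }
  do.call(rbind, out)
}

#' Run the full analysis
#'
#' Stages (each emitting a table in the returned bundle): splice-site
#' classification; junction windows + GC metrics; folding; per-side
#' category GC/MFE comparisons; GC-energy regressions per category;
#' GC-matched bin tests; distance-controlled paired tests; first-exon
#' donor comparison; long-vs-short exon comparison; tissue-specificity
#' comparison; decoy paired comparisons with positional GC profiles; and
#' the nucleotide-order (shuffle) analysis.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for TSV outputs.
#' @return list of class `splicegc_report` with one element per stage and
#'   a `log` of stage notes.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  model <- make_model(config$temperature_c)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  bundle <- list(config = config)

  # --- inputs ---
  syn <- NULL
  if (is.null(config$fasta) || is.null(config$gtf)) {
    syncfg <- config$synthetic
    syncfg$seed <- config$seed
    syncfg$flank <- config$flank
    syn <- generate_genome_annotation(syncfg)
    genome <- syn$genome
    models <- syn$models
    note("simulate: ", length(genome), " sequences, ",
         nrow(models), " exon records")
  } else {
    genome <- as_genome(config$fasta)
    models <- load_annotation(config$gtf, "gtf")
    note("load: ", length(genome), " sequences, ", nrow(models),
         " exon records")
  }

  # --- classification ---
  sites <- classify_splice_sites(models)
  bundle$sites <- sites
  note("classify: ", nrow(sites), " categorized splice sites")

  # --- windows + folding over genome-derived sites ---
  internal <- sites[sites$category %in% c("alternative", "constitutive",
                                          "skipped"), ]
  win <- extract_windows(genome, internal, flank = config$flank)
  win <- .fold_windows(win, model)
  bundle$windows <- win
  note("windows: ", nrow(win), " junction windows folded at ",
       config$temperature_c, " degC")

  # --- per-side category comparisons (genome route) ---
  cmp <- list()
  for (sd_ in c("donor", "acceptor")) {
    cmp[[sd_]] <- .category_comparisons(win[win$side == sd_, ], sd_)
  }
  bundle$category_comparisons <- do.call(rbind, cmp)

  # --- cohort-based stages (large n) ---
  cohort <- generate_windows_cohort(config$synthetic,
                                    n_per_category = config$n_cohort,
                                    seed = config$seed + 11L)
  cohort <- .fold_windows(cohort, model)
  bundle$cohort <- cohort
  bundle$cohort_comparisons <- .category_comparisons(cohort, "cohort")
  note("cohort: ", nrow(cohort), " windows across ",
       length(unique(cohort$category)), " categories")

  # --- GC-energy regression per category ---
  regs <- lapply(split(cohort, cohort$category), function(w) {
    cbind(category = w$category[1],
          gc_energy_regression(w$gc_fraction, w$mfe))
  })
  bundle$regressions <- do.call(rbind, regs)

  # --- GC-matched bins (alternative vs constitutive) ---
  two <- cohort[cohort$category %in% c("alternative", "constitutive"), ]
  bundle$gc_matched <- gc_matched_compare(two$mfe, two$category,
                                          two$gc_number)

  # --- distance-controlled pairing (alt vs constitutive, genome route) ---
  altw <- win[win$category == "alternative", ]
  consw <- win[win$category == "constitutive", ]
  if (nrow(altw) > 0 && nrow(consw) > 0) {
    altw$value <- altw$mfe
    consw$value <- consw$mfe
    bundle$distance_pairs <- tryCatch(
      distance_controlled_pairs(altw, consw, config$pair_max_dist),
      error = function(e) {
        note("distance pairing skipped: ", conditionMessage(e))
        NULL
      })
  }

  # --- first-exon donors vs internal donors ---
  firsts <- sites[sites$category %in% c("first_alternative",
                                        "first_constitutive"), ]
  fw <- extract_windows(genome, firsts, flank = config$flank,
                        warn_oob = FALSE)
  if (nrow(fw) >= 2) {
    fw <- .fold_windows(fw, model)
    bundle$first_exon_windows <- fw
    idon <- win[win$side == "donor", ]
    bundle$first_exon_comparisons <- rbind(
      rank_sum_test(fw$gc_fraction, idon$gc_fraction,
                    label_a = "first_donor:gc", label_b = "internal_donor:gc"),
      rank_sum_test(fw$mfe, idon$mfe,
                    label_a = "first_donor:mfe", label_b = "internal_donor:mfe"))
    note("first-exon: ", nrow(fw), " first-donor windows")
  } else {
    note("first-exon stage skipped: no first-exon sites")
  }

  # --- long vs short exon sites ---
  lw <- win[win$exon_length_class == "long", ]
  sw <- win[win$exon_length_class == "short", ]
  if (nrow(lw) >= 2 && nrow(sw) >= 2) {
    bundle$exon_length_comparisons <- rbind(
      rank_sum_test(lw$gc_fraction, sw$gc_fraction,
                    label_a = "long_exon:gc", label_b = "short_exon:gc"),
      rank_sum_test(lw$mfe, sw$mfe,
                    label_a = "long_exon:mfe", label_b = "short_exon:mfe"))
  } else {
    note("exon-length stage skipped: one class empty")
  }

  # --- tissue-specific stage ---
  tissue <- if (!is.null(config$tissue_tsv)) {
    list(events = read.table(config$tissue_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE), truth = NULL)
  } else {
    generate_tissue_table(config$synthetic, n_events = 400L,
                          seed = config$seed + 21L)
  }
  cls <- classify_tissue_specific(tissue$events)
  bundle$tissue_classes <- cls
  tw <- generate_windows_cohort(config$synthetic,
                                n_per_category = max(
                                  50L, min(sum(cls$class == "tissue_specific"),
                                           config$n_cohort)),
                                categories = c("tissue_specific",
                                               "non_tissue_specific"),
                                seed = config$seed + 31L)
  tw <- .fold_windows(tw, model)
  ts <- tw[tw$category == "tissue_specific", ]
  nts <- tw[tw$category == "non_tissue_specific", ]
  bundle$tissue_comparisons <- rbind(
    rank_sum_test(ts$gc_fraction, nts$gc_fraction,
                  label_a = "tissue_specific:gc",
                  label_b = "non_tissue_specific:gc"),
    rank_sum_test(ts$mfe, nts$mfe,
                  label_a = "tissue_specific:mfe",
                  label_b = "non_tissue_specific:mfe"))
  note("tissue: ", sum(cls$class == "tissue_specific"), " specific of ",
       nrow(cls), " events")

  # --- decoy stage (synthetic truth drives site choice) ---
  if (!is.null(syn)) {
    truth <- syn$truth
    hosts <- truth[!is.na(truth$decoy_junction), ]
    don_seq <- extract_site_sequence(genome,
                                     sites[sites$side == "donor", ])
    acc_seq <- extract_site_sequence(genome,
                                     sites[sites$side == "acceptor", ])
    don_model <- train_site_model(don_seq[!is.na(don_seq)], "donor",
                                  min_n = config$min_train)
    acc_model <- train_site_model(acc_seq[!is.na(acc_seq)], "acceptor",
                                  min_n = config$min_train)
    pd <- find_decoys(genome, hosts[hosts$side == "donor", ], don_model,
                      zone = config$decoy_zone)
    pa <- find_decoys(genome, hosts[hosts$side == "acceptor", ], acc_model,
                      zone = config$decoy_zone)
    pairs <- rbind(pd, pa)
    bundle$decoy_pairs <- pairs
    key_found <- paste(pairs$seqname, pairs$side, pairs$real_junction,
                       pairs$decoy_junction)
    key_truth <- paste(hosts$seqname, hosts$side, hosts$junction_pos,
                       hosts$decoy_junction)
    bundle$decoy_recovery <- mean(key_truth %in% key_found)
    note("decoys: ", nrow(pairs), " pairs; planted recovery ",
         sprintf("%.1f%%", 100 * bundle$decoy_recovery))
    if (nrow(pairs) >= 10) {
      dc <- paired_decoy_comparison(genome, pairs, model, config$flank)
      bundle$decoy_comparisons <- dc$comparisons
      bundle$decoy_profiles <- list(
        real_donor = positional_gc_profile(
          dc$windows$real[dc$windows$real$side == "donor", ],
          config$flank),
        decoy_donor = positional_gc_profile(
          dc$windows$decoy[dc$windows$decoy$side == "donor", ],
          config$flank))
    }
  } else {
    note("decoy stage skipped: no synthetic truth for site selection")
  }

  # --- nucleotide-order effect ---
  set.seed(config$seed + 40L)
  ow <- cohort[sample.int(nrow(cohort),
                          min(config$n_order_windows, nrow(cohort))), ]
  bundle$order_effect <- order_effect_analysis(
    ow, model, n_reps = config$n_shuffle, seed = config$seed + 41L)
  note("order effect: ", nrow(ow), " windows x ", config$n_shuffle,
       " shuffles per order")

  bundle$log <- log
  class(bundle) <- "splicegc_report"
  if (!is.null(out_dir)) write_report_tables(bundle, out_dir)
  bundle
}

#' Write the report bundle tables to a directory of TSV files
#' @param bundle a `splicegc_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  put(bundle$sites, "sites")
  put(bundle$windows, "windows")
  put(bundle$category_comparisons, "category_comparisons")
  put(bundle$cohort_comparisons, "cohort_comparisons")
  put(bundle$regressions, "regressions")
  put(bundle$gc_matched, "gc_matched")
  put(bundle$first_exon_comparisons, "first_exon_comparisons")
  put(bundle$exon_length_comparisons, "exon_length_comparisons")
  put(bundle$tissue_comparisons, "tissue_comparisons")
  put(bundle$decoy_comparisons, "decoy_comparisons")
  if (!is.null(bundle$order_effect)) {
    put(bundle$order_effect$comparisons, "order_effect_comparisons")
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' One-page human-readable summary of a report bundle
#' @param bundle a `splicegc_report`.
#' @return character vector of summary lines (also printed).
#' @export
report_summary <- function(bundle) {
  if (!inherits(bundle, "splicegc_report") || length(bundle) <= 1) {
    stop("not a completed report bundle")
  }
  lines <- c("== spliceGC analysis summary ==")
  fmt_cmp <- function(df, title) {
    if (is.null(df)) return(character(0))
    c(paste0("-- ", title, " --"),
      vapply(seq_len(nrow(df)), function(i) {
        sprintf("%s vs %s: n=%d/%d mean=%.3f/%.3f p=%.3g",
                df$label_a[i], df$label_b[i], df$n_a[i], df$n_b[i],
                df$mean_a[i], df$mean_b[i], df$p_value[i])
      }, character(1)))
  }
  lines <- c(lines,
             sprintf("sites classified: %d", nrow(bundle$sites)),
             fmt_cmp(bundle$category_comparisons, "genome-route categories"),
             fmt_cmp(bundle$cohort_comparisons, "cohort categories"),
             fmt_cmp(bundle$first_exon_comparisons, "first-exon donors"),
             fmt_cmp(bundle$exon_length_comparisons, "exon length"),
             fmt_cmp(bundle$tissue_comparisons, "tissue specificity"),
             fmt_cmp(bundle$decoy_comparisons, "real vs decoy (paired)"))
  if (!is.null(bundle$regressions)) {
    lines <- c(lines, "-- GC-energy regressions --",
               vapply(seq_len(nrow(bundle$regressions)), function(i) {
                 r <- bundle$regressions[i, ]
                 sprintf("%s: slope=%.2f r=%.3f R2=%.3f n=%d",
                         r$category, r$slope, r$pearson_r, r$r_squared, r$n)
               }, character(1)))
  }
  if (!is.null(bundle$gc_matched)) {
    tested <- bundle$gc_matched[bundle$gc_matched$tested, ]
    lines <- c(lines, sprintf(
      "GC-matched bins: %d tested, %d with p > 0.05",
      nrow(tested), sum(tested$p_value > 0.05)))
  }
  if (!is.null(bundle$decoy_recovery)) {
    lines <- c(lines, sprintf("planted decoy recovery: %.1f%%",
                              100 * bundle$decoy_recovery))
  }
  if (!is.null(bundle$order_effect)) {
    oc <- bundle$order_effect$comparisons
    lines <- c(lines, fmt_cmp(oc, "nucleotide-order effect"))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.splicegc_report <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
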