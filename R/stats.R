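# Statistical machinery: rank tests with exact small-sample enumeration,
# GC-energy regression, GC-matched bin comparisons, distance-controlled
# pairing, and the tissue-specificity rule.
#
# No multiple-testing correction is applied anywhere; raw p-values are
# reported together with sample sizes.

comparison_result <- function(label_a, label_b, n_a, n_b, mean_a, mean_b,
                              statistic, p_value, paired, method = "") {
  data.frame(label_a = label_a, label_b = label_b,
             n_a = as.integer(n_a), n_b = as.integer(n_b),
             mean_a = mean_a, mean_b = mean_b,
             statistic = statistic, p_value = p_value,
             paired = paired, method = method,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of all assignments of the pooled ranks when
#' `n_a + n_b <= exact_max` (ties handled by mid-ranks, enumeration over
#' the tied rank multiset); otherwise a tie-corrected normal approximation
#' without continuity correction. When every value in both samples is
#' identical the test is degenerate and `p = 1`.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (of `a`
#'   relative to `b`).
#' @param exact_max largest pooled size for exact enumeration.
#' @param label_a,label_b group labels carried into the result.
#' @return one-row `comparison_result` data.frame; `statistic` is the
#'   rank sum of `a`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "less",
                                                "greater"),
                          exact_max = 12L, label_a = "a", label_b = "b") {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  stopifnot(n_a >= 2, n_b >= 2)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(comparison_result(label_a, label_b, n_a, n_b, mean(a), mean(b),
                             n_a * (n_a + n_b + 1) / 2, 1, FALSE,
                             "rank-sum degenerate"))
  }
  r <- rank(pooled)
  stat <- sum(r[seq_len(n_a)])
  N <- n_a + n_b
  mu <- n_a * (N + 1) / 2
  if (N <= exact_max) {
    combs <- combn(N, n_a)
    sums <- colSums(matrix(r[combs], nrow = n_a))
    p <- switch(alternative,
      two.sided = mean(abs(sums - mu) >= abs(stat - mu) - 1e-9),
      greater = mean(sums >= stat - 1e-9),
      less = mean(sums <= stat + 1e-9)
    )
    method <- "rank-sum exact"
  } else {
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (stat - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(p, 1)
    method <- "rank-sum normal approx"
  }
  comparison_result(label_a, label_b, n_a, n_b, mean(a), mean(b),
                    stat, p, FALSE, method)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. Exact enumeration over all `2^n` sign
#' assignments when the non-zero count is at most `exact_max`; otherwise a
#' tie-corrected normal approximation. All-zero input gives `p = 1`.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (location of
#'   the differences relative to zero).
#' @param exact_max largest non-zero count for exact enumeration.
#' @param label_a,label_b,mean_a,mean_b metadata carried into the result.
#' @return one-row `comparison_result`; `statistic` is the positive-rank
#'   sum V.
#' @export
signed_rank_test <- function(diffs, alternative = c("two.sided", "less",
                                                    "greater"),
                             exact_max = 12L, label_a = "a", label_b = "b",
                             mean_a = NA_real_, mean_b = NA_real_) {
  alternative <- match.arg(alternative)
  diffs <- diffs[!is.na(diffs)]
  n_all <- length(diffs)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(comparison_result(label_a, label_b, n_all, n_all, mean_a, mean_b,
                             0, 1, TRUE, "signed-rank degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- switch(alternative,
      two.sided = mean(abs(vs - mu) >= abs(v - mu) - 1e-9),
      greater = mean(vs >= v - 1e-9),
      less = mean(vs <= v + 1e-9)
    )
    method <- "signed-rank exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(p, 1)
    method <- "signed-rank normal approx"
  }
  comparison_result(label_a, label_b, n_all, n_all, mean_a, mean_b,
                    v, p, TRUE, method)
}

#' GC-energy linear regression
#'
#' Ordinary least squares of MFE on GC, plus the Pearson correlation.
#'
#' @param gc GC measure per window (fraction or count).
#' @param mfe MFE per window (kcal/mol).
#' @return `data.frame` with `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `n`.
#' @export
gc_energy_regression <- function(gc, mfe) {
  ok <- complete.cases(gc, mfe)
  gc <- gc[ok]; mfe <- mfe[ok]
  if (length(gc) < 3) stop("need at least 3 points")
  if (length(unique(gc)) == 1L) stop("gc is constant; regression undefined")
  fit <- lm(mfe ~ gc)
  r <- cor(gc, mfe)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             pearson_r = r, r_squared = r^2, n = length(gc))
}

#' GC-matched between-group comparisons
#'
#' Bins windows by GC number and, within each bin containing at least
#' `min_per_group` windows of each group, compares the value (default MFE)
#' between the two groups with [rank_sum_test()]. Bins failing the size
#' requirement are reported as skipped.
#'
#' @param values numeric vector (e.g. MFE per window).
#' @param groups two-level factor/character vector of group labels.
#' @param gc_number integer GC counts per window.
#' @param bin_width width of the GC-number bins (default 5).
#' @param min_per_group minimum windows per group per tested bin.
#' @return `data.frame` with one row per bin: bin bounds, per-group n's and
#'   means, statistic, p-value, and a `tested` flag.
#' @export
gc_matched_compare <- function(values, groups, gc_number, bin_width = 5L,
                               min_per_group = 2L) {
  stopifnot(length(values) == length(groups),
            length(values) == length(gc_number))
  labs <- sort(unique(as.character(groups)))
  if (length(labs) != 2) stop("exactly two groups required")
  lo <- floor(min(gc_number) / bin_width) * bin_width
  breaks <- seq(lo, max(gc_number) + bin_width, by = bin_width)
  bin <- cut(gc_number, breaks = breaks, right = FALSE)
  out <- list()
  for (bl in levels(bin)) {
    idx <- which(bin == bl)
    va <- values[idx][groups[idx] == labs[1]]
    vb <- values[idx][groups[idx] == labs[2]]
    if (length(va) >= min_per_group && length(vb) >= min_per_group) {
      cmp <- rank_sum_test(va, vb, label_a = labs[1], label_b = labs[2])
      out[[bl]] <- cbind(data.frame(bin = bl, tested = TRUE), cmp)
    } else {
      out[[bl]] <- cbind(
        data.frame(bin = bl, tested = FALSE),
        comparison_result(labs[1], labs[2], length(va), length(vb),
                          if (length(va)) mean(va) else NA_real_,
                          if (length(vb)) mean(vb) else NA_real_,
                          NA_real_, NA_real_, FALSE, "skipped: too few")
      )
    }
  }
  res <- do.call(rbind, out)
  if (!any(res$tested)) stop("no testable GC bin")
  rownames(res) <- NULL
  res
}

#' Distance-controlled pairing of alternative and reference sites
#'
#' Pairs each alternative site with the nearest reference site on the same
#' sequence, strand, and side within `max_dist` nt (ties broken toward the
#' upstream, i.e. smaller-coordinate, reference), then runs a paired
#' signed-rank test on the supplied per-site values (e.g. MFE).
#'
#' @param alt_sites,ref_sites splice-site `data.frame`s, each with a
#'   `value` column holding the quantity to compare.
#' @param max_dist pairing radius in nt (default 3000).
#' @return list with `pairs` (alt index, ref index, distance, both values)
#'   and `comparison` (one-row signed-rank result alt - ref).
#' @export
distance_controlled_pairs <- function(alt_sites, ref_sites,
                                      max_dist = 3000L) {
  stopifnot("value" %in% names(alt_sites), "value" %in% names(ref_sites))
  pairs <- list()
  for (i in seq_len(nrow(alt_sites))) {
    same <- ref_sites$seqname == alt_sites$seqname[i] &
      ref_sites$strand == alt_sites$strand[i] &
      ref_sites$side == alt_sites$side[i]
    cand <- which(same)
    if (length(cand) == 0) next
    dist <- abs(ref_sites$junction_pos[cand] - alt_sites$junction_pos[i])
    ok <- dist <= max_dist
    if (!any(ok)) next
    cand <- cand[ok]; dist <- dist[ok]
    best <- which(dist == min(dist))
    if (length(best) > 1) {
      best <- best[which.min(ref_sites$junction_pos[cand[best]])]
    }
    pairs[[length(pairs) + 1]] <- data.frame(
      alt_index = i, ref_index = cand[best], distance = dist[best],
      alt_value = alt_sites$value[i], ref_value = ref_sites$value[cand[best]]
    )
  }
  if (length(pairs) == 0) stop("no pairs within max_dist")
  pr <- do.call(rbind, pairs)
  cmp <- signed_rank_test(pr$alt_value - pr$ref_value,
                          label_a = "alternative", label_b = "reference",
                          mean_a = mean(pr$alt_value),
                          mean_b = mean(pr$ref_value))
  list(pairs = pr, comparison = cmp)
}

#' Tissue-specificity classification of splicing events
#'
#' An event is `tissue_specific` when ANY tissue shows an isoform
#' proportion change of at least `delta_hi` with p below `p_cut`;
#' `non_tissue_specific` when EVERY tissue shows a change below `delta_lo`
#' or p above `p_cut`; otherwise `unclassified` (the rule as stated leaves
#' a gap between the two regions).
#'
#' @param events `data.frame` with columns `event_id`, `delta`
#'   (absolute isoform-proportion change, in \[0,1\]), `p_value`.
#' @param delta_hi,delta_lo,p_cut rule thresholds (defaults 0.10 / 0.05 /
#'   0.3).
#' @return `data.frame` with one row per event: `event_id`, `class`.
#' @export
classify_tissue_specific <- function(events, delta_hi = 0.10,
                                     delta_lo = 0.05, p_cut = 0.3) {
  stopifnot(all(c("event_id", "delta", "p_value") %in% names(events)),
            delta_hi > 0, delta_hi < 1, delta_lo > 0, delta_lo < 1,
            p_cut > 0, p_cut < 1)
  if (nrow(events) == 0) stop("empty event table")
  out <- lapply(split(events, events$event_id), function(ev) {
    if (nrow(ev) == 0) stop("event with no tissue entries")
    spec <- any(ev$delta >= delta_hi & ev$p_value < p_cut)
    nonspec <- all(ev$delta < delta_lo | ev$p_value > p_cut)
    cls <- if (spec) "tissue_specific"
           else if (nonspec) "non_tissue_specific"
           else "unclassified"
    data.frame(event_id = ev$event_id[1], class = cls,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a comparison table to TSV
#' @param comparisons `comparison_result` rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparisons, path) {
  write.table(comparisons, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
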