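# Permutation controls for the nucleotide-order effect.
#
# Mononucleotide shuffles are uniform permutations of the characters.
# Dinucleotide-preserving shuffles use the Altschul-Erickson random
# Eulerian path construction on the dinucleotide multigraph: the output has
# exactly the input's 16-dinucleotide count vector and the same first and
# last characters.

#' Mononucleotide (first-order) shuffle
#' @param sequence character scalar.
#' @return a uniform random permutation of the characters.
#' @export
shuffle_mono <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) == 0) stop("sequence must be non-empty")
  paste(ch[sample.int(length(ch))], collapse = "")
}

#' Dinucleotide-preserving (second-order) shuffle
#'
#' Altschul-Erickson Euler-path shuffle: treats the sequence as a walk on
#' the graph whose vertices are the distinct characters and whose edges are
#' the consecutive pairs, samples a random last-edge arborescence toward
#' the terminal vertex, permutes the remaining out-edges uniformly, and
#' reads off the resulting Eulerian path.
#'
#' @param sequence character scalar, length >= 2.
#' @return shuffled sequence with identical dinucleotide counts and
#'   endpoints.
#' @export
shuffle_dinuc <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 2) stop("sequence must have length >= 2")
  verts <- unique(ch)
  if (length(verts) == 1) return(sequence)
  last <- ch[n]
  # adjacency: out-edge target multisets
  from <- ch[-n]
  to <- ch[-1]
  adj <- split(to, factor(from, levels = verts))
  nonterm <- setdiff(names(adj)[vapply(adj, length, integer(1)) > 0], last)
  # sample last-edge choices until they form an arborescence toward `last`
  repeat {
    last_edge <- vapply(nonterm, function(v) {
      outs <- adj[[v]]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in nonterm) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonterm)) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # order each vertex's out-edges: random permutation, chosen last edge last
  ordered <- adj
  for (v in names(adj)) {
    outs <- adj[[v]]
    if (length(outs) == 0) next
    if (v %in% nonterm) {
      le <- last_edge[[v]]
      idx <- which(outs == le)[1]
      rest <- outs[-idx]
      if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
      ordered[[v]] <- c(rest, le)
    } else {
      if (length(outs) > 1) ordered[[v]] <- outs[sample.int(length(outs))]
    }
  }
  # walk the Eulerian path
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide count vector of a sequence
#' @param sequence character scalar.
#' @return named integer vector of the 16 (or observed-alphabet)
#'   dinucleotide counts.
#' @export
dinuc_counts <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

#' Native-vs-shuffled folding comparison (nucleotide-order effect)
#'
#' Folds each window and `n_reps` mononucleotide and dinucleotide shuffles
#' of it, then compares native MFE with the per-window mean shuffled MFE by
#' paired Wilcoxon signed-rank tests, overall and stratified by GC-number
#' group.
#'
#' @param windows window `data.frame` with `sequence` (and `gc_number`,
#'   recomputed if absent).
#' @param model an `energy_model`.
#' @param n_reps shuffles of each order per window (default 10).
#' @param seed integer seed; per-window substreams are derived from it so
#'   results do not depend on iteration order.
#' @param gc_centers,gc_halfwidth GC-number bins: `centers +/- halfwidth`
#'   (default 50/60/70/80 +/- 1).
#' @return list with `per_window` (native, mean mono, mean dinuc MFE and
#'   the per-replicate values), `comparisons` (paired tests, overall and
#'   per GC group), `n_reps`, `seed`.
#' @export
order_effect_analysis <- function(windows, model = make_model(37),
                                  n_reps = 10L, seed = 1L,
                                  gc_centers = c(50, 60, 70, 80),
                                  gc_halfwidth = 1) {
  if (nrow(windows) == 0) stop("no windows")
  stopifnot(n_reps >= 1L)
  if (is.null(windows$gc_number)) {
    windows$gc_number <- vapply(windows$sequence, gc_count, integer(1),
                                USE.NAMES = FALSE)
  }
  n <- nrow(windows)
  native <- numeric(n)
  mono <- matrix(NA_real_, n, n_reps)
  dinuc <- matrix(NA_real_, n, n_reps)
  for (i in seq_len(n)) {
    s <- windows$sequence[i]
    native[i] <- fold_mfe(s, model)$mfe
    set.seed((as.integer(seed) %% 100003L) * 10007L + i)
    for (r in seq_len(n_reps)) {
      sm <- shuffle_mono(s)
      sd2 <- shuffle_dinuc(s)
      mono[i, r] <- fold_mfe(sm, model)$mfe
      dinuc[i, r] <- fold_mfe(sd2, model)$mfe
    }
  }
  per_window <- data.frame(
    gc_number = windows$gc_number,
    native_mfe = native,
    mean_mono_mfe = rowMeans(mono),
    mean_dinuc_mfe = rowMeans(dinuc)
  )
  grp <- rep(NA_character_, n)
  for (cc in gc_centers) {
    inb <- abs(per_window$gc_number - cc) <= gc_halfwidth
    grp[inb] <- paste0("GC", cc)
  }
  per_window$gc_group <- grp
  run_cmp <- function(idx, label) {
    if (length(idx) < 2) return(NULL)
    rbind(
      signed_rank_test(native[idx] - rowMeans(mono)[idx],
                       label_a = paste0(label, ":native"),
                       label_b = paste0(label, ":mono_shuffled"),
                       mean_a = mean(native[idx]),
                       mean_b = mean(rowMeans(mono)[idx])),
      signed_rank_test(native[idx] - rowMeans(dinuc)[idx],
                       label_a = paste0(label, ":native"),
                       label_b = paste0(label, ":dinuc_shuffled"),
                       mean_a = mean(native[idx]),
                       mean_b = mean(rowMeans(dinuc)[idx]))
    )
  }
  comparisons <- run_cmp(seq_len(n), "all")
  for (g in unique(grp[!is.na(grp)])) {
    comparisons <- rbind(comparisons, run_cmp(which(!is.na(grp) & grp == g), g))
  }
  list(per_window = per_window, mono_mfes = mono, dinuc_mfes = dinuc,
       comparisons = comparisons, n_reps = n_reps, seed = seed)
}
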