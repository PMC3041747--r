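# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

random_seq <- function(n, gc = 0.5, rna = FALSE) {
  ab <- if (rna) c("G", "C", "A", "U") else c("G", "C", "A", "T")
  paste(sample(ab, n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# build a transcript_models table from a list of isoforms, each a list of
# c(start, end) exon vectors (0-based half-open)
gene_df <- function(isoforms, strand = "+", seqname = "chr1",
                    gene_id = "g1") {
  rows <- list()
  for (tx in names(isoforms)) {
    for (ex in isoforms[[tx]]) {
      rows[[length(rows) + 1]] <- data.frame(
        seqname = seqname, strand = strand, start = ex[1], end = ex[2],
        gene_id = gene_id, transcript_id = tx, stringsAsFactors = FALSE)
    }
  }
  as_transcript_models(do.call(rbind, rows))
}

# four-isoform gene with one internal constitutive exon at (1000, 1200)
constitutive_gene <- function(n_iso = 4, strand = "+") {
  isos <- lapply(seq_len(n_iso), function(i) {
    list(c(0, 100), c(1000, 1200), c(2000 + 10 * i, 2100 + 10 * i))
  })
  names(isos) <- paste0("tx", seq_len(n_iso))
  gene_df(isos, strand = strand)
}

# site row helper for window tests
site_row_fix <- function(seqname = "chr1", strand = "+", side = "donor",
                         jp = 200L, category = "constitutive") {
  data.frame(seqname = seqname, strand = strand, side = side,
             junction_pos = as.integer(jp), category = category,
             gene_id = "g1", stringsAsFactors = FALSE)
}

# noisy consensus training set for site-model tests
consensus_training <- function(n, consensus, noise = 0.1, keep = integer(0)) {
  vapply(seq_len(n), function(i) {
    ch <- strsplit(consensus, "")[[1]]
    hit <- setdiff(which(runif(length(ch)) < noise), keep)
    if (length(hit) > 0) {
      ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    }
    paste(ch, collapse = "")
  }, character(1))
}

# all distinct orderings of the characters of `s` that preserve the
# dinucleotide count vector and both endpoints (brute force, small n only)
valid_dinuc_arrangements <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      for (p in perm_rec(rest)) out[[length(out) + 1]] <- c(u, p)
    }
    out
  }
  mids <- perm_rec(ch[-c(1, n)])
  target <- sort(paste0(ch[-n], ch[-1]))
  hits <- character(0)
  for (m in mids) {
    cand <- c(ch[1], m, ch[n])
    if (identical(sort(paste0(cand[-n], cand[-1])), target)) {
      hits <- union(hits, paste(cand, collapse = ""))
    }
  }
  hits
}
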