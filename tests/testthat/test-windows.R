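test_that("window extraction matches flank geometry and strand symmetry", {
  set.seed(11)
  genome <- c(chrA = random_seq(600))
  site <- site_row_fix(seqname = "chrA", jp = 300L)
  w <- extract_window(genome, site, flank = 70)
  expect_equal(nchar(w$sequence), 141L)
  w61 <- extract_window(genome, site, flank = 30)
  expect_equal(nchar(w61$sequence), 61L)

  # '-' strand window is the reverse complement of the '+' extraction
  site_m <- site_row_fix(seqname = "chrA", jp = 300L, strand = "-")
  wm <- extract_window(genome, site_m, flank = 70)
  expect_equal(wm$sequence,
               spliceGC:::revcomp(w$sequence))

  # deterministic re-extraction
  expect_identical(extract_window(genome, site, 70)$sequence, w$sequence)

  # out-of-bounds sites are dropped with a warning in batch mode
  far <- site_row_fix(seqname = "chrA", jp = 10L)
  expect_warning(out <- extract_windows(genome, rbind(site, far), 70),
                 "dropped")
  expect_equal(nrow(out), 1)
  expect_error(extract_window(genome, far, 70), "bounds")
})

test_that("GC metrics count correctly and conserve across halves", {
  expect_equal(gc_count("GGCC"), 4L)
  expect_equal(gc_count("ATAT"), 0L)
  set.seed(12)
  s <- random_seq(141)
  expect_equal(gc_count(s),
               sum(strsplit(s, "")[[1]] %in% c("G", "C")))

  genome <- c(chrA = random_seq(600, gc = 0.6))
  sites <- rbind(site_row_fix("chrA", jp = 250L, side = "donor"),
                 site_row_fix("chrA", jp = 320L, side = "acceptor"),
                 site_row_fix("chrA", strand = "-", jp = 280L,
                              side = "donor"))
  w <- extract_windows(genome, sites, flank = 70)
  expect_equal(w$gc_number,
               vapply(w$exonic_half, gc_count, integer(1),
                      USE.NAMES = FALSE) +
               vapply(w$intronic_half, gc_count, integer(1),
                      USE.NAMES = FALSE))
  expect_true(all(w$gc_fraction >= 0 & w$gc_fraction <= 1))
  expect_equal(w$gc_fraction, w$gc_number / 141)
  # exonic half is left of center for donors, right for acceptors
  expect_equal(w$exonic_half[1], substr(w$sequence[1], 1, 70))
  expect_equal(w$exonic_half[2], substr(w$sequence[2], 72, 141))
  # N counts as non-GC and is rejected only outside the alphabet
  wN <- w[1, ]
  wN$sequence <- paste0(substr(wN$sequence, 1, 140), "N")
  expect_silent(gc_metrics(wN))
  wbad <- wN
  wbad$sequence <- paste0(substr(wbad$sequence, 1, 140), "X")
  expect_error(gc_metrics(wbad), "invalid")
})

test_that("positional GC profile averages indicators per offset", {
  wG <- data.frame(side = "donor",
                   sequence = strrep("G", 11), stringsAsFactors = FALSE)
  prof <- positional_gc_profile(rbind(wG, wG), flank = 5)
  expect_equal(prof$mean_gc, rep(1, 11))
  expect_equal(range(prof$offset), c(-5, 5))

  wA <- wG; wA$sequence <- strrep("A", 11)
  prof2 <- positional_gc_profile(rbind(wG, wA), flank = 5)
  expect_equal(prof2$mean_gc, rep(0.5, 11))

  # pooled profile equals the n-weighted mean of per-set profiles
  set.seed(13)
  mk <- function(n) data.frame(side = "donor",
                               sequence = vapply(seq_len(n), function(i)
                                 random_seq(11), character(1)),
                               stringsAsFactors = FALSE)
  s1 <- mk(7); s2 <- mk(3)
  p1 <- positional_gc_profile(s1, 5); p2 <- positional_gc_profile(s2, 5)
  pp <- positional_gc_profile(rbind(s1, s2), 5)
  expect_equal(pp$mean_gc, (7 * p1$mean_gc + 3 * p2$mean_gc) / 10)

  # acceptor offsets flip so negative stays exonic
  pa <- positional_gc_profile(
    data.frame(side = "acceptor", sequence = paste0(strrep("A", 6),
                                                    strrep("G", 5)),
               stringsAsFactors = FALSE), flank = 5)
  expect_equal(pa$mean_gc[pa$offset < 0], rep(1, 5))
  expect_error(positional_gc_profile(mk(0), 5))
})

test_that("normalized junction GC is near/wide ratio with NA handling", {
  # uniform GC sequence: ratio exactly 1
  genome <- c(chrA = strrep("GA", 300))
  site <- site_row_fix("chrA", jp = 300L, side = "donor")
  expect_equal(normalized_junction_gc(genome, site), 1)

  # constructed 0.6 / 0.5 ratio = 1.2: donor at jp=200, exon on the left;
  # [150,200) has 30 GC, [100,150) has 20 GC -> 100-bp region has 50 GC
  seqs <- paste0(strrep("A", 100),
                 strrep("G", 20), strrep("A", 30),    # [100,150)
                 strrep("G", 30), strrep("A", 20),    # [150,200)
                 strrep("A", 100))
  g2 <- c(chrB = seqs)
  s2 <- site_row_fix("chrB", jp = 200L, side = "donor")
  expect_equal(normalized_junction_gc(g2, s2), 1.2)

  # zero denominator: NA with warning
  g3 <- c(chrC = strrep("A", 400))
  s3 <- site_row_fix("chrC", jp = 200L)
  expect_warning(r3 <- normalized_junction_gc(g3, s3), "dropped")
  expect_true(is.na(r3))
})
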