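test_that("site model training captures planted consensus", {
  set.seed(201)
  train <- consensus_training(200, "CAGGTAAGT", noise = 0.15,
                              keep = c(4, 5))
  model <- train_site_model(train, "donor")
  # per-position foreground sums to 1
  expect_equal(colSums(model$foreground), rep(1, 9), tolerance = 1e-12)
  # position +1 (index 4) is always G: its weight is the column max
  expect_equal(which.max(model$weights[, 4]), c(G = 3))
  # consensus scores strictly above every single-mismatch variant
  cons_score <- score_site(model, "CAGGTAAGT")
  ch <- strsplit("CAGGTAAGT", "")[[1]]
  for (p in seq_len(9)) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      mut <- ch; mut[p] <- b
      expect_lt(score_site(model, paste(mut, collapse = "")), cons_score)
    }
  }
})

test_that("uniform training gives near-zero weights and scores", {
  set.seed(202)
  train <- vapply(1:400, function(i) random_seq(23), character(1))
  model <- train_site_model(train, "acceptor")
  expect_lt(max(abs(model$weights)), 0.5)
  expect_lt(abs(score_site(model, random_seq(23))), 3)
  # additivity: the score is the sum of per-position weights
  s <- random_seq(23)
  ch <- strsplit(s, "")[[1]]
  manual <- sum(vapply(seq_len(23), function(p) model$weights[ch[p], p],
                       numeric(1)))
  expect_equal(score_site(model, s), manual)
})

test_that("training input validation", {
  expect_error(train_site_model(rep("CAGGTAAGT", 10), "donor"),
               "at least")
  expect_error(train_site_model(rep("CAGGT", 60), "donor"), "width")
  set.seed(203)
  model <- train_site_model(consensus_training(60, "CAGGTAAGT"), "donor")
  expect_error(score_site(model, "CAGG"), "length")
})

test_that("site models serialize and score identically after round-trip", {
  set.seed(207)
  model <- train_site_model(
    consensus_training(80, "CAGGTAAGT", noise = 0.2, keep = c(4, 5)),
    "donor")
  f <- tempfile(fileext = ".tsv")
  write_site_model(model, f)
  back <- read_site_model(f)
  probe <- vapply(1:20, function(i) random_seq(9), character(1))
  expect_equal(score_site(back, probe), score_site(model, probe),
               tolerance = 1e-8)
  expect_equal(back$side, "donor")
})

test_that("find_decoy picks the nearest qualifying GT in the zone", {
  set.seed(204)
  model <- train_site_model(
    consensus_training(100, "CAGGTAAGT", noise = 0.1, keep = c(4, 5)),
    "donor")
  # background with no GT anywhere; real donor at jp = 500 on '+'
  base <- strsplit(strrep("A", 1200), "")[[1]]
  plant <- function(ch, jp) {
    ch[(jp - 3 + 1):(jp + 6)] <- strsplit("CAGGTAAGT", "")[[1]]
    ch
  }
  jp <- 500L
  ch <- plant(base, jp)
  ch <- plant(ch, jp + 160L)
  ch <- plant(ch, jp + 290L)
  genome <- c(chr = paste(ch, collapse = ""))
  real <- site_row_fix("chr", jp = jp, side = "donor")
  hit <- find_decoy(genome, real, model)
  expect_equal(hit$distance, 160L)
  expect_equal(hit$decoy_junction, jp + 160L)
  expect_gte(hit$decoy_score, 0)

  # candidate at 140 nt only: outside the zone
  ch2 <- plant(plant(base, jp), jp + 140L)
  expect_null(find_decoy(c(chr = paste(ch2, collapse = "")), real, model))

  # no GT in the zone at all
  ch3 <- plant(base, jp)
  expect_null(find_decoy(c(chr = paste(ch3, collapse = "")), real, model))

  # zone clamped below its start: warning + NULL
  g <- c(chr = paste(ch, collapse = ""))
  expect_warning(none <- find_decoy(g, real, model, max_distance = 100),
                 "zone")
  expect_null(none)
})

test_that("acceptor decoys scan the upstream intron in sense orientation", {
  set.seed(205)
  acc_cons <- "TTTCTTTTTTTTTTTCTCAGGCA"
  model <- train_site_model(
    consensus_training(100, acc_cons, noise = 0.1, keep = c(19, 20)),
    "acceptor")
  base <- strsplit(strrep("T", 1200), "")[[1]]
  plant <- function(ch, jp) {
    ch[(jp - 19 + 1):(jp + 4)] <- strsplit(acc_cons, "")[[1]]
    ch
  }
  jp <- 700L
  ch <- plant(plant(base, jp), jp - 200L)
  genome <- c(chr = paste(ch, collapse = ""))
  real <- site_row_fix("chr", jp = jp, side = "acceptor")
  hit <- find_decoy(genome, real, model)
  expect_equal(hit$distance, 200L)
  expect_equal(hit$decoy_junction, jp - 200L)
})

test_that("decoy selection is deterministic and respects constraints", {
  set.seed(206)
  syn <- generate_genome_annotation(synthetic_config(seed = 33,
                                                     n_genes = 12))
  sites <- classify_splice_sites(syn$models)
  don <- sites[sites$side == "donor", ]
  dseq <- extract_site_sequence(syn$genome, don)
  model <- train_site_model(dseq[!is.na(dseq)], "donor")
  hosts <- syn$truth[!is.na(syn$truth$decoy_junction) &
                       syn$truth$side == "donor", ]
  p1 <- find_decoys(syn$genome, hosts, model)
  p2 <- find_decoys(syn$genome, hosts, model)
  expect_identical(p1, p2)
  expect_true(all(p1$distance >= 150 & p1$distance <= 300))
  # every decoy junction carries a sense-strand GT
  w <- extract_windows(syn$genome,
                       data.frame(seqname = p1$seqname, strand = p1$strand,
                                  side = p1$side,
                                  junction_pos = p1$decoy_junction),
                       flank = 10, warn_oob = FALSE)
  expect_true(all(substr(w$sequence, 11, 12) == "GT"))
})

test_that("paired comparison demands enough pairs and handles degeneracy", {
  one <- data.frame(seqname = "chr", strand = "+", side = "donor",
                    real_junction = 500L, decoy_junction = 700L,
                    distance = 200L, real_score = 1, decoy_score = 1)
  expect_error(paired_decoy_comparison(c(chr = strrep("A", 1000)), one),
               "at least 10")
  # identical diffs of zero: p = 1
  res <- signed_rank_test(rep(0, 12))
  expect_equal(res$p_value, 1)
})
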