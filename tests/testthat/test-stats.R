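test_that("rank-sum exact mode matches enumeration and base R", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # 2 of the 20 rank assignments as extreme
  expect_equal(r$method, "rank-sum exact")
  set.seed(401)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb)  # continuous: tie-free
    mine <- rank_sum_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    g <- rank_sum_test(a, b, alternative = "greater")
    refg <- wilcox.test(a, b, exact = TRUE, alternative = "greater")
    expect_equal(g$p_value, refg$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum approximate mode matches base R without correction", {
  set.seed(402)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  mine <- rank_sum_test(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # with ties, the tie-corrected variance is used
  at <- round(rnorm(30), 1); bt <- round(rnorm(25, 0.5), 1)
  ref_t <- suppressWarnings(wilcox.test(at, bt, exact = FALSE,
                                        correct = FALSE))
  expect_equal(rank_sum_test(at, bt)$p_value, ref_t$p.value,
               tolerance = 1e-10)
  # degenerate identical samples
  expect_equal(rank_sum_test(rep(2, 5), rep(2, 9))$p_value, 1)
})

test_that("signed-rank exact and approximate modes are calibrated", {
  r <- signed_rank_test(rep(1, 10), alternative = "greater")
  expect_equal(r$p_value, 1 / 1024)
  expect_equal(signed_rank_test(rep(0, 8))$p_value, 1)
  # antisymmetric differences put the statistic at the null center
  d <- c(1.5, -1.5, 0.7, -0.7, 2.2, -2.2)
  r2 <- signed_rank_test(d)
  expect_equal(r2$statistic, length(d) * (length(d) + 1) / 4)
  set.seed(403)
  for (i in 1:15) {
    d <- rnorm(sample(6:11, 1))
    mine <- signed_rank_test(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  d30 <- rnorm(30, 0.3)
  ref30 <- wilcox.test(d30, exact = FALSE, correct = FALSE)
  expect_equal(signed_rank_test(d30)$p_value, ref30$p.value,
               tolerance = 1e-10)
})

test_that("GC-energy regression returns exact fits on exact lines", {
  r <- gc_energy_regression(c(0, 1, 2), c(0, -2, -4))
  expect_equal(r$slope, -2)
  expect_equal(r$intercept, 0)
  expect_equal(r$pearson_r, -1)
  expect_equal(r$r_squared, 1)
  set.seed(404)
  gc <- runif(50); mfe <- -3 * gc + rnorm(50, sd = 0.2)
  rr <- gc_energy_regression(gc, mfe)
  expect_equal(sign(rr$pearson_r), sign(rr$slope))
  expect_equal(rr$r_squared, rr$pearson_r^2)
  expect_error(gc_energy_regression(rep(0.5, 10), rnorm(10)), "constant")
  expect_error(gc_energy_regression(c(0, 1), c(1, 2)), "at least 3")
})

test_that("GC-matched bins separate composition from category effects", {
  set.seed(405)
  n <- 1000  # enough windows for ~15-20 tested bins, so the 80% bound
             # has negligible false-failure probability under the null
  mfe <- function(g) -0.5 * g + rnorm(length(g), sd = 2)
  # identical per-bin distributions: the within-bin null is exactly true
  gc_a <- round(rnorm(n, 70, 10)); gc_b <- round(rnorm(n, 70, 10))
  res0 <- gc_matched_compare(c(mfe(gc_a), mfe(gc_b)),
                             rep(c("A", "B"), each = n),
                             c(gc_a, gc_b), min_per_group = 10)
  t0 <- res0[res0$tested, ]
  expect_gt(nrow(t0), 2)
  expect_gte(mean(t0$p_value > 0.05), 0.8)

  # groups differing only through GC composition: the unmatched test is
  # strongly significant while matching on GC absorbs most of the signal
  gc_b2 <- round(rnorm(n, 75, 10))
  values <- c(mfe(gc_a), mfe(gc_b2))
  groups <- rep(c("A", "B"), each = n)
  expect_lt(rank_sum_test(values[groups == "A"],
                          values[groups == "B"])$p_value, 1e-6)
  res <- gc_matched_compare(values, groups, c(gc_a, gc_b2),
                            min_per_group = 10)
  tested <- res[res$tested, ]
  expect_gte(mean(tested$p_value > 0.05), 0.5)
  # bins with too few members are reported, not tested
  expect_true(all(!res$tested[is.na(res$p_value)]))
  expect_error(gc_matched_compare(rnorm(4), rep(c("A", "B"), 2),
                                  c(10, 11, 90, 91)),
               "no testable")
})

test_that("distance-controlled pairing respects the 3000-nt radius", {
  alt <- data.frame(seqname = "c1", strand = "+", side = "donor",
                    junction_pos = c(10000L, 50000L), value = c(-40, -42))
  ref <- data.frame(seqname = "c1", strand = "+", side = "donor",
                    junction_pos = c(12900L, 53100L), value = c(-39, -41))
  res <- distance_controlled_pairs(alt, ref)
  expect_equal(nrow(res$pairs), 1)       # 2900 paired, 3100 excluded
  expect_equal(res$pairs$distance, 2900L)
  # equidistant references: upstream one wins
  ref2 <- data.frame(seqname = "c1", strand = "+", side = "donor",
                     junction_pos = c(9000L, 11000L), value = c(-1, -2))
  res2 <- distance_controlled_pairs(alt[1, ], ref2)
  expect_equal(res2$pairs$ref_index, 1L)
  expect_error(distance_controlled_pairs(alt, ref, max_dist = 10L),
               "no pairs")
})

test_that("tissue rule partitions events into three disjoint classes", {
  ev <- function(id, delta, p) data.frame(event_id = id, tissue = "t1",
                                          delta = delta, p_value = p)
  e <- rbind(ev("spec", 0.12, 0.2),
             ev("non", 0.03, 0.5),
             ev("gap", 0.07, 0.2),
             ev("hi_p", 0.2, 0.5),       # big delta but p too large
             ev("boundary", 0.10, 0.29)) # closed boundary on delta
  cls <- classify_tissue_specific(e)
  got <- setNames(cls$class, cls$event_id)
  expect_equal(unname(got["spec"]), "tissue_specific")
  expect_equal(unname(got["non"]), "non_tissue_specific")
  expect_equal(unname(got["gap"]), "unclassified")
  expect_equal(unname(got["hi_p"]), "non_tissue_specific")
  expect_equal(unname(got["boundary"]), "tissue_specific")
  # ANY-quantifier: one qualifying tissue suffices
  multi <- rbind(ev("m", 0.02, 0.9), ev("m", 0.15, 0.1))
  expect_equal(classify_tissue_specific(multi)$class, "tissue_specific")
  expect_error(classify_tissue_specific(e[0, ]), "empty")
})
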