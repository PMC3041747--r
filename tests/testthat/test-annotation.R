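test_that("load_annotation parses GTF and BED12 and canonicalizes order", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t2001\t2100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  models <- load_annotation(gtf, "gtf")
  expect_s3_class(models, "transcript_models")
  expect_equal(nrow(models), 3)
  expect_equal(models$start, c(0L, 1000L, 2000L))  # sorted, 0-based
  expect_equal(models$end, c(100L, 1200L, 2100L))

  bed <- tempfile(fileext = ".bed")
  writeLines(paste(
    "chr1", 0, 2100, "g1|t1", 0, "+", 0, 2100, "0",
    3, "100,200,100", "0,1000,2000", sep = "\t"), bed)
  mb <- load_annotation(bed, "bed12")
  expect_equal(nrow(mb), 3)
  expect_equal(mb$gene_id, rep("g1", 3))
  expect_equal(mb$transcript_id, rep("t1", 3))
  expect_equal(mb$start, c(0L, 1000L, 2000L))
  expect_equal(mb$end, c(100L, 1200L, 2100L))

  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_warning(me <- load_annotation(empty, "gtf"))
  expect_equal(nrow(me), 0)
})

test_that("overlapping exons within a transcript are rejected", {
  df <- data.frame(seqname = "chr1", strand = "+",
                   start = c(0, 50), end = c(100, 150),
                   gene_id = "g", transcript_id = "t")
  expect_error(as_transcript_models(df), "overlapping")
})

test_that("constitutive sites need >= 4 isoforms, identity, and no overlap", {
  g4 <- constitutive_gene(4)
  sites <- find_constitutive_sites(g4)
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$side, c("donor", "acceptor"))
  expect_equal(sites$junction_pos[sites$side == "donor"], 1200L)
  expect_equal(sites$junction_pos[sites$side == "acceptor"], 999L)
  expect_true(all(sites$category == "constitutive"))

  # only 3 isoforms: empty
  expect_equal(nrow(find_constitutive_sites(constitutive_gene(3))), 0)

  # overlapped by a longer exon variant: excluded
  isos <- lapply(1:4, function(i) {
    list(c(0, 100), c(1000, 1200), c(2000 + 10 * i, 2100 + 10 * i))
  })
  names(isos) <- paste0("tx", 1:4)
  isos$tx4 <- list(c(0, 100), c(950, 1200), c(2040, 2140))
  g <- gene_df(isos)
  expect_equal(nrow(find_constitutive_sites(g)), 0)
})

test_that("constitutive classification is invariant to isoform order", {
  g <- constitutive_gene(4)
  ref <- find_constitutive_sites(g)
  for (i in 1:5) {
    perm <- g[sample.int(nrow(g)), ]
    got <- find_constitutive_sites(as_transcript_models(as.data.frame(perm)))
    expect_equal(got[order(got$junction_pos), ],
                 ref[order(ref$junction_pos), ], ignore_attr = TRUE)
  }
})

test_that("alternative-site distance filters follow the 5/8 bp rules", {
  alt_gene <- function(shift, vary = c("donor", "acceptor")) {
    vary <- match.arg(vary)
    e2a <- c(1000, 1200)
    e2b <- if (vary == "donor") c(1000, 1200 + shift)
           else c(1000 - shift, 1200)
    gene_df(list(
      tx1 = list(c(0, 100), e2a, c(2000, 2100)),
      tx2 = list(c(0, 100), e2b, c(2000, 2100))
    ))
  }
  # two donors 5 bp apart: both emitted
  s5 <- find_alternative_sites(alt_gene(5, "donor"))
  expect_equal(sort(s5$junction_pos[s5$side == "donor"]), c(1200L, 1205L))
  # 4 bp apart: none
  expect_equal(nrow(find_alternative_sites(alt_gene(4, "donor"))), 0)
  # two acceptors 8 bp apart: both; 7 bp: none
  s8 <- find_alternative_sites(alt_gene(8, "acceptor"))
  expect_equal(sort(s8$junction_pos[s8$side == "acceptor"]),
               c(991L, 999L))
  expect_equal(nrow(find_alternative_sites(alt_gene(7, "acceptor"))), 0)
})

test_that("cassette exons require retained flanks in the skipping isoform", {
  g <- gene_df(list(
    tx1 = list(c(0, 100), c(1000, 1100), c(2000, 2100)),
    tx2 = list(c(0, 100), c(2000, 2100))
  ))
  sk <- find_skipped_sites(g)
  expect_equal(nrow(sk), 2)
  expect_setequal(sk$side, c("donor", "acceptor"))
  expect_true(all(sk$category == "skipped"))
  expect_true(all(sk$exon_start == 1000 & sk$exon_end == 1100))

  # transcript merely ending earlier does not make the exon skipped
  g2 <- gene_df(list(
    tx1 = list(c(0, 100), c(1000, 1100), c(2000, 2100)),
    tx2 = list(c(0, 100))
  ))
  expect_equal(nrow(find_skipped_sites(g2)), 0)

  # exon present in all isoforms is not skipped
  g3 <- gene_df(list(
    tx1 = list(c(0, 100), c(1000, 1100), c(2000, 2100)),
    tx2 = list(c(0, 100), c(1000, 1100), c(2000, 2100))
  ))
  expect_equal(nrow(find_skipped_sites(g3)), 0)
})

test_that("first-exon donors split into constitutive and alternative", {
  shared <- list(c(1000, 1100), c(2000, 2100))
  g_const <- gene_df(list(
    tx1 = c(list(c(0, 100)), shared),
    tx2 = c(list(c(0, 100)), shared),
    tx3 = c(list(c(0, 100)), shared)
  ))
  fc <- classify_first_donor_sites(g_const)
  expect_equal(fc$category, "first_constitutive")
  expect_equal(fc$junction_pos, 100L)

  g_alt <- gene_df(list(
    tx1 = c(list(c(0, 100)), shared),
    tx2 = c(list(c(0, 100)), shared),
    tx3 = c(list(c(0, 106)), shared)
  ))
  fa <- classify_first_donor_sites(g_alt)
  expect_equal(sort(fa$junction_pos), c(100L, 106L))
  expect_true(all(fa$category == "first_alternative"))

  # isoforms with different TSS: gene excluded
  g_tss <- gene_df(list(
    tx1 = c(list(c(0, 100)), shared),
    tx2 = c(list(c(0, 100)), shared),
    tx3 = c(list(c(10, 100)), shared)
  ))
  expect_equal(nrow(classify_first_donor_sites(g_tss)), 0)
})

test_that("exon length class boundary sits at 200 bp", {
  expect_equal(exon_length_class(c(201, 200, 1)),
               c("long", "short", "short"))
})

test_that("category lists are duplicate-free and strand-aware", {
  g_minus <- constitutive_gene(4, strand = "-")
  s <- find_constitutive_sites(g_minus)
  expect_equal(nrow(s), 2)
  # on '-' the donor is at the genomic left edge of the exon
  expect_equal(s$junction_pos[s$side == "donor"], 999L)
  expect_equal(s$junction_pos[s$side == "acceptor"], 1200L)
  all_sites <- classify_splice_sites(constitutive_gene(4))
  key <- paste(all_sites$seqname, all_sites$strand, all_sites$side,
               all_sites$junction_pos, all_sites$category)
  expect_equal(anyDuplicated(key), 0L)
})
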