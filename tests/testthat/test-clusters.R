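mk_sites <- function(starts, lengths, mirna = NULL, region = "5UTR") {
  n <- length(starts)
  data.frame(
    mirna_id = if (is.null(mirna)) sprintf("m%02d", seq_len(n)) else
      rep_len(mirna, n),
    transcript_id = "tx1", gene = "G1", rpkm = 1,
    start = as.integer(starts), length = as.integer(rep_len(lengths, n)),
    delta_g = -100, ratio = 90, region = region,
    stringsAsFactors = FALSE
  )
}

test_that("overlapping intervals merge and disjoint ones do not", {
  cl <- build_clusters(mk_sites(c(3, 12), c(23, 24)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$span_start, 3L)
  expect_identical(cl$span_end, 35L)

  cl2 <- build_clusters(mk_sites(c(1, 30), 22))
  expect_identical(nrow(cl2), 2L)
  expect_identical(cl2$n_sites, c(1L, 1L))
  expect_equal(cl2$compaction, c(1, 1))
})

test_that("adjacent but non-overlapping sites stay separate clusters", {
  # [1,22] and [23,44] share no position
  cl <- build_clusters(mk_sites(c(1, 23), 22))
  expect_identical(nrow(cl), 2L)
  # [1,22] and [22,43] share position 22
  cl2 <- build_clusters(mk_sites(c(1, 22), 22))
  expect_identical(nrow(cl2), 1L)
})

test_that("cluster spans partition the union of site intervals", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    starts <- sample(500, n, replace = TRUE)
    lengths <- sample(18:26, n, replace = TRUE)
    sites <- mk_sites(starts, lengths)
    cl <- build_clusters(sites)
    # conservation of total site length
    expect_identical(sum(cl$total_site_length), sum(sites$length))
    # spans pairwise disjoint and sorted
    if (nrow(cl) > 1L) {
      expect_true(all(cl$span_start[-1] > cl$span_end[-nrow(cl)]))
    }
    # union of spans = union of site intervals
    covered <- unlist(lapply(seq_len(nrow(cl)), function(k)
      cl$span_start[[k]]:cl$span_end[[k]]))
    truth <- sort(unique(unlist(lapply(seq_len(n), function(k)
      starts[[k]]:(starts[[k]] + lengths[[k]] - 1L)))))
    expect_identical(sort(covered), truth)
    # membership agrees with the O(n^2) closure oracle
    want <- oracle_clusters(sites$start, sites$length)
    got <- integer(n)
    for (k in seq_len(nrow(cl))) got[cl$members[[k]]] <- k
    expect_identical(got, want)
  }
})

test_that("compaction is 1 exactly for tilings and > 1 under overlap", {
  tiling <- compaction_stats(c(1, 23, 45), 22)
  expect_equal(tiling$compaction, 1)
  overlapping <- compaction_stats(c(1, 12), 22)
  expect_gt(overlapping$compaction, 1)
  single <- compaction_stats(10, 22)
  expect_identical(single$total_site_length, 22L)
  expect_identical(single$span_length, 22L)
  expect_equal(single$compaction, 1)
})

test_that("reported 5'UTR tables reproduce the printed cluster totals", {
  rep5 <- reported_sites_long("5UTR")
  gsk <- rep5[rep5$gene == "GSK3B", ]
  expect_identical(nrow(gsk), 28L)  # 22 table rows, multi-start expanded
  cl <- build_clusters(gsk)
  expect_identical(nrow(cl), 1L)   # one cluster: starts 3..15 all overlap
  expect_identical(cl$total_site_length, 624L)
  expect_identical(cl$distinct_mirna_count, 21L)

  ccny <- rep5[rep5$gene == "CCNY", ]
  first <- ccny[ccny$start + ccny$length - 1L <= 30L, ]
  expect_identical(nrow(first), 9L)
  st <- compaction_stats(first$start, first$length)
  expect_identical(st$total_site_length, 206L)
  expect_identical(st$span_length, 30L)
  expect_equal(st$compaction_1dp, 6.9)
})

test_that("reported CDS tables reproduce the FOXO1 and SETD1A clusters", {
  repc <- reported_sites_long("CDS")
  fox <- repc[repc$gene == "FOXO1" & repc$start >= 655 & repc$start <= 695, ]
  expect_identical(nrow(fox), 6L)  # five table rows, one with two starts
  st <- compaction_stats(fox$start, fox$length,
                         span_start = 655, span_end = 695)
  expect_identical(st$total_site_length, 137L)
  expect_equal(st$compaction_1dp, 3.3)

  setd <- repc[repc$gene == "SETD1A" & repc$start >= 4877 &
                 repc$start <= 4928, ]
  st2 <- compaction_stats(setd$start, setd$length,
                          span_start = 4877, span_end = 4928)
  expect_identical(st2$total_site_length, 205L)
  expect_equal(round(st2$compaction), 4)
})

test_that("offset patterns find the recurrent 6/74/99 nt spacings", {
  rep3 <- reported_sites_long("3UTR")
  off6 <- offset_patterns(rep3, list(c("miR-5095", "miR-619-5p")))
  expect_true(all(off6$offset == 6))
  expect_true(all(off6$constant))
  expect_setequal(off6$gene, c("LRP10", "RBBP5", "SLC14A1"))

  two <- rep3[rep3$gene %in% c("RBBP5", "SLC14A1"), ]
  off74 <- offset_patterns(two, list(c("miR-619-5p", "miR-5096")))
  expect_true(all(off74$offset == 74))
  expect_true(all(off74$constant))

  off99 <- offset_patterns(rep3, list(c("miR-5585-3p", "miR-1285-5p")))
  expect_true(all(off99$offset == 99))
  expect_true(all(off99$constant))
  expect_setequal(off99$gene, c("LRP10", "PDP2"))
})

test_that("offset patterns handle identical starts and missing partners", {
  sites <- mk_sites(c(10, 10, 50), 22, mirna = c("a", "b", "a"))
  sites$gene <- c("G1", "G1", "G2")
  off <- offset_patterns(sites, list(c("a", "b")))
  expect_identical(off$offset, 0L)
  skipped <- attr(off, "skipped")
  expect_identical(skipped$gene, "G2")
})

test_that("region summary counts sites, clusters and multi-miRNA genes", {
  s1 <- mk_sites(c(1, 5, 40), 22, region = "5UTR")
  s2 <- mk_sites(c(500, 600), 22, region = "3UTR",
                 mirna = c("mx", "mx"))
  s2$transcript_id <- "tx2"; s2$gene <- "G2"
  sites <- rbind(s1, s2)
  sm <- summarize_by_region(sites)
  r5 <- sm$regions[sm$regions$region == "5UTR", ]
  expect_identical(r5$n_sites, 3L)
  expect_identical(r5$n_clusters, 2L)
  expect_identical(r5$n_multi_clusters, 1L)
  r3 <- sm$regions[sm$regions$region == "3UTR", ]
  expect_identical(r3$n_clusters, 2L)
  expect_identical(r3$n_multi_clusters, 0L)
  expect_true(sm$genes$multi_mirna[sm$genes$gene == "G1"])
  expect_false(sm$genes$multi_mirna[sm$genes$gene == "G2"])
})
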