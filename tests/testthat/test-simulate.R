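test_that("sequence generators respect parameters and the seed", {
  set.seed(71)
  gc_rich <- gen_mirna(20, 0.95)
  expect_identical(nchar(gc_rich), 20L)
  expect_gte(max_bonds(gc_rich), 56L)  # at least 18 of 20 are G/C in expectation
  au_only <- gen_mirna(22, 0)
  expect_identical(max_bonds(au_only), 44L)
  expect_error(gen_mirna(10, 0.5), class = "mirbind_config_error")
  expect_error(gen_mirna(22, 1.2), class = "mirbind_config_error")

  set.seed(5); a <- gen_mirna(22, 0.5)
  set.seed(5); b <- gen_mirna(22, 0.5)
  expect_identical(a, b)
})

test_that("plant_site reaches the target band and records ground truth", {
  set.seed(72)
  host <- random_rna(400, 0.5)
  for (target in c(100, 95, 90, 85)) {
    m <- random_rna(22, runif(1, 0.3, 0.8))
    pl <- plant_site(host, m, 100L, target)
    expect_lte(abs(pl$achieved_ratio - target), 1.5)
    # re-scoring the planted window recovers the recorded ratio
    w <- substr(pl$sequence, 100, 121)
    expect_equal(score_window(m, w)$ratio, pl$achieved_ratio)
    # the rest of the host is untouched
    expect_identical(substr(pl$sequence, 1, 99), substr(host, 1, 99))
    expect_identical(substr(pl$sequence, 122, 400), substr(host, 122, 400))
  }
  expect_error(plant_site(host, random_rna(22, 0.5), 390L, 95),
               class = "mirbind_generation_error")
  expect_error(plant_site(host, random_rna(22, 0.5), 10L, 60),
               class = "mirbind_config_error")
})

test_that("target 100 plants the exact reverse complement", {
  set.seed(73)
  m <- random_rna(22, 0.6)
  pl <- plant_site(random_rna(100, 0.5), m, 10L, 100)
  expect_identical(substr(pl$sequence, 10, 31), revcomp_rna(m))
  expect_equal(pl$achieved_ratio, 100)
})

test_that("ortholog generation preserves flanks and honors the rates", {
  set.seed(74)
  cluster <- random_rna(60, 0.6)
  ref <- paste0("UGCGGG", cluster, "CCGAG")
  # zero substitution rate: everything identical
  os0 <- gen_ortholog_set(ref, c("hsa", "ptr", "mmu"), sub_rate = 0)
  expect_true(all(os0$segments == ref))
  # transition-only divergence: no transversions, no indels, flanks intact
  os1 <- gen_ortholog_set(ref, c("hsa", "ptr", "ggo", "mmu", "bta"),
                          sub_rate = 0.15, transition_fraction = 1,
                          flanks = c("UGCGGG", "CCGAG"))
  for (sp in c("ptr", "ggo", "mmu", "bta")) {
    seg <- os1$segments[[sp]]
    expect_identical(substr(seg, 1, 6), "UGCGGG")
    expect_identical(substr(seg, nchar(seg) - 4, nchar(seg)), "CCGAG")
    counts <- classify_substitutions(ref, seg)$counts
    expect_identical(counts[["transversion"]], 0L)
    expect_identical(counts[["indel"]], 0L)
  }
  expect_error(gen_ortholog_set(ref, c("hsa", "ptr"), 0.1,
                                flanks = "AAAAAAAAAAAA"),
               class = "mirbind_generation_error")
})

test_that("transition-only divergence keeps canonical positions bonded", {
  # planted site, then transition-substituted copies: every originally
  # canonical pair retains >= 1 bond through the wobble/A-C backstop
  set.seed(75)
  m <- random_rna(22, 0.6)
  site <- revcomp_rna(m)
  q_rev <- rev(strsplit(m, "")[[1]])
  for (i in 1:20) {
    os <- gen_ortholog_set(site, c("hsa", "ptr"), sub_rate = 0.4,
                           transition_fraction = 1)
    w <- strsplit(os$segments[["ptr"]], "")[[1]]
    bonds <- vapply(seq_along(w), function(k)
      pair_bonds(w[[k]], q_rev[[k]]), integer(1))
    expect_true(all(bonds >= 1L))
    # and the re-scored ratio stays at or above the all-wobble floor
    mb <- max_bonds(m)
    expect_gte(score_window(m, os$segments[["ptr"]])$ratio, 100 * 22 / mb)
  }
})

test_that("cohort generation is deterministic and internally consistent", {
  cfg <- default_sim_config(seed = 99, n_genes = 6L, n_planted_sites = 12L)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_identical(c1$mirnas, c2$mirnas)
  expect_identical(c1$transcripts, c2$transcripts)
  expect_identical(c1$truth$planted_sites, c2$truth$planted_sites)

  # every transcript satisfies the coordinate invariants
  for (i in seq_len(nrow(c1$transcripts))) {
    expect_silent(validate_transcript(c1$transcripts[i, ]))
  }
  # planted achieved ratios honor the +/- 1.5 band
  tr <- c1$truth$planted_sites
  expect_true(all(abs(tr$achieved_ratio - tr$target_ratio) <= 1.5))
  # RPKM values span the configured regimes
  expect_true(all(c1$transcripts$rpkm >= 0.1))
  expect_true(any(c1$transcripts$rpkm > 43))
})

test_that("cohort files round-trip through the io layer byte-identically", {
  cfg <- default_sim_config(seed = 17, n_genes = 5L, n_planted_sites = 10L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_cohort(cfg, outdir = d1)
  gen_cohort(cfg, outdir = d2)
  for (f in c("mirnas.fasta", "transcripts.fasta", "annotations.tsv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  mirnas <- read_fasta(file.path(d1, "mirnas.fasta"))
  tx <- read_transcript_table(file.path(d1, "annotations.tsv"),
                              read_fasta(file.path(d1, "transcripts.fasta")))
  expect_identical(nrow(tx), 5L)
  expect_gt(nrow(mirnas), 10L)
})

test_that("scanner and cluster analysis recover the generated ground truth", {
  coh <- gen_cohort(default_sim_config(seed = 31, n_genes = 8L,
                                       n_planted_sites = 24L))
  sites <- scan_cohort(coh$mirnas, coh$transcripts)
  tr <- coh$truth$planted_sites
  found <- 0L
  for (i in seq_len(nrow(tr))) {
    s <- sites[sites$mirna_id == tr$mirna_id[[i]] &
                 sites$gene == tr$gene[[i]] &
                 sites$start == tr$start[[i]], ]
    if (nrow(s) == 1L && abs(s$ratio - tr$target_ratio[[i]]) <= 1.5) {
      found <- found + 1L
      expect_identical(s$region, tr$region[[i]])
    }
  }
  expect_gte(found / nrow(tr), 0.95)

  # polysite run recovered with the configured count and spacing
  pt <- coh$truth$polysite
  ps <- sites[sites$mirna_id == pt$mirna_id &
                sites$transcript_id == pt$transcript_id, ]
  gp <- group_polysites(ps)
  expect_identical(nrow(gp), 1L)
  expect_identical(gp$count, pt$count)
  expect_identical(gp$starts[[1]], pt$starts)

  # offset pairs recovered exactly and constant across genes
  ot <- coh$truth$offset_pairs
  for (pair_key in unique(paste(ot$mirna_a, ot$mirna_b))) {
    sub <- ot[paste(ot$mirna_a, ot$mirna_b) == pair_key, ]
    off <- offset_patterns(sites, list(c(sub$mirna_a[[1]],
                                         sub$mirna_b[[1]])))
    expect_true(all(off$constant))
    expect_setequal(off$gene, sub$gene)
    expect_identical(unique(off$offset), unique(sub$offset))
  }

  # clusters derived from the ground-truth intervals match build_clusters
  # on the scanned sites, transcript by transcript
  L <- 22L
  for (txid in unique(coh$transcripts$transcript_id)) {
    gene <- coh$transcripts$gene[coh$transcripts$transcript_id == txid]
    truth_iv <- rbind(
      {  # planted singles that scored at or above the report threshold
        p <- tr[tr$transcript_id == txid & tr$achieved_ratio >= 85 - 1e-9, ]
        if (nrow(p) > 0L) p[, c("start", "length")] else NULL
      },
      if (pt$transcript_id == txid)
        data.frame(start = pt$starts, length = L) else NULL,
      {
        o <- ot[ot$gene == gene, ]
        if (nrow(o) > 0L) data.frame(start = c(o$start_a, o$start_b),
                                     length = L) else NULL
      }
    )
    if (is.null(truth_iv) || nrow(truth_iv) == 0L) next
    truth_sites <- data.frame(
      mirna_id = "truth", transcript_id = txid, start = truth_iv$start,
      length = truth_iv$length, region = "x", stringsAsFactors = FALSE
    )
    want <- build_clusters(truth_sites)
    got <- build_clusters(sites[sites$transcript_id == txid, ])
    expect_identical(got$span_start, want$span_start)
    expect_identical(got$span_end, want$span_end)
    expect_identical(got$total_site_length, want$total_site_length)
  }
})

test_that("an empty cohort is valid", {
  coh <- gen_cohort(default_sim_config(seed = 1, n_genes = 0L,
                                       n_planted_sites = 0L))
  expect_identical(nrow(coh$transcripts), 0L)
  expect_identical(nrow(coh$mirnas), 0L)
})
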