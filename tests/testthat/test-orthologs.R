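test_that("ortholog sets validate species, reference and segments", {
  expect_error(ortholog_set("L", c(hsa = "ACGU")),
               class = "mirbind_validation_error")
  expect_error(ortholog_set("L", c(hsa = "ACGU", ptr = "")),
               class = "mirbind_validation_error")
  expect_error(ortholog_set("L", c(hsa = "ACGU", ptr = "ACGU"),
                            reference_species = "mmu"),
               class = "mirbind_validation_error")
  os <- ortholog_set("L", c(hsa = "acgt", ptr = "ACGU"))
  expect_identical(os$segments[["hsa"]], "ACGU")
})

test_that("conserved flanks are recovered exactly when planted at segment edges", {
  set.seed(51)
  cluster <- random_rna(30, 0.6)
  ref <- paste0("UGCGGG", cluster, "CCGAG")
  os <- gen_ortholog_set(ref, species = c("hsa", "ptr", "ggo", "mmu"),
                         sub_rate = 0.15, transition_fraction = 1,
                         flanks = c("UGCGGG", "CCGAG"))
  fl <- conserved_flanks(os, 7L, 36L)
  expect_identical(fl$flank5, "UGCGGG")
  expect_identical(fl$flank3, "CCGAG")
})

test_that("identical segments give max_len flanks; full divergence gives none", {
  seg <- strrep("ACGU", 20)
  os <- ortholog_set("L", c(hsa = seg, ptr = seg))
  fl <- conserved_flanks(os, 31L, 50L, max_len = 10L)
  expect_identical(nchar(fl$flank5), 10L)
  expect_identical(nchar(fl$flank3), 10L)
  # a partner sharing no oligonucleotide at all (disjoint alphabet use)
  os2 <- ortholog_set("L", c(hsa = strrep("A", 40), ptr = strrep("G", 40)))
  fl2 <- conserved_flanks(os2, 15L, 25L)
  expect_identical(fl2$flank5, "")
  expect_identical(fl2$flank3, "")
  expect_error(conserved_flanks(os2, 30L, 60L),
               class = "mirbind_coordinate_error")
})

test_that("substitution classification separates transitions and transversions", {
  r1 <- classify_substitutions("ACGU", "ACGC")
  expect_identical(r1$counts[["pyrimidine_transition"]], 1L)
  expect_identical(sum(r1$counts[c("transversion", "indel",
                                   "purine_transition")]), 0L)
  r2 <- classify_substitutions("AGGG", "GGGG")
  expect_identical(r2$counts[["purine_transition"]], 1L)
  r3 <- classify_substitutions("ACGU", "AAGU")
  expect_identical(r3$counts[["transversion"]], 1L)
  # identity: all matches, no substitutions
  set.seed(52)
  s <- random_rna(40, 0.5)
  r4 <- classify_substitutions(s, s)
  expect_identical(r4$counts[["match"]], 40L)
  expect_identical(sum(r4$counts) - r4$counts[["match"]], 0L)
  # symmetry of substitution classes under argument swap
  a <- "ACGUACGU"; b <- "GCGCACGA"
  ra <- classify_substitutions(a, b)$counts
  rb <- classify_substitutions(b, a)$counts
  expect_identical(ra[c("purine_transition", "pyrimidine_transition",
                        "transversion")],
                   rb[c("purine_transition", "pyrimidine_transition",
                        "transversion")])
  # a deletion shows up as indel columns
  r5 <- classify_substitutions("ACGUACGUAC", "ACGUGUAC")
  expect_identical(r5$counts[["indel"]], 2L)
})

test_that("the alignment is optimal versus exhaustive search on tiny strings", {
  set.seed(53)
  for (i in 1:12) {
    a <- random_rna(sample(3:7, 1), 0.5)
    b <- random_rna(sample(3:7, 1), 0.5)
    got <- classify_substitutions(a, b)$score
    want <- oracle_global_score(a, b)
    expect_equal(got, want)
  }
})

test_that("cross-species rescoring reproduces the reference and bands ratios", {
  set.seed(54)
  m <- random_rna(22, 0.6)
  ref <- paste0(random_rna(20, 0.4), revcomp_rna(m), random_rna(20, 0.4))
  os <- ortholog_set("L", c(hsa = ref, ptr = ref))
  rs <- rescore_across_species(make_mirna(m), os)
  expect_equal(rs$best_ratio, c(100, 100))
  expect_identical(rs$band, c(">=90", ">=90"))

  # one G->A transition inside a G-C paired position drops 2 bonds
  site <- revcomp_rna(m)
  gpos <- which(strsplit(site, "")[[1]] == "G")[1]
  expect_false(is.na(gpos))
  mutated <- site
  substr(mutated, gpos, gpos) <- "A"
  os2 <- ortholog_set("L", c(
    hsa = paste0(substr(ref, 1, 20), site, substr(ref, 43, 62)),
    ptr = paste0(substr(ref, 1, 20), mutated, substr(ref, 43, 62))
  ))
  rs2 <- rescore_across_species(make_mirna(m), os2)
  mb <- max_bonds(m)
  expect_equal(rs2$best_ratio[rs2$species == "ptr"],
               100 * (mb - 2) / mb)

  # segment shorter than the miRNA is not evaluable
  os3 <- ortholog_set("L", c(hsa = ref, ptr = "ACGUACGU"))
  rs3 <- rescore_across_species(make_mirna(m), os3)
  expect_false(rs3$evaluable[rs3$species == "ptr"])
  expect_identical(rs3$band[rs3$species == "ptr"], "not_evaluable")

  # deleting the site leaves only weak background binding
  os4 <- ortholog_set("L", c(hsa = ref,
                             ptr = paste0(substr(ref, 1, 20),
                                          substr(ref, 43, 62))))
  rs4 <- rescore_across_species(make_mirna(m), os4)
  expect_lt(rs4$best_ratio[rs4$species == "ptr"], 80)
})

test_that("translation drops partial codons, renders stops, obeys frames", {
  expect_identical(translate_segment("GCUGCU"), "AA")
  expect_identical(translate_segment("AUGUAA"), "M*")
  # GCN-repeat cluster with one GUN codon: poly-Ala with one Val
  seg <- paste0(strrep("GCA", 3), "GUC", strrep("GCG", 8))
  expect_identical(translate_segment(seg), "AAAVAAAAAAAA")
  # frame offsets and the length law
  set.seed(55)
  for (i in 1:10) {
    s <- random_rna(sample(6:30, 1), 0.5)
    for (f in 0:2) {
      if ((nchar(s) - f) %/% 3 < 1) next
      expect_identical(nchar(translate_segment(s, f)),
                       (nchar(s) - f) %/% 3L)
    }
  }
  expect_error(translate_segment("AC"), class = "mirbind_contract_error")
})

test_that("cluster shrinkage measures per-species flank-to-flank length", {
  set.seed(56)
  cluster <- random_rna(33, 0.7)
  ref <- paste0("UGCGGG", cluster, "CCGAG")
  # one species identical, one with an 11-nt internal deletion
  shrunk <- paste0("UGCGGG", substr(cluster, 1, 10),
                   substr(cluster, 22, 33), "CCGAG")
  os <- ortholog_set("GSK3B-like",
                     c(hsa = ref, ptr = shrunk, ggo = ref))
  sh <- cluster_shrinkage(os, 7L, 39L)
  expect_identical(sh$cluster_length[sh$species == "hsa"], 33L)
  expect_identical(sh$cluster_length[sh$species == "ptr"], 22L)
  expect_identical(sh$cluster_length[sh$species == "ggo"], 33L)
  expect_true(all(sh$locatable))
})
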