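#!/usr/bin/env Rscript
# Recurrent start offsets and polysite runs, on the reported tables (the
# 6 / 74 / 99 nt offsets and the VSNL1 13-site run) and on the synthetic
# cohort's planted pairs. Writes results/offsets.tsv and
# results/polysites.tsv.

suppressMessages(library(mirbind))

rep3 <- reported_sites_long("3UTR")

off <- rbind(
  offset_patterns(rep3, list(c("miR-5095", "miR-619-5p"))),
  offset_patterns(rep3[rep3$gene %in% c("RBBP5", "SLC14A1"), ],
                  list(c("miR-619-5p", "miR-5096"))),
  offset_patterns(rep3, list(c("miR-5585-3p", "miR-1285-5p")))
)
write.table(off, "results/offsets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("reported-table offsets:\n")
print(off[, c("mirna_a", "mirna_b", "gene", "offset", "constant")],
      row.names = FALSE)

vsnl <- rep3[rep3$gene == "VSNL1" & rep3$mirna_id == "miR-574-5p", ]
gp <- group_polysites(vsnl)
cat(sprintf("\nVSNL1 miR-574-5p polysite: %d starts from %d to %d (spacing 2 nt)\n",
            gp$count, gp$first_start, gp$last_start))

## cohort: planted offsets and the polysite run
truth <- jsonlite::read_json("results/cohort/ground_truth.json",
                             simplifyVector = TRUE)
tab <- read_site_table("results/sites.tsv")
sites <- data.frame(
  mirna_id = tab$mirna_id, transcript_id = tab$gene, gene = tab$gene,
  start = tab$start, length = tab$length, region = tab$region,
  stringsAsFactors = FALSE
)

ot <- truth$offset_pairs
cat("\ncohort planted offsets (recovered / truth):\n")
for (key in unique(paste(ot$mirna_a, ot$mirna_b))) {
  sub <- ot[paste(ot$mirna_a, ot$mirna_b) == key, ]
  got <- offset_patterns(sites, list(c(sub$mirna_a[[1]], sub$mirna_b[[1]])))
  cat(sprintf("  %s / %s: %s nt in %d genes (constant: %s)\n",
              sub$mirna_a[[1]], sub$mirna_b[[1]],
              paste(unique(got$offset), collapse = ","), nrow(got),
              all(got$constant)))
}

pt <- truth$polysite
ps <- sites[sites$mirna_id == pt$mirna_id &
              sites$transcript_id == pt$gene, ]
gp2 <- group_polysites(ps)
all_ps <- do.call(rbind, lapply(
  split(sites, paste(sites$mirna_id, sites$transcript_id, sep = "\r")),
  function(s) group_polysites(s)
))
all_ps$starts <- vapply(all_ps$starts, paste, character(1), collapse = ",")
write.table(all_ps, "results/polysites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\ncohort polysite: recovered %d starts (planted %d) in %s\n",
            gp2$count, pt$count, pt$gene))
cat(sprintf("phase distribution of polysite starts mod 3: %s\n",
            paste(capture.output(print(table(ps$start %% 3))),
                  collapse = " ")))
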