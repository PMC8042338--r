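# Seeded generators for synthetic cohorts. The generator plants ground-truth
# structure into random background transcripts: single sites at controlled
# dG/dGm ratios, a tandem-repeat polysite run, constant-offset site pairs
# recurring across genes, and (separately) ortholog sets diverging by
# transition-biased substitutions around preserved flanking oligonucleotides.
# All randomness flows from the single config seed through R's global RNG, so
# identical configs produce byte-identical artifacts.

#' Random RNA sequence with a given expected GC fraction
#'
#' @param n length, nt.
#' @param gc_fraction expected fraction of G+C in [0, 1].
#' @return RNA string.
#' @export
random_rna <- function(n, gc_fraction = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random miRNA sequence
#'
#' @param length miRNA length in nt, within 18-26.
#' @param gc_fraction expected GC fraction in [0, 1].
#' @return miRNA sequence string.
#' @export
gen_mirna <- function(length = 22L, gc_fraction = 0.5) {
  if (length < 18L || length > 26L) {
    stop_mirbind("miRNA length must be within [18, 26]",
                 "mirbind_config_error")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop_mirbind("gc_fraction must be in [0, 1]", "mirbind_config_error")
  }
  random_rna(length, gc_fraction)
}

.transition <- c(A = "G", G = "A", C = "U", U = "C")
.transversions <- list(A = c("C", "U"), G = c("C", "U"),
                       C = c("A", "G"), U = c("A", "G"))

.window_ratio <- function(window_chars, q_rev, mb) {
  w <- .ENC[utf8ToInt(paste(window_chars, collapse = ""))]
  100 * sum(.BOND[cbind(w, q_rev)]) / mb
}

#' Plant a binding site of a controlled quality into a sequence
#'
#' Writes the exact reverse complement of the miRNA at `position`, then
#' applies transition-biased substitutions (re-scoring after each edit)
#' until the unrounded dG/dGm ratio lies within +/- 1.5 points of
#' `target_ratio`. A final deterministic sweep over position x base
#' combinations guards against the stochastic search stalling; an
#' unreachable target raises a generation error.
#'
#' @param sequence host sequence (the window must fit at `position`).
#' @param mirna miRNA sequence.
#' @param position 1-based start of the planted window.
#' @param target_ratio desired ratio, percent, in [70, 100].
#' @param transition_bias probability that an edit is a transition
#'   (default 0.8, mimicking the purine<->purine / pyrimidine<->pyrimidine
#'   predominance of diverging real sites).
#' @param max_attempts bound on stochastic edit attempts.
#' @return list with `sequence` (modified host), `start`, `achieved_ratio`.
#' @export
plant_site <- function(sequence, mirna, position, target_ratio,
                       transition_bias = 0.8, max_attempts = 200L) {
  L <- nchar(mirna)
  if (target_ratio < 70 || target_ratio > 100) {
    stop_mirbind("target_ratio must be in [70, 100]", "mirbind_config_error")
  }
  if (position < 1L || position + L - 1L > nchar(sequence)) {
    stop_mirbind("planted window does not fit in the sequence",
                 "mirbind_generation_error")
  }
  mb <- max_bonds(mirna)
  q_rev <- rev(encode_rna(mirna, "miRNA"))
  w <- strsplit(revcomp_rna(mirna), "")[[1]]
  lo <- target_ratio - 1.5
  hi <- target_ratio + 1.5
  ratio <- 100
  attempts <- 0L
  edited <- logical(L)
  while (ratio > hi && attempts < max_attempts) {
    attempts <- attempts + 1L
    free <- which(!edited)
    if (length(free) == 0L) break
    i <- free[[sample.int(length(free), 1L)]]
    old <- w[[i]]
    w[[i]] <- if (stats::runif(1) < transition_bias) .transition[[old]] else
      sample(.transversions[[old]], 1L)
    new_ratio <- .window_ratio(w, q_rev, mb)
    if (new_ratio < lo) {
      w[[i]] <- old  # overshoot: revert and retry elsewhere
    } else {
      ratio <- new_ratio
      edited[[i]] <- TRUE
    }
  }
  if (ratio > hi || ratio < lo) {
    # deterministic sweep: any single further edit landing inside the band
    done <- FALSE
    for (i in seq_len(L)) {
      for (b in setdiff(c("A", "C", "G", "U"), w[[i]])) {
        old <- w[[i]]
        w[[i]] <- b
        r <- .window_ratio(w, q_rev, mb)
        if (r >= lo && r <= hi) { ratio <- r; done <- TRUE; break }
        w[[i]] <- old
      }
      if (done) break
    }
    if (!done) {
      stop_mirbind(
        sprintf("cannot reach target ratio %.1f +/- 1.5 for this miRNA",
                target_ratio),
        "mirbind_generation_error"
      )
    }
  }
  window <- paste(w, collapse = "")
  out <- paste0(substr(sequence, 1L, position - 1L), window,
                substr(sequence, position + L, nchar(sequence)))
  list(sequence = out, start = position, achieved_ratio = ratio)
}

#' Generate an ortholog set by transition-biased divergence
#'
#' Each non-reference species receives i.i.d. substitutions at `sub_rate`
#' per position outside the preserved flank oligonucleotides; an edit is a
#' transition (A<->G, C<->U) with probability `transition_fraction`,
#' otherwise a random transversion. Flank occurrences in the reference are
#' never mutated.
#'
#' @param reference reference segment (RNA string).
#' @param species character vector of species codes; the first is the
#'   unchanged reference species.
#' @param sub_rate per-nucleotide substitution probability in [0, 1].
#' @param transition_fraction probability an edit is a transition.
#' @param flanks character vector of oligonucleotides to preserve (all of
#'   their occurrences in the reference are masked).
#' @param locus locus label.
#' @return an [ortholog_set()] with the first species as reference.
#' @export
gen_ortholog_set <- function(reference, species, sub_rate,
                             transition_fraction = 0.8,
                             flanks = character(0), locus = "locus") {
  reference <- normalize_rna(reference, "reference")
  n <- nchar(reference)
  mask <- logical(n)
  for (f in flanks) {
    hits <- gregexpr(f, reference, fixed = TRUE)[[1]]
    if (hits[[1]] == -1L) {
      stop_mirbind(sprintf("flank %s not found in the reference", sQuote(f)),
                   "mirbind_generation_error")
    }
    for (h in hits) mask[h:(h + nchar(f) - 1L)] <- TRUE
  }
  ref_chars <- strsplit(reference, "")[[1]]
  segs <- stats::setNames(vector("character", length(species)), species)
  segs[[1]] <- reference
  for (k in seq_along(species)[-1]) {
    chars <- ref_chars
    hit <- !mask & stats::runif(n) < sub_rate
    for (i in which(hit)) {
      chars[[i]] <- if (stats::runif(1) < transition_fraction)
        .transition[[chars[[i]]]] else sample(.transversions[[chars[[i]]]], 1L)
    }
    segs[[k]] <- paste(chars, collapse = "")
  }
  ortholog_set(locus, segs, reference_species = species[[1]])
}

#' Default simulation configuration (the study conditions)
#'
#' 20 genes with 5'UTR 100-300 nt, triplet CDS 300-1500 nt and 3'UTR
#' 300-4000 nt; 100 planted single sites (one fresh miRNA each, target
#' ratios evenly spaced over 85-100, regions cycling 5'UTR/CDS/3'UTR); one
#' 13-member polysite run at 2-nt spacing over a dinucleotide repeat; three
#' recurrent-offset pairs (6 nt across 3 genes via overlapping sub-windows
#' of one planted block, 74 nt and 99 nt across 2 genes each); RPKM with
#' 20% of genes log-uniform in the 43.1-322.5 high band and the rest
#' lognormal matched to mean 3.5, sd 2.9, truncated to 0.1-10.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param n_planted_sites planted single sites in total.
#' @return list of class `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, n_genes = 20L,
                               n_planted_sites = 100L) {
  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    utr5_len = c(100L, 300L),
    cds_len = c(300L, 1500L),
    utr3_len = c(300L, 4000L),
    gc_background = 0.5,
    mirna_length = 22L,
    mirna_gc = 0.6,
    n_planted_sites = as.integer(n_planted_sites),
    target_ratio_range = c(85, 100),
    transition_bias = 0.8,
    polysite = list(count = 13L, spacing = 2L, region = "3UTR"),
    offset_pairs = list(
      list(offset = 6L, n_genes = 3L, overlapping = TRUE),
      list(offset = 74L, n_genes = 2L, overlapping = FALSE),
      list(offset = 99L, n_genes = 2L, overlapping = FALSE)
    ),
    rpkm = list(high_fraction = 0.2, high_range = c(43.1, 322.5),
                meanlog = 0.992, sdlog = 0.723, low_range = c(0.1, 10)),
    thresholds = c(report = 85, efficient = 90)
  ), class = "sim_config")
}

.region_bounds <- function(tx, region) {
  switch(region,
    "5UTR" = c(1L, tx$utr5_end),
    "CDS" = c(tx$utr5_end + 1L, tx$cds_end),
    "3UTR" = c(tx$cds_end + 1L, nchar(tx$sequence)),
    c(1L, nchar(tx$sequence))
  )
}

# sample a start for a width-w window inside [lo, hi] avoiding occupied
# intervals (matrix with columns start, end); NA if no room found
.free_start <- function(lo, hi, w, occupied, tries = 200L) {
  hi_start <- hi - w + 1L
  if (hi_start < lo) return(NA_integer_)
  for (t in seq_len(tries)) {
    s <- lo + sample.int(hi_start - lo + 1L, 1L) - 1L
    e <- s + w - 1L
    if (nrow(occupied) == 0L ||
        all(e < occupied[, 1L] | s > occupied[, 2L])) {
      return(s)
    }
  }
  NA_integer_
}

#' Generate a full synthetic cohort with ground truth
#'
#' Builds the miRNA set, transcripts with annotation and RPKM, plants every
#' configured structure, and (optionally) writes the four artifacts: miRNA
#' FASTA, transcript FASTA, annotation TSV and ground-truth JSON. Identical
#' configs (including the seed) give byte-identical outputs.
#'
#' @param config a [default_sim_config()]-style list.
#' @param outdir output directory, or NULL to skip writing.
#' @return invisibly, a list with `mirnas`, `transcripts`, `truth` (planted
#'   sites, polysite, offset pairs) and `paths` (when written).
#' @export
gen_cohort <- function(config = default_sim_config(), outdir = NULL) {
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("GENE%02d", seq_len(ng))
  tx_ids <- sprintf("tx%02d", seq_len(ng))

  transcripts <- data.frame(
    transcript_id = tx_ids, gene = genes,
    sequence = character(ng), utr5_end = integer(ng),
    cds_end = integer(ng), rpkm = numeric(ng),
    stringsAsFactors = FALSE
  )
  occupied <- rep(list(matrix(integer(0), 0L, 2L)), max(ng, 1L))
  for (i in seq_len(ng)) {
    u5 <- sample(config$utr5_len[[1]]:config$utr5_len[[2]], 1L)
    cds <- sample(config$cds_len[[1]]:config$cds_len[[2]], 1L)
    cds <- cds - cds %% 3L
    u3 <- sample(config$utr3_len[[1]]:config$utr3_len[[2]], 1L)
    transcripts$utr5_end[[i]] <- u5
    transcripts$cds_end[[i]] <- u5 + cds
    transcripts$sequence[[i]] <- random_rna(u5 + cds + u3,
                                            config$gc_background)
  }

  # RPKM: forced high band for a fixed fraction of genes, lognormal low band
  if (ng > 0L) {
    n_high <- round(config$rpkm$high_fraction * ng)
    high_idx <- if (n_high > 0L) sample(ng, n_high) else integer(0)
    for (i in seq_len(ng)) {
      if (i %in% high_idx) {
        lr <- log(config$rpkm$high_range)
        transcripts$rpkm[[i]] <- exp(stats::runif(1, lr[[1]], lr[[2]]))
      } else {
        r <- stats::rlnorm(1, config$rpkm$meanlog, config$rpkm$sdlog)
        for (t in 1:1000) {
          if (r >= config$rpkm$low_range[[1]] &&
              r <= config$rpkm$low_range[[2]]) break
          r <- stats::rlnorm(1, config$rpkm$meanlog, config$rpkm$sdlog)
        }
        transcripts$rpkm[[i]] <- min(max(r, config$rpkm$low_range[[1]]),
                                     config$rpkm$low_range[[2]])
      }
    }
    transcripts$rpkm <- round(transcripts$rpkm, 1)
  }

  mirnas <- data.frame(id = character(0), sequence = character(0),
                       stringsAsFactors = FALSE)
  add_mirna <- function(id, seq) {
    mirnas[nrow(mirnas) + 1L, ] <<- list(id, seq)
  }
  truth_sites <- list()
  regions <- c("5UTR", "CDS", "3UTR")

  # --- planted single sites, round-robin over genes and regions ---
  if (ng > 0L && config$n_planted_sites > 0L) {
    targets <- seq(config$target_ratio_range[[1]],
                   config$target_ratio_range[[2]],
                   length.out = config$n_planted_sites)
    for (k in seq_len(config$n_planted_sites)) {
      gi <- ((k - 1L) %% ng) + 1L
      region <- regions[[((k - 1L) %% 3L) + 1L]]
      mseq <- gen_mirna(config$mirna_length, config$mirna_gc)
      mid <- sprintf("plant-miR-%03d", k)
      tx <- transcripts[gi, ]
      b <- .region_bounds(tx, region)
      s <- .free_start(b[[1]], b[[2]], config$mirna_length, occupied[[gi]])
      if (is.na(s)) {  # fall back to any region with room
        for (r2 in regions) {
          b <- .region_bounds(tx, r2)
          s <- .free_start(b[[1]], b[[2]], config$mirna_length,
                           occupied[[gi]])
          if (!is.na(s)) { region <- r2; break }
        }
      }
      if (is.na(s)) {
        stop_mirbind("no room left to plant a site", "mirbind_generation_error")
      }
      pl <- plant_site(tx$sequence, mseq, s, targets[[k]],
                       transition_bias = config$transition_bias)
      transcripts$sequence[[gi]] <- pl$sequence
      occupied[[gi]] <- rbind(occupied[[gi]],
                              c(s, s + config$mirna_length - 1L))
      add_mirna(mid, mseq)
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        mirna_id = mid, gene = genes[[gi]], transcript_id = tx_ids[[gi]],
        region = region, start = s, length = config$mirna_length,
        target_ratio = targets[[k]], achieved_ratio = pl$achieved_ratio,
        stringsAsFactors = FALSE
      )
    }
  }

  # --- polysite: dinucleotide-repeat block, same miRNA at 2-nt spacing ---
  # An AC-repeat block of f = count-2 perfect windows is framed by UA-repeat
  # guards. The two 2-nt-shifted shoulder windows still phase-match 20 of 22
  # repeat positions (50/55 bonds ~ 90.9%) and are genuine sites, while the
  # guards contribute zero bonds so the next shifts fall below threshold:
  # the recovered run has exactly `count` starts at `spacing` nt.
  truth_polysite <- NULL
  if (ng > 0L && !is.null(config$polysite)) {
    ps <- config$polysite
    L <- config$mirna_length
    if (ps$spacing != 2L || L %% 2L != 0L || ps$count < 3L) {
      stop_mirbind(
        "polysite generator requires spacing 2, an even miRNA length and count >= 3",
        "mirbind_config_error"
      )
    }
    n_full <- ps$count - 2L
    block <- paste(rep("AC", (L + ps$spacing * (n_full - 1L)) / 2L),
                   collapse = "")
    insert <- paste0("UAUA", block, "UAUA")
    gi <- 1L
    tx <- transcripts[gi, ]
    b <- .region_bounds(tx, ps$region)
    p <- .free_start(b[[1]], b[[2]], nchar(insert), occupied[[gi]])
    if (is.na(p)) {
      stop_mirbind("no room for the polysite block", "mirbind_generation_error")
    }
    transcripts$sequence[[gi]] <- paste0(
      substr(tx$sequence, 1L, p - 1L), insert,
      substr(tx$sequence, p + nchar(insert), nchar(tx$sequence))
    )
    occupied[[gi]] <- rbind(occupied[[gi]], c(p, p + nchar(insert) - 1L))
    mid <- "polysite-miR"
    add_mirna(mid, revcomp_rna(substr(block, 1L, L)))
    truth_polysite <- list(
      mirna_id = mid, gene = genes[[gi]], transcript_id = tx_ids[[gi]],
      starts = p + 2L + ps$spacing * (seq_len(ps$count) - 1L),
      count = ps$count, spacing = ps$spacing
    )
  }

  # --- recurrent constant-offset pairs across genes ---
  truth_offsets <- list()
  if (ng > 1L && length(config$offset_pairs) > 0L) {
    gene_cursor <- 2L  # gene 1 hosts the polysite
    for (j in seq_along(config$offset_pairs)) {
      spec <- config$offset_pairs[[j]]
      L <- config$mirna_length
      ids <- sprintf(c("offset%02d-a-miR", "offset%02d-b-miR"), spec$offset)
      target_genes <- (((gene_cursor - 1L) + seq_len(spec$n_genes) - 1L)
                       %% ng) + 1L
      gene_cursor <- gene_cursor + spec$n_genes
      if (spec$overlapping) {
        # one block; the two miRNAs are revcomps of its overlapping windows
        block <- random_rna(L + spec$offset, gc_fraction = 0.6)
        seq_a <- revcomp_rna(substr(block, 1L, L))
        seq_b <- revcomp_rna(substr(block, spec$offset + 1L,
                                    spec$offset + L))
        add_mirna(ids[[1]], seq_a)
        add_mirna(ids[[2]], seq_b)
        for (gi in target_genes) {
          tx <- transcripts[gi, ]
          b <- .region_bounds(tx, "3UTR")
          s <- .free_start(b[[1]], b[[2]], nchar(block), occupied[[gi]])
          if (is.na(s)) {
            stop_mirbind("no room for an offset block",
                         "mirbind_generation_error")
          }
          transcripts$sequence[[gi]] <- paste0(
            substr(tx$sequence, 1L, s - 1L), block,
            substr(tx$sequence, s + nchar(block), nchar(tx$sequence))
          )
          occupied[[gi]] <- rbind(occupied[[gi]],
                                  c(s, s + nchar(block) - 1L))
          truth_offsets[[length(truth_offsets) + 1L]] <- data.frame(
            mirna_a = ids[[1]], mirna_b = ids[[2]], gene = genes[[gi]],
            start_a = s, start_b = s + spec$offset, offset = spec$offset,
            stringsAsFactors = FALSE
          )
        }
      } else {
        seq_a <- gen_mirna(L, config$mirna_gc)
        seq_b <- gen_mirna(L, config$mirna_gc)
        add_mirna(ids[[1]], seq_a)
        add_mirna(ids[[2]], seq_b)
        span <- spec$offset + L
        for (gi in target_genes) {
          tx <- transcripts[gi, ]
          b <- .region_bounds(tx, "3UTR")
          s <- .free_start(b[[1]], b[[2]], span, occupied[[gi]])
          if (is.na(s)) {
            stop_mirbind("no room for an offset pair",
                         "mirbind_generation_error")
          }
          seq2 <- tx$sequence
          seq2 <- plant_site(seq2, seq_a, s, 100)$sequence
          seq2 <- plant_site(seq2, seq_b, s + spec$offset, 100)$sequence
          transcripts$sequence[[gi]] <- seq2
          occupied[[gi]] <- rbind(occupied[[gi]], c(s, s + span - 1L))
          truth_offsets[[length(truth_offsets) + 1L]] <- data.frame(
            mirna_a = ids[[1]], mirna_b = ids[[2]], gene = genes[[gi]],
            start_a = s, start_b = s + spec$offset, offset = spec$offset,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  truth <- list(
    planted_sites = if (length(truth_sites) > 0L)
      do.call(rbind, truth_sites) else NULL,
    polysite = truth_polysite,
    offset_pairs = if (length(truth_offsets) > 0L)
      do.call(rbind, truth_offsets) else NULL
  )

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      mirnas = file.path(outdir, "mirnas.fasta"),
      transcripts = file.path(outdir, "transcripts.fasta"),
      annotations = file.path(outdir, "annotations.tsv"),
      ground_truth = file.path(outdir, "ground_truth.json")
    )
    write_fasta(mirnas$id, mirnas$sequence, paths$mirnas)
    write_fasta(transcripts$transcript_id, transcripts$sequence,
                paths$transcripts)
    utils::write.table(
      transcripts[, c("transcript_id", "gene", "utr5_end", "cds_end", "rpkm")],
      paths$annotations, sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(list(mirnas = mirnas, transcripts = transcripts, truth = truth,
                 paths = paths))
}
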