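# Cross-species conservation of binding-site clusters: conserved flanking
# oligonucleotides around a cluster interval, classification of aligned
# substitutions into transitions (purine<->purine A-G, pyrimidine<->pyrimidine
# C-U) and transversions, re-scoring of a miRNA against each species' segment,
# and translation of CDS cluster segments into the encoded peptide.

#' Construct and validate an ortholog set
#'
#' @param locus locus label (e.g. gene symbol).
#' @param segments named character vector of homologous mRNA segments, names
#'   are species codes (hsa, ptr, mmu, ...). Duplicate codes in source lists
#'   are treated as distinct user-supplied labels and must be disambiguated
#'   by the caller.
#' @param reference_species species code of the reference segment.
#' @return object of class `ortholog_set`.
#' @export
ortholog_set <- function(locus, segments, reference_species = "hsa") {
  if (length(segments) < 2L) {
    stop_mirbind("an ortholog set needs at least two species",
                 "mirbind_validation_error")
  }
  if (is.null(names(segments)) || anyNA(names(segments)) ||
      any(names(segments) == "")) {
    stop_mirbind("every segment must carry a species code",
                 "mirbind_validation_error")
  }
  if (!reference_species %in% names(segments)) {
    stop_mirbind(sprintf("reference species %s absent from the set",
                         sQuote(reference_species)),
                 "mirbind_validation_error")
  }
  if (any(nchar(segments) == 0L)) {
    stop_mirbind("segments must be non-empty", "mirbind_validation_error")
  }
  segments <- vapply(segments, normalize_rna, character(1))
  structure(
    list(locus = locus, segments = segments,
         reference_species = reference_species),
    class = "ortholog_set"
  )
}

#' Conserved flanking oligonucleotides of a cluster interval
#'
#' Anchored at the edges of the reference cluster interval: the 5' flank is
#' the longest oligonucleotide (up to `max_len`) ending immediately before
#' `cluster_start` in the reference that occurs exactly in every species
#' segment; the 3' flank likewise starts immediately after `cluster_end`.
#' Empty strings mean no length-1 flank is shared.
#'
#' @param set an [ortholog_set()].
#' @param cluster_start,cluster_end 1-based cluster interval in the
#'   reference segment.
#' @param max_len maximum flank length searched, nt.
#' @return list with `flank5` and `flank3`.
#' @export
conserved_flanks <- function(set, cluster_start, cluster_end, max_len = 10L) {
  ref <- set$segments[[set$reference_species]]
  if (cluster_start < 1L || cluster_end > nchar(ref) ||
      cluster_start > cluster_end) {
    stop_mirbind(
      sprintf("cluster interval [%d, %d] outside reference segment (1..%d)",
              cluster_start, cluster_end, nchar(ref)),
      "mirbind_coordinate_error"
    )
  }
  shared <- function(oligo) {
    nchar(oligo) > 0L &&
      all(vapply(set$segments, function(s) grepl(oligo, s, fixed = TRUE),
                 logical(1)))
  }
  flank5 <- ""
  for (k in rev(seq_len(min(max_len, cluster_start - 1L)))) {
    cand <- substr(ref, cluster_start - k, cluster_start - 1L)
    if (shared(cand)) { flank5 <- cand; break }
  }
  flank3 <- ""
  for (k in rev(seq_len(min(max_len, nchar(ref) - cluster_end)))) {
    cand <- substr(ref, cluster_end + 1L, cluster_end + k)
    if (shared(cand)) { flank3 <- cand; break }
  }
  list(flank5 = flank5, flank3 = flank3)
}

#' Alignment parameters for pairwise segment comparison
#'
#' Global alignment with small fixed integer scores and linear gaps.
#'
#' @param match,mismatch,gap score units; must satisfy
#'   gap <= mismatch <= 0 < match.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1, gap = -2) {
  if (!(gap <= mismatch && mismatch <= 0 && 0 < match)) {
    stop_mirbind("alignment scores must satisfy gap <= mismatch <= 0 < match",
                 "mirbind_config_error")
  }
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_params")
}

.align_matrix <- function(params) {
  m <- matrix(params$mismatch, 5L, 5L,
              dimnames = list(.RNA_BASES, .RNA_BASES))
  diag(m) <- params$match
  m["N", ] <- params$mismatch
  m[, "N"] <- params$mismatch
  m
}

#' Globally align two segments and classify their substitutions
#'
#' Needleman-Wunsch global alignment (via Biostrings) under
#' [alignment_params()]; aligned mismatch columns are classified as
#' purine_transition (A<->G), pyrimidine_transition (C<->U) or transversion,
#' and gap columns are counted as indels.
#'
#' @param reference,other RNA segments (reference first).
#' @param params an [alignment_params()].
#' @return list with `counts` (named integer vector: match,
#'   purine_transition, pyrimidine_transition, transversion, indel),
#'   `score`, and the two aligned strings.
#' @export
classify_substitutions <- function(reference, other,
                                   params = alignment_params()) {
  if (nchar(reference) == 0L || nchar(other) == 0L) {
    stop_mirbind("segments must be non-empty", "mirbind_contract_error")
  }
  reference <- normalize_rna(reference, "reference segment")
  other <- normalize_rna(other, "other segment")
  aln <- Biostrings::pairwiseAlignment(
    other, reference, type = "global",
    substitutionMatrix = .align_matrix(params),
    gapOpening = 0, gapExtension = abs(params$gap)
  )
  a_ref <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  a_oth <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  counts <- c(match = 0L, purine_transition = 0L,
              pyrimidine_transition = 0L, transversion = 0L, indel = 0L)
  purine <- c("A", "G")
  pyrimidine <- c("C", "U")
  for (i in seq_along(a_ref)) {
    r <- a_ref[[i]]; o <- a_oth[[i]]
    if (r == "-" || o == "-") {
      counts[["indel"]] <- counts[["indel"]] + 1L
    } else if (r == o) {
      counts[["match"]] <- counts[["match"]] + 1L
    } else if (r %in% purine && o %in% purine) {
      counts[["purine_transition"]] <- counts[["purine_transition"]] + 1L
    } else if (r %in% pyrimidine && o %in% pyrimidine) {
      counts[["pyrimidine_transition"]] <- counts[["pyrimidine_transition"]] + 1L
    } else {
      counts[["transversion"]] <- counts[["transversion"]] + 1L
    }
  }
  list(counts = counts, score = BiocGenerics::score(aln),
       aligned_reference = paste(a_ref, collapse = ""),
       aligned_other = paste(a_oth, collapse = ""))
}

#' Best site ratio of a miRNA in each species' segment
#'
#' Scans every window of every segment and reports the best dG/dGm ratio per
#' species, banded as >=90 (efficient), 85-90, 80-85, and <80 (weak).
#' Species whose segment is shorter than the miRNA are marked not evaluable.
#'
#' @param mirna one-row data.frame or list with `id`, `sequence`.
#' @param set an [ortholog_set()].
#' @param model an [energy_model()].
#' @return data.frame with species, best_ratio, best_start, band, evaluable.
#' @export
rescore_across_species <- function(mirna, set, model = energy_model()) {
  mseq <- mirna$sequence[[1]]
  mb <- max_bonds(mseq)
  out <- lapply(names(set$segments), function(sp) {
    seg <- set$segments[[sp]]
    if (nchar(seg) < nchar(mseq)) {
      return(data.frame(species = sp, best_ratio = NA_real_,
                        best_start = NA_integer_, band = "not_evaluable",
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    tot <- scan_bonds(mseq, seg)
    ratio <- 100 * max(tot) / mb
    band <- if (ratio >= 90 - 1e-9) ">=90"
            else if (ratio >= 85 - 1e-9) "85-90"
            else if (ratio >= 80 - 1e-9) "80-85"
            else "<80"
    data.frame(species = sp, best_ratio = ratio,
               best_start = which.max(tot), band = band, evaluable = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Translate an RNA segment in a given frame
#'
#' Standard genetic code; the trailing partial codon is dropped and stop
#' codons render as "*". Codons containing N translate to "X".
#'
#' @param segment RNA string.
#' @param frame_offset 0, 1 or 2 nucleotides skipped before the first codon.
#' @return peptide string.
#' @export
translate_segment <- function(segment, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  segment <- normalize_rna(segment, "segment")
  eff <- substr(segment, frame_offset + 1L, nchar(segment))
  n_codons <- nchar(eff) %/% 3L
  if (n_codons < 1L) {
    stop_mirbind("effective sequence shorter than one codon",
                 "mirbind_contract_error")
  }
  eff <- substr(eff, 1L, 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::RNAString(eff),
                                     if.fuzzy.codon = "X"))
}

#' Homologous cluster length per species, between conserved flanks
#'
#' Finds the conserved flanks of the reference cluster, locates them in every
#' species segment (first occurrence of the 5' flank, then the first
#' occurrence of the 3' flank after it), and measures the enclosed length.
#' Species in which either flank cannot be located are reported as
#' not locatable.
#'
#' @param set an [ortholog_set()].
#' @param cluster_start,cluster_end reference cluster interval.
#' @param max_flank_len passed to [conserved_flanks()].
#' @return data.frame with species, cluster_length, locatable; attribute
#'   "flanks" holds the flank pair used.
#' @export
cluster_shrinkage <- function(set, cluster_start, cluster_end,
                              max_flank_len = 10L) {
  fl <- conserved_flanks(set, cluster_start, cluster_end,
                         max_len = max_flank_len)
  if (nchar(fl$flank5) == 0L || nchar(fl$flank3) == 0L) {
    stop_mirbind("no conserved flank pair brackets the cluster",
                 "mirbind_validation_error")
  }
  out <- lapply(names(set$segments), function(sp) {
    seg <- set$segments[[sp]]
    p5 <- regexpr(fl$flank5, seg, fixed = TRUE)
    if (p5 == -1L) {
      return(data.frame(species = sp, cluster_length = NA_integer_,
                        locatable = FALSE, stringsAsFactors = FALSE))
    }
    inner_from <- p5 + nchar(fl$flank5)
    rest <- substr(seg, inner_from, nchar(seg))
    p3 <- regexpr(fl$flank3, rest, fixed = TRUE)
    if (p3 == -1L) {
      return(data.frame(species = sp, cluster_length = NA_integer_,
                        locatable = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(species = sp, cluster_length = as.integer(p3 - 1L),
               locatable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "flanks") <- fl
  res
}
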