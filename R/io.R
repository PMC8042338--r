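# External representations: FASTA, transcript annotation TSV, site report TSV,
# key-value (YAML) config. All coordinates are 1-based inclusive and counted
# from the first nucleotide of the transcript (= first nucleotide of the
# 5'UTR when one is annotated).

#' Read a FASTA file of RNA or DNA sequences
#'
#' Records are normalized to the RNA alphabet (upper case, T -> U) so NCBI
#' DNA-alphabet mRNA records and miRBase RNA records are interchangeable.
#' Record order is preserved.
#'
#' @param path FASTA file path.
#' @param alphabet_policy "auto" (default) accepts T or U, "rna" rejects T,
#'   "dna" rejects U; all policies return U-alphabet sequences.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, alphabet_policy = c("auto", "rna", "dna")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) {
    stop_mirbind(sprintf("FASTA file not found: %s", path), "mirbind_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  # keep only the first whitespace-delimited token as the id
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L) {
      stop_mirbind(sprintf("empty FASTA record %s", sQuote(ids[[i]])),
                   "mirbind_format_error")
    }
    if (alphabet_policy == "rna" && grepl("T", seqs[[i]], fixed = TRUE)) {
      stop_mirbind(sprintf("record %s contains T under alphabet_policy 'rna'",
                           sQuote(ids[[i]])), "mirbind_alphabet_error")
    }
    if (alphabet_policy == "dna" && grepl("U", seqs[[i]], fixed = TRUE)) {
      stop_mirbind(sprintf("record %s contains U under alphabet_policy 'dna'",
                           sQuote(ids[[i]])), "mirbind_alphabet_error")
    }
    seqs[[i]] <- normalize_rna(seqs[[i]],
                               what = sprintf("record %s", sQuote(ids[[i]])))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids record identifiers.
#' @param sequences sequences (character vector, same length as `ids`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(stats::setNames(as.character(sequences), ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a set of miRNA records
#'
#' Enforces the miRNA contract: non-empty sequence over A,C,G,U and length
#' within 18-26 nt unless relaxed.
#'
#' @param mirnas data.frame with `id`, `sequence` (e.g. from [read_fasta()]).
#' @param length_range allowed length range, default c(18, 26); use NULL to
#'   skip the length check.
#' @return the validated data.frame.
#' @export
validate_mirnas <- function(mirnas, length_range = c(18L, 26L)) {
  for (i in seq_len(nrow(mirnas))) {
    idx <- encode_rna(mirnas$sequence[[i]],
                      what = sprintf("miRNA %s", sQuote(mirnas$id[[i]])))
    if (any(idx == 5L)) {
      stop_mirbind(sprintf("miRNA %s contains N", sQuote(mirnas$id[[i]])),
                   "mirbind_validation_error")
    }
    len <- nchar(mirnas$sequence[[i]])
    if (!is.null(length_range) &&
        (len < length_range[[1]] || len > length_range[[2]])) {
      stop_mirbind(
        sprintf("miRNA %s has length %d outside [%d, %d]",
                sQuote(mirnas$id[[i]]), len,
                length_range[[1]], length_range[[2]]),
        "mirbind_validation_error"
      )
    }
  }
  mirnas
}

#' Read the transcript annotation table and attach sequences
#'
#' The sidecar TSV has header columns transcript_id, gene, utr5_end, cds_end,
#' rpkm. `utr5_end` is the last nucleotide of the 5'UTR (0 if absent) and
#' `cds_end` the last nucleotide of the CDS, both 1-based; the 3'UTR is
#' everything after `cds_end`. A transcript with utr5_end = cds_end = 0 is a
#' single unannotated region.
#'
#' @param path annotation TSV path.
#' @param fasta data.frame with `id`, `sequence` (from [read_fasta()]).
#' @return data.frame of validated transcripts: transcript_id, gene,
#'   sequence, utr5_end, cds_end, rpkm.
#' @export
read_transcript_table <- function(path, fasta) {
  if (!file.exists(path)) {
    stop_mirbind(sprintf("annotation file not found: %s", path),
                 "mirbind_io_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "utr5_end", "cds_end", "rpkm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop_mirbind(sprintf("annotation table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "mirbind_format_error")
  }
  seq_lookup <- stats::setNames(fasta$sequence, fasta$id)
  out <- data.frame(
    transcript_id = as.character(tab$transcript_id),
    gene = as.character(tab$gene),
    sequence = NA_character_,
    utr5_end = as.integer(tab$utr5_end),
    cds_end = as.integer(tab$cds_end),
    rpkm = as.numeric(tab$rpkm),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    id <- out$transcript_id[[i]]
    if (!id %in% names(seq_lookup)) {
      stop_mirbind(sprintf("transcript %s has no sequence in the FASTA",
                           sQuote(id)), "mirbind_reference_error")
    }
    out$sequence[[i]] <- seq_lookup[[id]]
    validate_transcript(out[i, ])
  }
  out
}

#' Validate one transcript row against the coordinate invariants
#'
#' @param transcript one-row data.frame with sequence, utr5_end, cds_end, rpkm.
#' @return the row, invisibly.
#' @export
validate_transcript <- function(transcript) {
  id <- transcript$transcript_id[[1]]
  len <- nchar(transcript$sequence[[1]])
  u <- transcript$utr5_end[[1]]
  cds <- transcript$cds_end[[1]]
  if (is.na(u) || is.na(cds) || u < 0L || cds < u || cds > len) {
    stop_mirbind(
      sprintf("transcript %s: boundaries must satisfy 0 <= utr5_end (%s) <= cds_end (%s) <= length (%d)",
              sQuote(id), u, cds, len),
      "mirbind_boundary_error"
    )
  }
  if (cds > u && (cds - u) %% 3L != 0L) {
    stop_mirbind(
      sprintf("transcript %s: CDS length %d is not a multiple of 3",
              sQuote(id), cds - u),
      "mirbind_frame_error"
    )
  }
  if (is.na(transcript$rpkm[[1]]) || transcript$rpkm[[1]] < 0) {
    stop_mirbind(sprintf("transcript %s: rpkm must be >= 0", sQuote(id)),
                 "mirbind_validation_error")
  }
  invisible(transcript)
}

.SITE_TABLE_COLS <- c("gene", "rpkm", "mirna_id", "start", "region", "length",
                      "delta_g_kj_mol", "ratio_percent", "efficient_flag")

#' Write a binding-site report TSV
#'
#' Columns: gene, rpkm, mirna_id, start, region, length, delta_g_kj_mol,
#' ratio_percent, efficient_flag, sorted by (gene, start, mirna_id).
#' ratio_percent is printed to the nearest integer (half away from zero);
#' all in-memory comparisons elsewhere use unrounded ratios.
#'
#' @param sites data.frame of binding sites (see [find_sites()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_table <- function(sites, path) {
  if (nrow(sites) == 0L) {
    out <- data.frame(matrix(nrow = 0L, ncol = length(.SITE_TABLE_COLS),
                             dimnames = list(NULL, .SITE_TABLE_COLS)))
  } else {
    out <- data.frame(
      gene = sites$gene,
      rpkm = sites$rpkm,
      mirna_id = sites$mirna_id,
      start = sites$start,
      region = sites$region,
      length = sites$length,
      delta_g_kj_mol = sites$delta_g,
      ratio_percent = round_half_away(sites$ratio),
      efficient_flag = sites$efficient,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$gene, out$start, out$mirna_id), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_mirbind(sprintf("cannot write site table to %s", path),
                 "mirbind_io_error")
  }
  invisible(path)
}

#' Read back a binding-site report TSV
#'
#' @param path path written by [write_site_table()].
#' @return data.frame with the report columns.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) > 0L) {
    tab$efficient_flag <- as.logical(tab$efficient_flag)
    tab$delta_g_kj_mol <- as.numeric(tab$delta_g_kj_mol)
    tab$ratio_percent <- as.numeric(tab$ratio_percent)
    tab$rpkm <- as.numeric(tab$rpkm)
  }
  tab
}

#' Round half away from zero
#'
#' Report-facing integer rounding for dG/dGm percentages (round() in R
#' rounds half to even, which is not the reporting convention here).
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.CONFIG_DEFAULTS <- list(
  threshold_report = 85,
  threshold_efficient = 90,
  e_hb_kj_per_bond = 2.1,
  polysite_max_gap = 3L,
  marker_dg_cutoff = 130,
  marker_multisite_min = 5L,
  seed = 1L
)

#' Read a key-value analysis config file
#'
#' YAML `key: value` file with keys threshold_report, threshold_efficient,
#' e_hb_kj_per_bond, polysite_max_gap, marker_dg_cutoff,
#' marker_multisite_min, seed. Missing keys take the package defaults;
#' unknown keys are an error.
#'
#' @param path config file path, or NULL for pure defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_mirbind(sprintf("config file not found: %s", path),
                   "mirbind_io_error")
    }
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L) {
      stop_mirbind(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")),
                   "mirbind_config_error")
    }
    cfg[names(user)] <- user
  }
  cfg
}
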