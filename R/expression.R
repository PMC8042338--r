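# Expression context and marker rules. Genes split into low (< 10 RPKM) and
# high expression; a miRNA-gene association is a diagnostic marker candidate
# when its strongest site has |dG| above the cutoff (default 130 kJ/mol) or
# the miRNA has multiple sites in the gene's mRNA.

#' Classify a gene's expression level from RPKM
#'
#' Step function with a single breakpoint at 10 RPKM; 10 itself is "high".
#'
#' @param rpkm non-negative numeric vector.
#' @return character vector "low"/"high".
#' @export
classify_expression <- function(rpkm) {
  if (any(is.na(rpkm)) || any(rpkm < 0)) {
    stop_mirbind("rpkm must be non-negative", "mirbind_contract_error")
  }
  ifelse(rpkm < 10, "low", "high")
}

#' Summarize sites into miRNA-gene associations
#'
#' One association per (miRNA, gene): the best site (largest |dG|, ties by
#' higher ratio then earlier start), the site count, and the gene's
#' expression class.
#'
#' @param sites binding-site data.frame (needs mirna_id, gene, rpkm, region,
#'   start, delta_g, ratio).
#' @return data.frame with mirna_id, gene, rpkm, expression_class, n_sites,
#'   best_region, best_start, best_delta_g, best_ratio.
#' @export
associations <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(
      mirna_id = character(0), gene = character(0), rpkm = numeric(0),
      expression_class = character(0), n_sites = integer(0),
      best_region = character(0), best_start = integer(0),
      best_delta_g = numeric(0), best_ratio = numeric(0)
    ))
  }
  key <- paste(sites$mirna_id, sites$gene, sep = "\r")
  out <- do.call(rbind, lapply(split(sites, key), function(s) {
    ord <- order(s$delta_g, -s$ratio, s$start)  # most negative dG first
    b <- s[ord[[1]], ]
    data.frame(
      mirna_id = b$mirna_id, gene = b$gene, rpkm = b$rpkm,
      expression_class = classify_expression(b$rpkm),
      n_sites = nrow(s),
      best_region = b$region, best_start = b$start,
      best_delta_g = b$delta_g, best_ratio = b$ratio,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$gene, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag marker candidate associations
#'
#' marker = |best dG| strictly above `dg_cutoff`, OR at least `multisite_min`
#' sites of the miRNA in the gene (multiple binding sites compensate for
#' moderate per-site energy).
#'
#' @param assoc association data.frame from [associations()].
#' @param dg_cutoff free-energy magnitude cutoff, kJ/mol (default 130).
#' @param multisite_min minimum site count for the multi-site rule
#'   (default 5).
#' @return `assoc` with logical columns marker_energy, marker_multisite,
#'   marker.
#' @export
marker_candidates <- function(assoc, dg_cutoff = 130, multisite_min = 5L) {
  assoc$marker_energy <- abs(assoc$best_delta_g) > dg_cutoff
  assoc$marker_multisite <- assoc$n_sites >= multisite_min
  assoc$marker <- assoc$marker_energy | assoc$marker_multisite
  assoc
}

#' Pearson product-moment correlation
#'
#' Validated front door to the standard correlation: equal lengths of at
#' least 3 and non-degenerate variance in both arguments.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_mirbind("pearson_r needs two equal-length vectors of length >= 3",
                 "mirbind_contract_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_mirbind("correlation undefined: an argument has zero variance",
                 "mirbind_degenerate_error")
  }
  stats::cor(x, y, method = "pearson")
}
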