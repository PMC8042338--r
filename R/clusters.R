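# Cluster and compaction analysis. A cluster is a connected component of the
# interval-overlap graph over site intervals [start, start+length-1] (closed,
# overlap of >= 1 nt). Its compaction is the total member length, counting
# every start separately, divided by the realized union span: compaction > 1
# means sites overlap and compete for the same stretch of mRNA.

#' Group overlapping binding sites into clusters
#'
#' Connected components of interval overlap among the sites of one
#' transcript. Each start counts as a full member, so polysite runs
#' contribute their whole multiplicity to the cluster totals.
#'
#' @param sites binding sites of one transcript (any miRNAs).
#' @return data.frame of clusters sorted by span_start, with columns
#'   transcript_id, cluster_id, region, span_start, span_end, span_length,
#'   n_sites, total_site_length, compaction, distinct_mirna_count, and a
#'   list column `members` of row indices into `sites`.
#' @export
build_clusters <- function(sites) {
  empty <- data.frame(
    transcript_id = character(0), cluster_id = integer(0),
    region = character(0), span_start = integer(0), span_end = integer(0),
    span_length = integer(0), n_sites = integer(0),
    total_site_length = integer(0), compaction = numeric(0),
    distinct_mirna_count = integer(0)
  )
  if (nrow(sites) == 0L) return(empty)
  if (length(unique(sites$transcript_id)) > 1L) {
    stop_mirbind("build_clusters expects sites of a single transcript",
                 "mirbind_contract_error")
  }
  ir <- IRanges::IRanges(start = sites$start, width = sites$length)
  # min.gapwidth = 0: merge on true overlap only, never mere adjacency
  merged <- IRanges::reduce(ir, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(ir, merged)
  cluster_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  members <- split(seq_len(nrow(sites)), cluster_of)
  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    rows <- members[[k]]
    stats <- compaction_stats(sites$start[rows], sites$length[rows])
    region <- unique(sites$region[rows])
    data.frame(
      transcript_id = sites$transcript_id[[1]],
      cluster_id = k,
      region = if (length(region) == 1L) region else
        paste(sort(region), collapse = "/"),
      span_start = stats$span_start,
      span_end = stats$span_end,
      span_length = stats$span_length,
      n_sites = length(rows),
      total_site_length = stats$total_site_length,
      compaction = stats$compaction,
      distinct_mirna_count = length(unique(sites$mirna_id[rows])),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$span_start), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  out$members <- I(unname(members[order(vapply(members, function(r)
    min(sites$start[r]), numeric(1)))]))
  rownames(out) <- NULL
  out
}

#' Compaction statistics of a set of member sites
#'
#' total_site_length sums every member's length (each start counted
#' separately); span is the realized union interval unless an explicit span
#' is supplied (used when reproducing narrative cluster bounds); compaction
#' is their ratio, > 1 whenever any two members overlap and exactly 1 when
#' the members tile the span without overlap.
#'
#' @param starts member start positions (1-based).
#' @param lengths member lengths, nt (recycled to `starts`).
#' @param span_start,span_end optional explicit span bounds.
#' @return list with total_site_length, span_start, span_end, span_length,
#'   compaction, and compaction_1dp (reported to one decimal).
#' @export
compaction_stats <- function(starts, lengths, span_start = NULL,
                             span_end = NULL) {
  stopifnot(length(starts) >= 1L)
  lengths <- rep_len(lengths, length(starts))
  total <- sum(lengths)
  if (is.null(span_start)) span_start <- min(starts)
  if (is.null(span_end)) span_end <- max(starts + lengths - 1L)
  span_length <- span_end - span_start + 1L
  compaction <- total / span_length
  list(
    total_site_length = as.integer(total),
    span_start = as.integer(span_start),
    span_end = as.integer(span_end),
    span_length = as.integer(span_length),
    compaction = compaction,
    compaction_1dp = round_half_away(compaction * 10) / 10
  )
}

#' Recurrent start offsets between two miRNAs across genes
#'
#' For each requested (mirna_a, mirna_b) pair and each gene in which both
#' have at least one site, matches the nearest pair of starts (the pairing
#' minimizing the absolute start difference) and records the signed offset
#' start_b - start_a. A pattern is `constant` when every gene agrees on the
#' offset. Genes carrying only one of the two miRNAs are omitted and listed
#' in the `skipped` attribute.
#'
#' @param sites binding sites across genes (needs mirna_id, gene, start).
#' @param pairs list of two-element character vectors c(mirna_a, mirna_b).
#' @return data.frame with mirna_a, mirna_b, gene, start_a, start_b, offset,
#'   constant (per-pair flag); attribute "skipped" records omitted genes.
#' @export
offset_patterns <- function(sites, pairs) {
  rows <- list()
  skipped <- list()
  for (p in pairs) {
    a <- p[[1]]; b <- p[[2]]
    genes <- sort(unique(sites$gene[sites$mirna_id %in% c(a, b)]))
    for (g in genes) {
      sa <- sort(unique(sites$start[sites$mirna_id == a & sites$gene == g]))
      sb <- sort(unique(sites$start[sites$mirna_id == b & sites$gene == g]))
      if (length(sa) == 0L || length(sb) == 0L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          mirna_a = a, mirna_b = b, gene = g,
          reason = sprintf("no site for %s", if (length(sa) == 0L) a else b),
          stringsAsFactors = FALSE
        )
        next
      }
      d <- outer(sb, sa, "-")
      best <- which(abs(d) == min(abs(d)), arr.ind = TRUE)[1, , drop = TRUE]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_a = a, mirna_b = b, gene = g,
        start_a = sa[[best[["col"]]]],
        start_b = sb[[best[["row"]]]],
        offset = d[[best[["row"]], best[["col"]]]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(mirna_a = character(0), mirna_b = character(0),
               gene = character(0), start_a = integer(0),
               start_b = integer(0), offset = integer(0))
  if (nrow(out) > 0L) {
    key <- paste(out$mirna_a, out$mirna_b, sep = "\r")
    const <- tapply(out$offset, key, function(x) length(unique(x)) == 1L)
    out$constant <- unname(const[key])
  } else {
    out$constant <- logical(0)
  }
  attr(out, "skipped") <- if (length(skipped) > 0L)
    do.call(rbind, skipped) else NULL
  rownames(out) <- NULL
  out
}

#' Per-region summary of sites and clusters
#'
#' Counts sites and clusters per region, how many clusters have two or more
#' members, the compaction distribution, and how many genes carry sites of
#' a single versus multiple distinct miRNAs.
#'
#' @param sites combined binding-site data.frame (possibly many transcripts).
#' @param clusters optional precomputed clusters (per transcript, rbind-ed);
#'   computed from `sites` when NULL.
#' @return list with `regions` (data.frame region, n_sites, n_clusters,
#'   n_multi_clusters, mean_compaction, max_compaction) and `genes`
#'   (data.frame gene, n_mirnas, multi_mirna).
#' @export
summarize_by_region <- function(sites, clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- do.call(rbind, lapply(split(sites, sites$transcript_id),
                                      build_clusters))
    if (is.null(clusters)) clusters <- build_clusters(sites[0, ])
  }
  regions <- sort(unique(c(sites$region, clusters$region)))
  reg <- do.call(rbind, lapply(regions, function(r) {
    cl <- clusters[clusters$region == r, , drop = FALSE]
    data.frame(
      region = r,
      n_sites = sum(sites$region == r),
      n_clusters = nrow(cl),
      n_multi_clusters = sum(cl$n_sites >= 2L),
      mean_compaction = if (nrow(cl) > 0L) mean(cl$compaction) else NA_real_,
      max_compaction = if (nrow(cl) > 0L) max(cl$compaction) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(reg)) {
    reg <- data.frame(region = character(0), n_sites = integer(0),
                      n_clusters = integer(0), n_multi_clusters = integer(0),
                      mean_compaction = numeric(0), max_compaction = numeric(0))
  }
  gene_counts <- if (nrow(sites) > 0L) {
    tab <- tapply(sites$mirna_id, sites$gene,
                  function(x) length(unique(x)))
    data.frame(gene = names(tab), n_mirnas = as.integer(tab),
               multi_mirna = as.integer(tab) > 1L,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = character(0), n_mirnas = integer(0),
               multi_mirna = logical(0))
  }
  list(regions = reg, genes = gene_counts)
}
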