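# Reported reference site tables. The package ships, as plain TSVs under
# extdata, the printed per-gene site tables for the worked examples (start
# positions, dG, dG/dGm, lengths, expression values). Ranged start runs
# ("a..b" with a count) are expanded to explicit starts only when the run is
# uniformly spaced ((b - a) divisible by n - 1); otherwise first/last/count
# are kept and the row is excluded from per-start analyses.

#' Load the reported reference site tables
#'
#' @param region "5UTR", "CDS", "3UTR" or "all".
#' @return data.frame, one row per reported table row, with `starts` as a
#'   list column of explicit starts (NULL when not expandable), plus
#'   start_first, start_last, n_starts, delta_g_lo/hi (kJ/mol, lo is the
#'   most negative), ratio_lo/hi (percent), length_nt, gene_rpkm and
#'   host_rpkm (miRNA host-gene RPKM where printed).
#' @export
reported_sites <- function(region = c("all", "5UTR", "CDS", "3UTR")) {
  region <- match.arg(region)
  files <- c("5UTR" = "reported_sites_5utr.tsv",
             "CDS" = "reported_sites_cds.tsv",
             "3UTR" = "reported_sites_3utr.tsv")
  if (region != "all") files <- files[region]
  tabs <- lapply(files, function(f) {
    path <- system.file("extdata", f, package = "mirbind", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  parsed <- lapply(tab$starts, .parse_starts)
  tab$start_first <- vapply(parsed, function(p) p$first, integer(1))
  tab$start_last <- vapply(parsed, function(p) p$last, integer(1))
  explicit <- lapply(seq_len(nrow(tab)), function(i) {
    .expand_starts(parsed[[i]], tab$n_starts[[i]])
  })
  tab$starts <- I(explicit)
  tab
}

.parse_starts <- function(s) {
  if (grepl("..", s, fixed = TRUE)) {
    ends <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    list(first = ends[[1]], last = ends[[2]], explicit = NULL)
  } else {
    v <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    list(first = min(v), last = max(v), explicit = v)
  }
}

.expand_starts <- function(p, n) {
  if (!is.null(p$explicit)) {
    stopifnot(length(p$explicit) == n)
    return(p$explicit)
  }
  if (n > 1L && (p$last - p$first) %% (n - 1L) == 0L) {
    return(as.integer(seq(p$first, p$last, length.out = n)))
  }
  NULL  # non-uniform run: starts not individually known
}

#' Reported tables in long (one row per site start) form
#'
#' Rows whose starts are individually known (explicit or uniformly spaced)
#' are expanded to one row per start, shaped like scanner output so the
#' cluster, polysite, offset and association operations apply directly.
#' Per-start dG/ratio are not individually printed for multi-start rows;
#' the row's strongest values (delta_g_lo, ratio_hi) are carried.
#'
#' @inheritParams reported_sites
#' @return binding-site-shaped data.frame (mirna_id, transcript_id, gene,
#'   rpkm, start, length, delta_g, ratio, region).
#' @export
reported_sites_long <- function(region = c("all", "5UTR", "CDS", "3UTR")) {
  tab <- reported_sites(region)
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    st <- tab$starts[[i]]
    if (is.null(st)) return(NULL)
    data.frame(
      mirna_id = tab$mirna_id[[i]],
      transcript_id = tab$gene[[i]],  # one reported transcript per gene
      gene = tab$gene[[i]],
      rpkm = tab$gene_rpkm[[i]],
      start = st,
      length = tab$length_nt[[i]],
      delta_g = tab$delta_g_lo[[i]],
      ratio = tab$ratio_hi[[i]],
      region = tab$region[[i]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
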