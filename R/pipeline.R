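# End-to-end orchestration: read inputs, scan, cluster, detect offsets and
# polysites, optionally analyze ortholog sets, rank marker candidates, and
# write one output directory with a run manifest. Stages are deterministic;
# any stage failure aborts with the stage name attached.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = c("mirbind_stage_error", "mirbind_error", "error", "condition"),
      list(message = sprintf("stage %s: %s", name, conditionMessage(e)),
           call = NULL, stage = name)
    ))
  })
}

#' Run the full analysis pipeline
#'
#' scan -> clusters -> polysites -> offsets -> (orthologs) -> markers, with
#' TSV/JSON outputs and a manifest (config snapshot, input digests, package
#' version, per-stage record counts). Identical config and inputs give
#' identical stage outputs; the manifest additionally records a wall-clock
#' timestamp.
#'
#' @param mirna_fasta path to the miRNA FASTA.
#' @param transcript_fasta path to the transcript FASTA.
#' @param annotation_tsv path to the transcript annotation TSV.
#' @param out_dir output directory (created if needed).
#' @param config named list from [read_config()] (or a path to a config
#'   file).
#' @param offset_pairs list of c(mirna_a, mirna_b) pairs to test for
#'   recurrent offsets; NULL skips the stage output (empty table).
#' @param ortholog_sets optional list of [ortholog_set()] objects with a
#'   `cluster_interval` attribute c(start, end) each; NULL skips.
#' @return invisibly, a list with the in-memory stage results and `paths`.
#' @export
run_pipeline <- function(mirna_fasta, transcript_fasta, annotation_tsv,
                         out_dir, config = read_config(),
                         offset_pairs = NULL, ortholog_sets = NULL) {
  if (is.character(config)) config <- read_config(config)
  model <- energy_model(config$e_hb_kj_per_bond)
  thresholds <- c(report = config$threshold_report,
                  efficient = config$threshold_efficient)

  mirnas <- .stage("io_formats", {
    validate_mirnas(read_fasta(mirna_fasta))
  })
  transcripts <- .stage("io_formats", {
    read_transcript_table(annotation_tsv, read_fasta(transcript_fasta))
  })

  sites <- .stage("site_scanner", {
    scan_cohort(mirnas, transcripts, thresholds = thresholds, model = model)
  })

  clusters <- .stage("cluster_analysis", {
    cl <- do.call(rbind, lapply(split(sites, sites$transcript_id),
                                build_clusters))
    if (is.null(cl)) cl <- build_clusters(sites[0, ])
    rownames(cl) <- NULL
    cl
  })

  polysites <- .stage("site_scanner", {
    keys <- unique(sites[, c("mirna_id", "transcript_id")])
    ps <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sub <- sites[sites$mirna_id == keys$mirna_id[[i]] &
                   sites$transcript_id == keys$transcript_id[[i]], ]
      group_polysites(sub, max_gap = config$polysite_max_gap)
    }))
    if (is.null(ps)) ps <- group_polysites(sites[0, ])
    ps
  })

  offsets <- .stage("cluster_analysis", {
    if (is.null(offset_pairs)) offset_pairs <- list()
    offset_patterns(sites, offset_pairs)
  })

  conservation <- NULL
  if (!is.null(ortholog_sets)) {
    conservation <- .stage("ortholog_conservation", {
      lapply(ortholog_sets, function(os) {
        iv <- attr(os, "cluster_interval")
        fl <- conserved_flanks(os, iv[[1]], iv[[2]])
        shrink <- cluster_shrinkage(os, iv[[1]], iv[[2]])
        ref <- os$segments[[os$reference_species]]
        subs <- lapply(setdiff(names(os$segments), os$reference_species),
                       function(sp) {
                         c(list(species = sp),
                           as.list(classify_substitutions(
                             ref, os$segments[[sp]])$counts))
                       })
        list(locus = os$locus, flank5 = fl$flank5, flank3 = fl$flank3,
             shrinkage = shrink, substitutions = subs)
      })
    })
  }

  markers <- .stage("expression_context", {
    marker_candidates(associations(sites),
                      dg_cutoff = config$marker_dg_cutoff,
                      multisite_min = config$marker_multisite_min)
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    sites = file.path(out_dir, "sites.tsv"),
    clusters = file.path(out_dir, "clusters.json"),
    polysites = file.path(out_dir, "polysites.tsv"),
    offsets = file.path(out_dir, "offsets.tsv"),
    conservation = file.path(out_dir, "conservation.json"),
    markers = file.path(out_dir, "markers.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_site_table(sites, paths$sites)
  cl_out <- clusters
  cl_out$members <- NULL
  jsonlite::write_json(cl_out, paths$clusters, digits = NA, pretty = TRUE)
  ps_out <- polysites
  ps_out$starts <- vapply(ps_out$starts, paste, character(1), collapse = ",")
  utils::write.table(ps_out, paths$polysites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  off_out <- offsets
  utils::write.table(off_out, paths$offsets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(conservation)) {
    jsonlite::write_json(conservation, paths$conservation,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    paths$conservation <- NULL
  }
  utils::write.table(markers, paths$markers, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    tool = "mirbind",
    version = as.character(utils::packageVersion("mirbind")),
    generated_at = format(Sys.time(), tz = "UTC"),
    config = config,
    inputs = as.list(tools::md5sum(c(mirna_fasta, transcript_fasta,
                                     annotation_tsv))),
    counts = list(
      mirnas = nrow(mirnas), transcripts = nrow(transcripts),
      sites = nrow(sites), clusters = nrow(clusters),
      polysites = nrow(polysites), offsets = nrow(offsets),
      markers = sum(markers$marker)
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(mirnas = mirnas, transcripts = transcripts, sites = sites,
                 clusters = clusters, polysites = polysites,
                 offsets = offsets, conservation = conservation,
                 markers = markers, paths = paths))
}
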