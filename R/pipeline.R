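#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic pipeline in one
#' serializable list; a config plus its seed reproduces a run's outputs
#' exactly, stochastic steps included.
#'
#' @param n_regions,n_hubs parcellation size and hub count.
#' @param volume_spec lognormal volume model, see [make_parcellation()].
#' @param grid_shape label-volume grid dimensions.
#' @param w_in,w_out,hub_boost block-model weights, see
#'   [make_ground_truth_matrix()].
#' @param n_subjects,n_runs,n_streamlines ensemble design.
#' @param subject_noise_sd inter-subject lognormal noise sd.
#' @param remove_labels labels removed in the restricted variant (default:
#'   the hub labels).
#' @param restrict_mode restriction mode, see [restrict_connectome()].
#' @param measures centrality measures to rank.
#' @param n_restarts Louvain restarts.
#' @param top_edges number of strongest edges exported per variant.
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_regions = 10L, n_hubs = 1L,
                            volume_spec = list(median = 5000, sdlog = 0.5,
                                               hub_multiplier = 3),
                            grid_shape = c(24L, 24L, 24L),
                            w_in = 2, w_out = 1, hub_boost = 3,
                            n_subjects = 4L, n_runs = 2L,
                            n_streamlines = 2000L, subject_noise_sd = 0.2,
                            remove_labels = NULL,
                            restrict_mode = "traversal_filter",
                            measures = c("degree", "eigenvector",
                                         "betweenness"),
                            n_restarts = 10L, top_edges = 20L, seed = 1L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic connectome analysis pipeline
#'
#' Orchestrates the whole study design end to end: simulate a parcellation,
#' label volume, planted-hub ground truth, and multi-subject/multi-run
#' endpoint ensemble; build per-run matrices and average them per subject;
#' derive the four connectome variants (extended/restricted x
#' raw/volume-normalized, restriction via the configured mode); rank
#' structures by every centrality measure with cross-subject means and SDs;
#' and summarize global topology (efficiency, ultimate modularity, global
#' reaching centrality) per variant. When `config$out_dir` is set, writes
#' group-mean matrices (TSV + JSON sidecar), ranking tables, topology
#' tables, community partitions, top-edge lists, and a provenance JSON;
#' reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a report bundle: list with `parcellation`,
#'   `ground_truth`, `variants` (per-subject matrices per variant),
#'   `group_means`, `rankings` (variant -> measure -> ranking table),
#'   `topology`, `discards`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  parc <- stage("parcellation",
                make_parcellation(cfg$n_regions, cfg$n_hubs, cfg$volume_spec,
                                  seed = derive_seed(cfg$seed, 1L)))
  lv <- stage("label_volume",
              make_label_volume(parc, cfg$grid_shape,
                                seed = derive_seed(cfg$seed, 2L)))
  gt <- stage("ground_truth",
              make_ground_truth_matrix(parc, cfg$w_in, cfg$w_out,
                                       cfg$hub_boost,
                                       seed = derive_seed(cfg$seed, 3L)))
  ens <- stage("ensemble",
               generate_ensemble(gt, lv, cfg$n_subjects, cfg$n_runs,
                                 cfg$n_streamlines, cfg$subject_noise_sd,
                                 seed = derive_seed(cfg$seed, 4L)))

  remove_labels <- as.integer(cfg$remove_labels %||% hub_ids(parc))
  keep_labels <- setdiff(parc$label_id, remove_labels)
  if (length(keep_labels) == 0L) stop("restriction removes every structure")
  parc_res <- parcellation(as.data.frame(parc)[parc$label_id %in% keep_labels, ,
                                               drop = FALSE])

  sids <- vapply(ens, function(e) e$subject_id, numeric(1))
  by_subject <- split(ens, factor(sids, levels = sort(unique(sids))))
  discards <- list()
  build_variant <- function(restricted) {
    lapply(by_subject, function(runs) {
      mats <- lapply(runs, function(es) {
        if (restricted) {
          restrict_connectome(es, keep_labels, mode = cfg$restrict_mode,
                              lv = lv, parc = parc)
        } else {
          build_matrix(es, lv, parc)
        }
      })
      for (m in mats) {
        discards[[length(discards) + 1L]] <<- m$discards
      }
      average_runs(mats)
    })
  }
  ext_raw <- stage("build_extended", build_variant(restricted = FALSE))
  res_raw <- stage("build_restricted", build_variant(restricted = TRUE))
  ext_norm <- stage("volume_normalize",
                    lapply(ext_raw, volume_normalize, volumes = parc))
  res_norm <- stage("volume_normalize",
                    lapply(res_raw, volume_normalize, volumes = parc_res))

  variants <- list(extended_raw = ext_raw,
                   extended_volnorm = ext_norm,
                   restricted_raw = res_raw,
                   restricted_volnorm = res_norm)
  group_means <- lapply(variants, function(v) average_subjects(v))

  rankings <- stage("centrality", lapply(variants, function(mats) {
    out <- lapply(cfg$measures, function(ms) {
      rank_structures(per_subject_centralities(mats, ms))
    })
    names(out) <- cfg$measures
    out
  }))

  topology <- stage("topology",
                    integration_segregation_summary(
                      variants, seed = derive_seed(cfg$seed, 5L),
                      n_restarts = cfg$n_restarts))

  tally <- Reduce(function(a, b) {
    keys <- union(names(a), names(b))
    av <- stats::setNames(rep(0, length(keys)), keys)
    av[names(a)] <- av[names(a)] + a
    av[names(b)] <- av[names(b)] + b
    av
  }, discards, numeric(0))

  bundle <- list(parcellation = parc, ground_truth = gt,
                 label_volume = lv, variants = variants,
                 group_means = group_means, rankings = rankings,
                 topology = topology, discards = tally, config = cfg,
                 files = character(0))
  if (!is.null(cfg$out_dir)) {
    bundle$files <- write_report_bundle(bundle, cfg$out_dir)
  }
  invisible(bundle)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  files <- character(0)
  emit <- function(p) { files <<- c(files, p); p }

  write_parcellation_csv(bundle$parcellation,
                         emit(file.path(out_dir, "parcellation.csv")))
  write_label_nifti(bundle$label_volume,
                    emit(file.path(out_dir, "labels.nii")))
  for (vn in names(bundle$group_means)) {
    gm <- bundle$group_means[[vn]]
    write_matrix_tsv(gm$mean_matrix,
                     emit(file.path(out_dir, sprintf("matrix_%s.tsv", vn))),
                     provenance = list(seed = cfg$seed,
                                       n_subjects = gm$n_subjects,
                                       n_runs = cfg$n_runs))
    for (ms in names(bundle$rankings[[vn]])) {
      rt <- bundle$rankings[[vn]][[ms]]
      utils::write.csv(as.data.frame(rt),
                       emit(file.path(out_dir,
                                      sprintf("ranking_%s_%s.csv", vn, ms))),
                       row.names = FALSE)
    }
    lp <- louvain_partition(gm$mean_matrix,
                            seed = derive_seed(cfg$seed, 6L),
                            n_restarts = cfg$n_restarts)
    utils::write.csv(data.frame(node = names(lp$membership),
                                community = unname(lp$membership)),
                     emit(file.path(out_dir,
                                    sprintf("partition_%s.csv", vn))),
                     row.names = FALSE)
    w <- gm$mean_matrix$weights
    ut <- which(upper.tri(w), arr.ind = TRUE)
    ew <- w[upper.tri(w)]
    ord <- order(-ew, ut[, 1], ut[, 2])[seq_len(min(cfg$top_edges, length(ew)))]
    utils::write.csv(data.frame(
      from = gm$mean_matrix$node_names[ut[ord, 1]],
      to = gm$mean_matrix$node_names[ut[ord, 2]],
      weight = ew[ord]),
      emit(file.path(out_dir, sprintf("edges_top_%s.csv", vn))),
      row.names = FALSE)
  }
  utils::write.csv(bundle$topology$per_matrix,
                   emit(file.path(out_dir, "topology_per_matrix.csv")),
                   row.names = FALSE)
  utils::write.csv(bundle$topology$centroids,
                   emit(file.path(out_dir, "topology_centroids.csv")),
                   row.names = FALSE)
  prov <- list(config = unclass(cfg), discards = as.list(bundle$discards),
               package_version = as.character(utils::packageVersion("brainhub")))
  jsonlite::write_json(prov, emit(file.path(out_dir, "provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files
}
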