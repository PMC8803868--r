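# Configuration-driven end-to-end pipeline and plain-text serialisation.
# Maps travel as one CSV matrix plus one JSON metadata record each;
# tables as CSV; configuration as YAML (or JSON); every run directory
# carries a provenance record.

#' Write a cohort to a directory
#'
#' Serialises each map as a CSV amplitude matrix (rows = grid rows,
#' columns = mediolateral sites) plus a JSON metadata record (geometry,
#' condition, resolution, positions), the behaviour table as CSV, and a
#' JSON manifest.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  map_dir <- file.path(dir, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$maps) {
    utils::write.csv(m$amplitudes,
                     file.path(map_dir, paste0(m$map_id, ".csv")),
                     row.names = FALSE)
    meta <- list(
      map_id = m$map_id, subject_id = m$subject_id,
      condition = m$condition, site_size = m$site_size,
      positions = m$positions,
      geometry = list(band_widths = as.list(m$geometry$band_widths),
                      pc_position = m$geometry$pc_position,
                      midline_position = m$geometry$midline_position)
    )
    jsonlite::write_json(meta, file.path(map_dir, paste0(m$map_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cohort$behavior)) {
    utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$features)) {
    utils::write.csv(data.frame(map_id = rownames(cohort$features),
                                cohort$features, check.names = FALSE),
                     file.path(dir, "features.csv"), row.names = FALSE)
  }
  manifest <- list(
    n_maps = length(cohort$maps),
    map_ids = vapply(cohort$maps, function(m) m$map_id, character(1)),
    conditions = as.character(cohort$labels),
    resolution = cohort$config$resolution,
    seed = cohort$config$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Inverse of [write_cohort()]: reconstructs the maps (amplitudes,
#' positions, geometry, metadata), labels, and the behaviour table when
#' present. Graph features are not recomputed.
#'
#' @param dir directory written by [write_cohort()].
#' @return object of class `cohort` (without `config`; `features` read
#'   from file when present).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  maps <- lapply(manifest$map_ids, function(id) {
    amp <- as.matrix(utils::read.csv(
      file.path(dir, "maps", paste0(id, ".csv"))))
    dimnames(amp) <- NULL
    meta <- jsonlite::read_json(file.path(dir, "maps", paste0(id, ".json")),
                                simplifyVector = TRUE)
    geom <- zebrin_geometry(unlist(meta$geometry$band_widths),
                            pc_position = meta$geometry$pc_position,
                            midline_position = meta$geometry$midline_position)
    connectivity_map(amp, meta$site_size, meta$positions, geom,
                     condition = meta$condition, map_id = meta$map_id,
                     subject_id = meta$subject_id)
  })
  behavior <- NULL
  if (file.exists(file.path(dir, "behavior.csv"))) {
    behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
                                stringsAsFactors = FALSE)
  }
  features <- NULL
  if (file.exists(file.path(dir, "features.csv"))) {
    ft <- utils::read.csv(file.path(dir, "features.csv"),
                          check.names = FALSE)
    features <- as.matrix(ft[, -1, drop = FALSE])
    rownames(features) <- ft[[1]]
  }
  structure(
    list(maps = maps,
         labels = factor(manifest$conditions,
                         levels = unique(manifest$conditions)),
         group_codes = if (!is.null(behavior)) behavior$group_code else NULL,
         features = features, behavior = behavior, config = NULL),
    class = "cohort"
  )
}

#' Pipeline configuration
#'
#' All stage parameters in one serialisable list. Defaults follow the
#' published settings: z threshold 3, triangular kernel half-widths 9/18
#' um, averaging bins 30/60 um, at least 10 null graphs, a 150-tree
#' depth-30 random forest over 100 stratified 80:20 trials, and a
#' 100-trial 75:25 GLM.
#'
#' @param cohort a [cohort_config()] (or arguments for one, via `...`).
#' @param stages named logical list toggling `process`, `graph`,
#'   `zones`, `classify`, `predict`.
#' @param n_nulls null-ensemble size for relative features (0 skips
#'   them).
#' @param zone_template structural template for zone analyses.
#' @param seed global seed (propagated to the cohort when it has none).
#' @param ... passed to [cohort_config()] when `cohort` is `NULL`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            stages = list(process = TRUE, graph = TRUE,
                                          zones = TRUE, classify = TRUE,
                                          predict = TRUE),
                            n_nulls = 0, zone_template = "bands8",
                            seed = 1L, ...) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed, ...)
  structure(
    list(cohort = cohort, stages = stages, n_nulls = n_nulls,
         zone_template = zone_template, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path (`.yaml`).
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$conditions <- as.list(x$cohort$conditions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cc <- x$cohort
  cc$conditions <- as.data.frame(cc$conditions, stringsAsFactors = FALSE)
  cohort <- do.call(cohort_config, cc[c("conditions", "resolution",
                                        "noise_mean", "noise_sd", "frac_sd",
                                        "patch_centers", "patch_center_sds",
                                        "patch_center_weights",
                                        "patch_ml_radius", "patch_row_radius",
                                        "n_trials", "glm_coef",
                                        "behavior_noise_sd", "seed")])
  pipeline_config(cohort = cohort, stages = x$stages, n_nulls = x$n_nulls,
                  zone_template = x$zone_template, seed = x$seed)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, then runs the enabled stages: map
#' processing (z-scoring, active-site statistics, profiles), graph
#' construction and feature assembly, structural/functional zoning with
#' normalised mutual information, random-forest classification of the
#' conditions, and GLM prediction of the behavioural feature. Artifacts
#' are written as CSV/JSON under `out_dir` together with a provenance
#' record; a rerun with the same configuration reproduces them exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param cohort optional pre-built [generate_cohort()] result; by
#'   default the cohort is generated from `config$cohort`.
#' @return list with the in-memory stage results (`cohort`, `features`,
#'   `zones_mi`, `classification`, `prediction`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  on <- function(s) isTRUE(st[[s]])
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  res <- list(cohort = cohort)
  cc <- cohort$config
  noise_mean <- if (!is.null(cc)) cc$noise_mean else 6
  noise_sd <- if (!is.null(cc)) cc$noise_sd else 3

  if (on("process")) {
    stats_tab <- do.call(rbind, lapply(cohort$maps, function(m) {
      zm <- compute_zscore_map(m, noise_mean = noise_mean,
                               noise_sd = noise_sd)
      s <- active_site_stats(zm, m)
      prof <- project_profile(m, zm, mode = "max_weight")
      cum <- cumulative_strength(prof)
      data.frame(map_id = m$map_id, condition = m$condition,
                 fraction_active = s$fraction_active,
                 n_active = s$n_active,
                 mean_active_amplitude = if (s$n_active) mean(s$amplitudes)
                                         else NA_real_,
                 total_strength_nA = max(cum$cumulative_nA))
    }))
    utils::write.csv(stats_tab, file.path(out_dir, "map_stats.csv"),
                     row.names = FALSE)
    res$map_stats <- stats_tab
  }

  graphs <- partitions <- NULL
  if (on("graph") || on("zones")) {
    graphs <- lapply(cohort$maps, build_correlation_graph)
    partitions <- lapply(seq_along(graphs), function(i) {
      detect_modules(graphs[[i]], seed = config$seed + 3000L + i)
    })
  }
  if (on("graph")) {
    feats <- t(vapply(seq_along(graphs), function(i) {
      assemble_features(graphs[[i]], partitions[[i]], scheme = "g_bilateral")
    }, numeric(7)))
    rownames(feats) <- vapply(cohort$maps, function(m) m$map_id, character(1))
    if (config$n_nulls > 0) {
      rel <- t(vapply(seq_along(graphs), function(i) {
        nulls <- null_ensemble(graphs[[i]], n_nulls = config$n_nulls,
                               seed = config$seed + 5000L + i)
        assemble_features(graphs[[i]], partitions[[i]],
                          scheme = "g_bilateral", relative = TRUE,
                          nulls = nulls, seed = config$seed + 6000L + i)
      }, numeric(7)))
      colnames(rel) <- paste0("rel_", colnames(feats))
      feats <- cbind(feats, rel)
    }
    utils::write.csv(data.frame(map_id = rownames(feats), feats,
                                check.names = FALSE),
                     file.path(out_dir, "graph_features.csv"),
                     row.names = FALSE)
    res$features <- feats
  }

  if (on("zones")) {
    mi_tab <- do.call(rbind, lapply(seq_along(graphs), function(i) {
      m <- cohort$maps[[i]]
      sz <- structural_zones(m$positions, m$geometry,
                             template = config$zone_template)
      fz_c <- functional_zones(partitions[[i]], "contiguous")
      fz_m <- functional_zones(partitions[[i]], "modulewise")
      data.frame(map_id = m$map_id,
                 nmi_contiguous = normalized_mi(sz, fz_c)$nmi,
                 nmi_modulewise = normalized_mi(sz, fz_m)$nmi,
                 n_modules = partitions[[i]]$n_modules)
    }))
    utils::write.csv(mi_tab, file.path(out_dir, "zones_mi.csv"),
                     row.names = FALSE)
    res$zones_mi <- mi_tab
  }

  if (on("classify")) {
    feats <- if (!is.null(res$features)) res$features[, 1:7, drop = FALSE]
             else cohort$features
    cls <- classify_conditions(feats, cohort$labels,
                               seed = config$seed + 7000L)
    jsonlite::write_json(
      list(summary = as.list(cls$summary),
           confusion = as.data.frame(cls$confusion)),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
    res$classification <- cls
  }

  if (on("predict") && !is.null(cohort$behavior)) {
    feats <- if (!is.null(res$features)) res$features[, 1:7, drop = FALSE]
             else cohort$features
    prd <- glm_predict(feats, cohort$behavior$y,
                       cohort$behavior$group_code,
                       seed = config$seed + 8000L)
    jsonlite::write_json(
      list(summary = as.list(prd$summary),
           coefficients = as.list(prd$coefficients)),
      file.path(out_dir, "prediction.json"), auto_unbox = TRUE, digits = NA)
    res$prediction <- prd
  }

  provenance <- list(
    package = "synaptograph",
    version = as.character(utils::packageVersion("synaptograph")),
    seed = config$seed,
    stages = st,
    timestamp_free = TRUE   # runs are content-addressed by config + seed
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
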