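# Pipeline orchestration: simulate -> template -> aggregate -> cluster ->
# evaluate -> render, with NIfTI-1 volumes on disk, JSON sidecar manifests,
# and a YAML config.  Every stage writes a manifest recording parameters,
# seeds and the config hash; reruns with the same config reproduce identical
# label outputs.  No stage mutates upstream artifacts.

PIPELINE_STAGES <- c("simulate", "template", "aggregate", "cluster",
                     "evaluate", "render")

#' Pipeline configuration
#'
#' @param out_dir output directory (stages write to `out_dir/<stage>/`).
#' @param seed master seed; all randomness flows from it.
#' @param grid grid shape in pixels.
#' @param pixel_size pixel size in micrometres.
#' @param n_subjects subjects to simulate.
#' @param levels level labels (default: the full 31-level scheme).
#' @param noise_scale,deform_amplitude generator parameters.
#' @param merge_lfvf 8-tract reference convention (see [toy_atlas_spec()]).
#' @param registration list of [registration_config()] overrides.
#' @param n_clusters cluster count; or `sweep = c(from, to)` for a sweep.
#' @param sweep optional integer range `c(from, to)`.
#' @param mode `"slice"` or `"region"` clustering driver.
#' @param scheme connectivity scheme.
#' @param metrics optional metric subset for clustering.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "cordparc_out", seed = 1L,
                            grid = c(64L, 64L), pixel_size = 50,
                            n_subjects = 5L, levels = NULL, noise_scale = 1,
                            deform_amplitude = 1.5, merge_lfvf = FALSE,
                            registration = list(), n_clusters = 8L,
                            sweep = NULL, mode = c("slice", "region"),
                            scheme = "axial4", metrics = NULL) {
  mode <- match.arg(mode)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              grid = as.integer(grid), pixel_size = pixel_size,
              n_subjects = as.integer(n_subjects),
              levels = levels, noise_scale = noise_scale,
              deform_amplitude = deform_amplitude, merge_lfvf = merge_lfvf,
              registration = registration, n_clusters = as.integer(n_clusters),
              sweep = sweep, mode = mode, scheme = scheme, metrics = metrics)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration (YAML)
#'
#' The on-disk form round-trips losslessly.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("not a valid pipeline config: ", path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

reg_config_from <- function(config) {
  do.call(registration_config, config$registration %||% list())
}

write_nifti_map <- function(img, path, pixel_size) {
  img_out <- img
  img_out[is.na(img_out)] <- NaN
  RNifti::writeNifti(RNifti::asNifti(img_out, pixdim = c(pixel_size, pixel_size)),
                     path)
}

read_nifti_map <- function(path) {
  m <- RNifti::readNifti(path)
  m <- matrix(as.numeric(m), dim(m)[1], dim(m)[2])
  m[is.nan(m)] <- NA_real_
  m
}

write_manifest <- function(dir, stage, config, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(utils::packageVersion("cordparc")),
                     config = unclass(config),
                     config_hash = config_hash(unclass(config))),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Write a subject sample as NIfTI volumes plus JSON sidecar
#'
#' One volume per metric channel, one white-matter mask, one ground-truth
#' label volume; a JSON sidecar records the seed, parameters and the
#' pixel-center, 0-based row = dorsoventral / column = left-right coordinate
#' convention.
#'
#' @param sample a [sample_subject()] result.
#' @param dir output directory.
#' @export
write_subject <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- sample$stack$pixel_size
  for (m in METRIC_NAMES)
    write_nifti_map(sample$stack$metrics[[m]], file.path(dir, paste0(m, ".nii.gz")), ps)
  write_nifti_map(sample$stack$mask * 1, file.path(dir, "mask.nii.gz"), ps)
  write_nifti_map(sample$truth$labels + 0, file.path(dir, "labels.nii.gz"), ps)
  jsonlite::write_json(list(seed = sample$seed, level = sample$level,
                            subject = sample$subject,
                            noise_scale = sample$noise_scale,
                            deform_amplitude = sample$deform_amplitude,
                            tract_names = sample$truth$tract_names,
                            coordinate_convention = paste(
                              "pixel-center, 0-based; row = dorsoventral",
                              "(row 0 dorsal), column = left-right")),
                       file.path(dir, "sample.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run pipeline stages
#'
#' Stages execute in dependency order; `"all"` runs everything.  Each stage
#' writes its outputs and a manifest under `config$out_dir/<stage>/`.  A
#' stage whose upstream outputs are missing stops with an error naming the
#' stage to run first.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @param stage one of `"simulate"`, `"template"`, `"aggregate"`,
#'   `"cluster"`, `"evaluate"`, `"render"`, `"all"`.
#' @return invisibly, a list of stage outputs (kept in memory across stages
#'   within one call).
#' @export
run_pipeline <- function(config, stage = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!stage %in% c(PIPELINE_STAGES, "all"))
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(c(PIPELINE_STAGES, "all"), collapse = ", "))
  stages <- if (stage == "all") PIPELINE_STAGES
            else PIPELINE_STAGES[seq_len(match(stage, PIPELINE_STAGES))]
  state <- list()
  for (s in stages) state <- run_stage(s, config, state)
  invisible(state)
}

run_stage <- function(stage, config, state) {
  dir <- file.path(config$out_dir, stage)
  scheme <- level_scheme()
  lvls <- config$levels %||% scheme$levels
  spec <- toy_atlas_spec(shape = config$grid, pixel_size = config$pixel_size,
                         merge_lfvf = config$merge_lfvf)
  sig <- default_signatures(merge_lfvf = config$merge_lfvf)
  rcfg <- reg_config_from(config)
  need <- function(key, upstream) {
    if (is.null(state[[key]]))
      stop("stage '", stage, "' needs outputs of stage '", upstream,
           "'; run that stage (or 'all') first", call. = FALSE)
    state[[key]]
  }
  switch(stage,
    simulate = {
      cohort <- generate_cohort(spec, sig, config$n_subjects, scheme,
                                levels = lvls, noise_scale = config$noise_scale,
                                deform_amplitude = config$deform_amplitude,
                                seed = config$seed)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(cohort$samples))
        write_subject(cohort$samples[[nm]], file.path(dir, nm))
      write_manifest(dir, stage, config,
                     list(seeds = cohort$manifest$seeds,
                          n_samples = length(cohort$samples)))
      state$cohort <- cohort
      state
    },
    template = {
      cohort <- need("cohort", "simulate")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      templates <- lapply(lvls, function(l) build_template(cohort, l, rcfg))
      names(templates) <- lvls
      for (l in lvls)
        for (m in METRIC_NAMES)
          write_nifti_map(templates[[l]]$metrics[[m]],
                          file.path(dir, sprintf("%s_%s.nii.gz", l, m)),
                          config$pixel_size)
      write_manifest(dir, stage, config, list(levels = lvls))
      state$templates <- templates
      state
    },
    aggregate = {
      templates <- need("templates", "template")
      cohort <- need("cohort", "simulate")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      regions <- unique(unname(scheme$region[lvls]))
      agg <- lapply(regions, function(rg) {
        in_rg <- lvls[scheme$region[lvls] == rg]
        aggregate_region(templates[in_rg], cohort$atlases[in_rg], rg, rcfg)
      })
      names(agg) <- regions
      for (rg in regions) {
        for (m in METRIC_NAMES)
          write_nifti_map(agg[[rg]]$stack$metrics[[m]],
                          file.path(dir, sprintf("%s_%s.nii.gz", rg, m)),
                          config$pixel_size)
        RNifti::writeNifti(RNifti::asNifti(agg[[rg]]$soft$pv),
                           file.path(dir, sprintf("%s_soft_atlas.nii.gz", rg)))
      }
      write_manifest(dir, stage, config,
                     list(regions = regions,
                          n_maps = length(regions) * length(METRIC_NAMES)))
      state$aggregated <- agg
      state
    },
    cluster = {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      ks <- if (!is.null(config$sweep)) seq(config$sweep[1], config$sweep[2])
            else config$n_clusters
      inputs <- if (config$mode == "slice") {
        need("templates", "template")
      } else {
        lapply(need("aggregated", "aggregate"), `[[`, "stack")
      }
      parcs <- list()
      for (k in ks) {
        pk <- if (config$mode == "slice")
          cluster_slicewise(inputs, k, config$scheme, config$metrics)
        else cluster_regionwise(inputs, k, config$scheme, config$metrics)
        for (nm in names(pk))
          write_nifti_map(pk[[nm]]$labels + 0,
                          file.path(dir, sprintf("parcellation_k%d_%s.nii.gz", k, nm)),
                          config$pixel_size)
        parcs[[as.character(k)]] <- pk
      }
      write_manifest(dir, stage, config,
                     list(n_clusters = ks, mode = config$mode,
                          n_parcellations = sum(lengths(parcs))))
      state$parcellations <- parcs
      state
    },
    evaluate = {
      parcs <- need("parcellations", "cluster")
      cohort <- need("cohort", "simulate")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      results <- list()
      for (k in names(parcs)) {
        for (nm in names(parcs[[k]])) {
          if (config$mode == "slice") {
            atl <- cohort$atlases[[nm]]
            om <- overlap_matrix(parcs[[k]][[nm]], atl)
            a <- ari(parcs[[k]][[nm]], atl)
          } else {
            # soft (partial-volume) reference for aggregated regions; ARI
            # against the discrete atlas of the region's first level
            om <- overlap_matrix(parcs[[k]][[nm]], state$aggregated[[nm]]$soft)
            a <- ari(parcs[[k]][[nm]],
                     cohort$atlases[[lvls[scheme$region[lvls] == nm][1]]])
          }
          results[[paste0("k", k, "_", nm)]] <-
            list(overlap = unclass(om), ari = a,
                 recall = tract_recall(om),
                 colors = match_and_color(om))
        }
      }
      jsonlite::write_json(results, file.path(dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(dir, stage, config, list(n_evaluated = length(results)))
      state$evaluation <- results
      state
    },
    render = {
      parcs <- need("parcellations", "cluster")
      cohort <- need("cohort", "simulate")
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      n_files <- 0L
      for (k in names(parcs)) {
        for (nm in names(parcs[[k]])) {
          atl <- if (config$mode == "slice") cohort$atlases[[nm]]
                 else cohort$atlases[[lvls[scheme$region[lvls] == nm][1]]]
          om <- overlap_matrix(parcs[[k]][[nm]], atl)
          cols <- match_and_color(om)
          render_hemisection(parcs[[k]][[nm]], atl, cols,
                             file.path(dir, sprintf("hemisection_k%s_%s.png", k, nm)))
          n_files <- n_files + 1L
        }
      }
      write_manifest(dir, stage, config, list(n_rendered = n_files))
      state
    })
}
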