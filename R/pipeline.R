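## End-to-end pipeline configuration and orchestration.

#' Derive simulated annotations from ground truth
#'
#' Emulates the sparse click-annotation protocol on a simulated slice:
#' every lymphocyte (and memory-T) truth center becomes a cell annotation
#' whose Likert decorations are 5 for markers the phenotype expresses and
#' 1 otherwise; background-structure cells become background annotations;
#' `n_empty` additional background annotations are placed on random
#' cell-free pixels (sites without a cell).
#'
#' @param slice A `sim_slice` from [render_slice()].
#' @param n_empty Number of cell-free background annotations.
#' @param rng_seed Seed for the cell-free site draw.
#' @return An [annotation_set()].
#' @export
annotations_from_truth <- function(slice, n_empty = 25L, rng_seed = 1L) {
  tc <- slice$truth_centers
  profiles <- phenotype_profiles()
  mk <- phenotyping_markers()
  is_cell <- tc$phenotype != "background"
  lik <- t(vapply(tc$phenotype, function(ph)
    setNames(ifelse(mk %in% names(profiles[[ph]]), 5, 1), mk),
    numeric(length(mk))))
  xs <- round(tc$x_px); ys <- round(tc$y_px)
  kind <- ifelse(is_cell, "cell", "background")
  if (n_empty > 0) {
    set.seed(rng_seed)
    empty <- which(slice$truth_mask == 0L)
    sel <- sample(empty, min(n_empty, length(empty)))
    rc <- arrayInd(sel, dim(slice$truth_mask))
    xs <- c(xs, rc[, 2] - 1L); ys <- c(ys, rc[, 1] - 1L)
    kind <- c(kind, rep("background", nrow(rc)))
    lik <- rbind(lik, matrix(NA_real_, nrow(rc), length(mk)))
  }
  colnames(lik) <- mk
  annotation_set(xs, ys, kind, likert = as.data.frame(lik))
}

#' Ground-truth phenotype as it would be called from the panel
#'
#' Maps simulator phenotypes onto the called phenotype vocabulary:
#' memory-T cells (CD3+CD45RO+) are called `Th` since CD45RO is evaluated
#' on a continuum, and background-structure cells are `background`.
#'
#' @param phenotype Character vector of simulator phenotypes.
#' @return Character vector of called phenotypes.
#' @export
called_truth_phenotype <- function(phenotype) {
  out <- phenotype
  out[phenotype == "Tmem"] <- "Th"
  out
}

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with a
#' single master seed from which every stage seed is derived. Every
#' default is either a fixed pipeline constant (pixel size, panel, disk
#' radii, LoG parameters, cutoff, loss weights) or a documented package
#' choice.
#'
#' @param rng_seed Master seed.
#' @param side_um,density_fraction,n_slices Simulator settings.
#' @param width,fc_width,epochs,batch_size Network settings.
#' @param n_patches Training-set size cap after pooling tiles.
#' @param radius_um Matching radius for evaluation.
#' @param cutoff Pseudomarker positivity cutoff.
#' @return Nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, side_um = 64,
                            density_fraction = 0.25, n_slices = 2L,
                            width = 8L, fc_width = 24L, epochs = 10L,
                            batch_size = 32L, n_patches = 1500L,
                            radius_um = 3.5, cutoff = 0.4) {
  structure(list(
    rng_seed = as.integer(rng_seed),
    pixel_size_um = PIXEL_SIZE_UM,
    panel = panel_channels(),
    simulator = list(side_um = side_um, density_fraction = density_fraction,
                     n_slices = as.integer(n_slices),
                     phenotype_freqs = as.list(default_phenotype_freqs()),
                     cpm = cpm_params(),
                     noise = render_noise()),
    labels = list(disk_radius_px = ANNOTATION_DISK_PX, sample_fraction = 8,
                  max_patches_per_tile = 1000L),
    training = list(width = as.integer(width),
                    fc_width = as.integer(fc_width),
                    epochs = as.integer(epochs),
                    batch_size = as.integer(batch_size),
                    n_patches = as.integer(n_patches),
                    learning_rate = 1e-3, loss_weight_proximity = 1,
                    loss_weight_phenotype = 20, dropout = 0.2,
                    input_noise_sd = 0.1),
    detection = list(min_sigma = 3, max_sigma = 5, threshold = 0.07,
                     n_sigma = 10L, overlap = 0.5, cutoff = cutoff),
    evaluation = list(radius_um = radius_um, n_boot = 1000L),
    spatial = list(margin_um = 100, neighbor_radius_um = 14,
                   tumor_threshold = unclass(threshold_params()),
                   tissue_threshold = unclass(threshold_params()))),
    class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip load(dump(config)) is the identity.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Run the full pipeline on simulated tissue
#'
#' Executes simulate -> label -> train -> predict -> detect -> evaluate on
#' self-generated data, writing all artifacts (images, label maps, model,
#' prediction maps, cell table CSV, FCS export, metrics JSON, provenance
#' manifest) to `out_dir`. All randomness derives from the master seed, so
#' the same configuration reproduces the same cell table.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `model`, `detections`, `metrics`, and
#'   the paths of the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  seed <- config$rng_seed
  sim <- config$simulator

  say("simulating training volume (side ", sim$side_um, " um, fraction ",
      sim$density_fraction, ")")
  freqs <- unlist(sim$phenotype_freqs)
  st_train <- simulate_tissue(sim$side_um, sim$density_fraction, freqs,
                              rng_seed = seed, params = sim$cpm)
  train_slices <- render_slices(st_train, sim$n_slices,
                                noise = sim$noise, rng_seed = seed + 1L)
  say("simulating held-out volume")
  st_test <- simulate_tissue(sim$side_um, sim$density_fraction, freqs,
                             rng_seed = seed + 1000L, params = sim$cpm)
  test_slice <- render_slices(st_test, 1L, noise = sim$noise,
                              rng_seed = seed + 1001L)[[1]]

  say("building labels and sampling patches")
  patch_sets <- lapply(seq_along(train_slices), function(i) {
    sl <- train_slices[[i]]
    ann <- annotations_from_truth(sl, rng_seed = seed + 10L + i)
    maps <- build_label_maps(ann, dim(sl$truth_mask))
    sample_patches(normalize_tile(sl$image), maps, rng_seed = seed + 20L + i)
  })
  patches <- subsample_patches(do.call(combine_patches, patch_sets),
                               config$training$n_patches,
                               rng_seed = seed + 30L)

  say("training model on ", dim(patches$input)[4], " patches")
  tr <- config$training
  model <- build_model(tr$width, tr$fc_width, rng_seed = seed + 40L)
  cfg <- train_config(learning_rate = tr$learning_rate, epochs = tr$epochs,
                      batch_size = tr$batch_size,
                      loss_weight_proximity = tr$loss_weight_proximity,
                      loss_weight_phenotype = tr$loss_weight_phenotype,
                      dropout = tr$dropout,
                      input_noise_sd = tr$input_noise_sd,
                      rng_seed = seed + 41L)
  model <- train_model(model, patches, cfg)

  say("predicting held-out slice and detecting cells")
  det_cfg <- config$detection
  maps <- predict_tile(model, normalize_tile(test_slice$image))
  detections <- detect_and_phenotype(
    maps, cutoff = det_cfg$cutoff, min_sigma = det_cfg$min_sigma,
    max_sigma = det_cfg$max_sigma, threshold = det_cfg$threshold,
    n_sigma = det_cfg$n_sigma, overlap = det_cfg$overlap)

  say("evaluating against ground truth")
  truth <- data.frame(x = test_slice$truth_centers$x_px,
                      y = test_slice$truth_centers$y_px,
                      phenotype = called_truth_phenotype(
                        test_slice$truth_centers$phenotype))
  lym_truth <- truth[truth$phenotype %in% lymphocyte_phenotypes(), ]
  lym_det <- detections[detections$phenotype %in% lymphocyte_phenotypes(), ]
  mr <- match_roi(lym_truth, lym_det,
                  radius_um = config$evaluation$radius_um)
  metrics <- prf(list(mr), n_boot = config$evaluation$n_boot,
                 rng_seed = seed + 50L)

  say("writing artifacts")
  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    test_image = file.path(out_dir, "test_tile.tiff"),
    truth_mask = file.path(out_dir, "test_truth_mask.tiff"),
    truth_centers = file.path(out_dir, "test_truth_centers.csv"),
    proximity = file.path(out_dir, "predicted_maps.tiff"),
    cells = file.path(out_dir, "cell_table.csv"),
    fcs = file.path(out_dir, "cells.fcs"),
    metrics = file.path(out_dir, "metrics.json"),
    model = file.path(out_dir, "model.rds"),
    manifest = file.path(out_dir, "manifest.json"))
  write_config(config, paths$config)
  write_multiplex_tiff(test_slice$image, paths$test_image)
  tiff::writeTIFF(test_slice$truth_mask / 65535, paths$truth_mask,
                  bits.per.sample = 16L)
  write.csv(test_slice$truth_centers, paths$truth_centers,
            row.names = FALSE)
  pred_stack <- array(c(maps$proximity, unlist(maps$phenotype)),
                      dim = c(dim(maps$proximity), 6),
                      dimnames = list(NULL, NULL,
                                      c("proximity", names(maps$phenotype))))
  write_multiplex_tiff(pred_stack, paths$proximity)
  write_cell_table(detections, paths$cells)
  if (nrow(detections) > 0) export_fcs(detections, paths$fcs)
  jsonlite::write_json(metrics, paths$metrics, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, paths$model)
  jsonlite::write_json(list(
    package = "immunopoint",
    version = as.character(utils::packageVersion("immunopoint")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(paths$config)),
    rng_seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$manifest, auto_unbox = TRUE)

  invisible(list(model = model, detections = detections, metrics = metrics,
                 maps = maps, test_slice = test_slice, paths = paths))
}
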