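# End-to-end orchestration: simulate (optional) -> screen -> per-species
# MaxEnt evaluation -> AUC/CV exclusion -> binarize/stack/hotspots ->
# group importance -> preference -> landscape -> gap report, with one root
# seed, fixed output names and a JSON run manifest.

#' Pipeline configuration
#'
#' Defaults follow the analysis protocol: 1-km de-duplication before
#' snapping to the analysis grid, `|r| >= 0.8` correlation filtering, 10,000
#' background points, 75/25 subsample replicated 10 times, reliability
#' thresholds AUC > 0.90 and CV < 15%, a 10% contribution threshold for the
#' group-level climate predictors, 70/30 split with fivefold stratified CV
#' for the boosted trees, and a 900-m landscape window.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Root seed; all stage seeds derive from it.
#' @param dedup_cellsize,r_threshold,contribution_threshold,n_background
#'   Screening/modelling controls.
#' @param train_fraction,n_replicates,auc_min,cv_max MaxEnt evaluation
#'   protocol.
#' @param feature_classes MaxEnt feature classes.
#' @param gbt_split,gbt_folds,gbt_sample_cap Boosted-tree protocol.
#' @param window_edge Landscape window edge (map units).
#' @param density_window Group density window edge (map units).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("habistack_run_"), seed = 1,
                            dedup_cellsize = 1000, r_threshold = 0.8,
                            contribution_threshold = 10,
                            n_background = 10000, train_fraction = 0.75,
                            n_replicates = 10, auc_min = 0.90, cv_max = 0.15,
                            feature_classes = c("linear", "quadratic", "hinge"),
                            gbt_split = 0.7, gbt_folds = 5,
                            gbt_sample_cap = 100000,
                            window_edge = 900, density_window = 900) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            gbt_split > 0, gbt_split < 1,
            r_threshold > 0, r_threshold <= 1,
            contribution_threshold >= 0, n_background >= 1,
            n_replicates >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

write_csv_ <- function(d, dir, file) {
  utils::write.csv(d, file.path(dir, file), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: variable screening (preliminary all-variable fit for percent
#' contribution + Pearson filtering at occurrence points, per species),
#' replicate MaxEnt evaluation per species with the AUC/CV exclusion rule,
#' per-species binarization and stacking into richness/hotspot surfaces
#' (overall and per group), group-level boosted-tree climate importance,
#' land-use preference and terrain profiles, landscape diversity and
#' disturbance exposure, and the regional gap report. All artifacts are
#' written under `config$out_dir` with fixed names and a `manifest.json`.
#'
#' @param stack Environmental [raster_stack()].
#' @param occurrences Occurrence data.frame (`species`, `group`, `x`, `y`).
#' @param reserves Binary reserve [raster_layer()].
#' @param regions Integer-labelled region [raster_layer()].
#' @param config A [pipeline_config()].
#' @param climate_variables Layer names eligible as group-level climate
#'   predictors (default: layers named `bio*`).
#' @param write_rasters Also export richness/hotspot/density rasters as ASC
#'   (default TRUE).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(stack, occurrences, reserves, regions,
                         config = pipeline_config(),
                         climate_variables = NULL, write_rasters = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- stack$grid
  if (is.null(climate_variables))
    climate_variables <- grep("^bio", names(stack), value = TRUE)
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  occ <- dedup_grid(occurrences, config$dedup_cellsize)
  occ <- snap_occurrences(occ, g)
  species <- unique(occ$species)
  cont_vars <- names(stack)[vapply(stack$layers, function(l)
    l$kind == "continuous", logical(1))]
  tick("prepare")

  # --- per-species screening + evaluation -------------------------------
  reports <- list(); screenings <- list()
  for (sp in species) {
    occ_sp <- occ[occ$species == sp, ]
    cells <- unique(occ_sp$cell)
    sp_seed <- derive_seed(config$seed, "species", sp)
    valid <- finite_cells(stack)
    prelim <- with_seed(derive_seed(sp_seed, "prelim"), {
      bg <- sample(valid, min(config$n_background, length(valid)))
      fs <- build_features(stack, bg, classes = config$feature_classes,
                           variables = cont_vars)
      maxent_fit(fs, stack, cells, bg)
    })
    contrib_all <- percent_contribution(prelim)
    contrib <- stats::setNames(rep(0, length(cont_vars)), cont_vars)
    contrib[names(contrib_all)] <- contrib_all
    corr <- pearson_at_points(stack, occ_sp, variables = cont_vars)
    scr <- select_variables(contrib, corr, config$r_threshold)
    screenings[[sp]] <- scr
    reports[[sp]] <- evaluate_subsample(
      stack, cells, n_background = config$n_background,
      train_fraction = config$train_fraction,
      n_replicates = config$n_replicates, seed = sp_seed,
      classes = config$feature_classes, variables = scr$kept,
      auc_min = config$auc_min, cv_max = config$cv_max, species = sp)
  }
  scr_tab <- do.call(rbind, lapply(species, function(sp) {
    d <- screening_table(screenings[[sp]]); d$species <- sp; d
  }))
  write_csv_(scr_tab, config$out_dir, "screening.csv")
  eval_tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(species = r$species, auc_mean = r$auc_mean, auc_sd = r$auc_sd,
               cv = r$cv, excluded = r$excluded)))
  write_csv_(eval_tab, config$out_dir, "evaluation.csv")
  contrib_tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(species = r$species, variable = names(r$contributions),
               contribution = as.numeric(r$contributions))))
  write_csv_(contrib_tab, config$out_dir, "contributions.csv")
  tick("maxent")

  # --- exclusion rule, binarization, stacking ---------------------------
  kept_species <- names(reports)[!vapply(reports, `[[`, TRUE, "excluded")]
  write_csv_(eval_tab[eval_tab$excluded, c("species", "auc_mean", "cv")],
             config$out_dir, "exclusions.csv")
  binmaps <- list(); thresholds <- c()
  for (sp in kept_species) {
    b <- binarize_species(reports[[sp]]$mean_map, method = "jenks3_top")
    binmaps[[sp]] <- b
    thresholds[sp] <- attr(b, "threshold")
  }
  if (length(binmaps) == 0) stop("no species passed the AUC/CV rule")
  write_csv_(data.frame(species = names(thresholds),
                        threshold = as.numeric(thresholds)),
             config$out_dir, "binarization_thresholds.csv")
  richness <- stack_richness(binmaps, grid = g)
  hotspots <- suppressWarnings(classify_hotspots(richness))
  # suitable habitat = the top hotspot class (class 2 normally; under a
  # degenerate two-class coding, the upper class; empty when no cell is rich)
  top_class_mask <- function(hot, rich, name) {
    fin <- is.finite(hot$values)
    top <- max(hot$values[fin], 0)
    m <- ifelse(fin,
                as.numeric(hot$values == top & rich$values > 0), NA_real_)
    raster_layer(m, g, name = name, kind = "categorical")
  }
  suitable_all <- top_class_mask(hotspots, richness, "suitable")

  groups <- unique(occ$group[occ$species %in% kept_species])
  groups <- groups[!is.na(groups)]
  group_masks <- list(); group_density <- list()
  for (gr in groups) {
    sp_g <- intersect(kept_species,
                      unique(occ$species[occ$group == gr]))
    rich_g <- stack_richness(binmaps[sp_g], grid = g)
    hot_g <- suppressWarnings(classify_hotspots(rich_g))
    group_masks[[gr]] <- top_class_mask(hot_g, rich_g,
                                        paste0("suitable_", gr))
    group_density[[gr]] <- neighborhood_density(group_masks[[gr]],
                                                config$density_window)
  }
  uniq <- unique_group_cells(group_masks)
  if (write_rasters) {
    write_raster(richness, file.path(config$out_dir, "richness.asc"))
    write_raster(hotspots, file.path(config$out_dir, "hotspot3.asc"))
    for (gr in groups)
      write_raster(group_masks[[gr]],
                   file.path(config$out_dir, paste0("suitable_", gr, ".asc")))
    write_raster(uniq, file.path(config$out_dir, "unique_group.asc"))
  }
  tick("stack")

  # --- group-level climate importance -----------------------------------
  importance <- list()
  for (gr in groups) {
    sp_g <- intersect(kept_species, unique(occ$species[occ$group == gr]))
    contrib_g <- contrib_tab[contrib_tab$species %in% sp_g &
                               contrib_tab$variable %in% climate_variables, ]
    major <- unique(contrib_g$variable[
      contrib_g$contribution > config$contribution_threshold])
    if (length(major) == 0) major <- climate_variables
    importance[[gr]] <- tryCatch(
      fit_gbt(assemble_design(group_masks[[gr]], stack, major,
                              sample_cap = config$gbt_sample_cap,
                              seed = derive_seed(config$seed, "design", gr)),
              split = config$gbt_split, cv_folds = config$gbt_folds,
              seed = derive_seed(config$seed, "gbt", gr)),
      error = function(e) NULL)
  }
  imp_tab <- do.call(rbind, lapply(groups, function(gr) {
    r <- importance[[gr]]
    if (is.null(r)) return(NULL)
    cbind(data.frame(group = gr), r$importance,
          overall_accuracy = r$overall_accuracy)
  }))
  if (!is.null(imp_tab)) write_csv_(imp_tab, config$out_dir, "importance.csv")
  tick("importance")

  # --- preference, landscape, gaps --------------------------------------
  # land-cover and disturbance stages need the conventional layer names
  pref_tab <- NULL; sw <- NULL; expo <- NULL
  if ("lc" %in% names(stack)) {
    pref_tab <- do.call(rbind, lapply(groups, function(gr) {
      cbind(data.frame(group = gr),
            rf_index(occ[occ$group == gr, ], group_masks[[gr]],
                     stack[["lc"]]))
    }))
    write_csv_(pref_tab, config$out_dir, "preference.csv")
  }
  prof_tab <- terrain_profiles(group_masks, stack)
  if (!is.null(prof_tab))
    write_csv_(prof_tab, config$out_dir, "terrain_profiles.csv")
  tick("preference")

  if ("lc" %in% names(stack)) {
    sw <- shannon_window(stack[["lc"]], config$window_edge)
    if (write_rasters) {
      write_raster(sw$shdi, file.path(config$out_dir, "shdi.asc"))
      write_raster(sw$shei, file.path(config$out_dir, "shei.asc"))
    }
  }
  if ("net" %in% names(stack)) {
    expo <- exposure_summary(stack[["net"]], group_masks)
    write_csv_(expo, config$out_dir, "exposure.csv")
  }
  tick("landscape")

  gaps <- regional_overlay(suitable_all, reserves, regions)
  write_csv_(as.data.frame(gaps), config$out_dir, "gap_report.csv")
  tick("gaps")

  manifest <- list(
    package = "habistack",
    version = as.character(utils::packageVersion("habistack")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_species = length(species), kept_species = kept_species,
    excluded_species = setdiff(species, kept_species),
    groups = as.list(groups),
    stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = config, screening = screenings, reports = reports,
                 kept_species = kept_species, richness = richness,
                 hotspots = hotspots, suitable = suitable_all,
                 group_masks = group_masks, group_density = group_density,
                 unique_group = uniq, importance = importance,
                 preference = pref_tab, terrain = prof_tab,
                 landscape = sw, exposure = expo, gaps = gaps))
}
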