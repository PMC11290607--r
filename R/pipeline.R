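#' Default run configuration
#'
#' All stage parameters of the pipeline in one list; every stochastic stage
#' derives its seed deterministically from the master seed and the stage
#' name via [stage_seed()]. The defaults define the demonstration study:
#' a 60 x 60 synthetic world at 0.1 degrees, 15 species, one warming
#' scenario and horizon.
#'
#' @param seed master seed.
#' @param ... named overrides of any default entry.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    world = list(nrow = 60, ncol = 60, cellsize = 0.1, origin = c(-5, 40)),
    n_species = 15,
    scenarios = "MIROC-ESM-CHEM",
    periods = "2050",
    dirty_fraction = 0.1,
    max_uncertainty_m = 10000,
    min_year = 1970,
    min_distance_cells = 1,
    outlier_pct = 0.01,
    buffer_per_10months = 1e5,
    background_ratio = 2,
    min_presences = 30,
    train_frac = 0.75,
    auc_min = 0.7,
    boyce_min = 0.4,
    r_max = 0.5,
    vif_max = 3,
    keep_predictors = c("water", "elevation", "embergerQ",
                        "bio7", "bio8", "bio10", "bio15"),
    lambda_signal = 1,
    n_permutations = 199,
    subsets = list(all = NULL))
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline end-to-end
#'
#' Executes synthetic-data generation, occurrence preparation, predictor
#' derivation and collinearity filtering, per-species distribution
#' modelling, diversity mapping, range-shift computation and the comparative
#' analyses, in that order, writing every intermediate artefact (evaluation
#' CSV, alpha/beta rasters, shift tables, comparative results and a
#' machine-readable manifest) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir artefact directory (created if needed); `NULL` skips all
#'   file output.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every in-memory result: `world`, `pool`,
#'   `traits`, `trees`, `filter`, `species` (per-species fits and maps),
#'   `evaluation`, `facets` (per scenario/period), `shifts`, `shift_summary`,
#'   `comparative`, `manifest`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  t0 <- Sys.time()

  say("stage: synth")
  world <- do.call(generate_world,
                   c(config$world, list(seed = stage_seed(seed, "world"))))
  pool <- make_species_pool(world, config$n_species,
                            seed = stage_seed(seed, "species"))
  sim <- simulate_phylogeny_and_traits(
    config$n_species, lambda_signal = config$lambda_signal,
    seed = stage_seed(seed, "phylogeny"), n_traits = 6)
  traits <- synth_trait_table(sim, pool)

  say("stage: predictors")
  full_stack <- world_predictors(world, full = TRUE)
  flt <- filter_collinear(stack_values(full_stack),
                          r_max = config$r_max, vif_max = config$vif_max,
                          keep = config$keep_predictors)
  predictors <- intersect(names(full_stack$layers), flt$retained)
  cur_stack <- predictor_stack(full_stack$layers[predictors])
  grid <- cur_stack$grid
  ext <- c(grid$xll, grid$yll,
           grid$xll + ncol(grid$values) * grid$cellsize,
           grid$yll + nrow(grid$values) * grid$cellsize)
  study_area <- cbind(lon = ext[c(1, 3, 3, 1)], lat = ext[c(2, 2, 4, 4)])

  sp_grid <- expand.grid(scenario = config$scenarios,
                         period = config$periods,
                         stringsAsFactors = FALSE)
  future_stacks <- lapply(seq_len(nrow(sp_grid)), function(i) {
    st <- world_predictors(world, sp_grid$scenario[i], sp_grid$period[i],
                           full = TRUE)
    predictor_stack(st$layers[predictors], sp_grid$scenario[i],
                    sp_grid$period[i])
  })

  say("stage: occurrences + sdm")
  species <- list()
  eval_tab <- NULL
  for (sp in pool) {
    sid <- sp$species_id
    res <- list(status = "ok")
    occ <- sample_occurrences(world, sp,
                              seed = stage_seed(seed, paste0("occ_", sid)),
                              dirty_fraction = config$dirty_fraction)
    occ <- clean_records(occ, study_area,
                         max_uncertainty_m = config$max_uncertainty_m,
                         min_year = config$min_year)
    occ <- thin_spatially(occ, config$min_distance_cells, grid$cellsize,
                          seed = stage_seed(seed, paste0("thin_", sid)))
    if (nrow(occ$records) < config$min_presences) {
      res$status <- "unmodellable"
      species[[sid]] <- res
      next
    }
    area <- accessible_area(occ, sp$flight_months,
                            outlier_pct = config$outlier_pct,
                            buffer_per_10months = config$buffer_per_10months)
    pcells <- cell_index(grid, occ$records$lon, occ$records$lat)
    pcells <- pcells[!is.na(pcells)]
    bg <- sample_background(area, length(pcells), grid,
                            presence_cells = pcells,
                            seed = stage_seed(seed, paste0("bg_", sid)),
                            ratio = config$background_ratio)
    dat <- make_sdm_data(stack_values(cur_stack, pcells),
                         stack_values(cur_stack, bg$cell), sid,
                         seed = stage_seed(seed, paste0("split_", sid)),
                         train_frac = config$train_frac)
    ms <- fit_learners(dat, seed = stage_seed(seed, paste0("fit_", sid)),
                       min_presences = config$min_presences)
    fin <- evaluate_and_finalize(dat, ms, auc_min = config$auc_min,
                                 boyce_min = config$boyce_min,
                                 seed = stage_seed(seed, paste0("refit_", sid)))
    eval_tab <- rbind(eval_tab,
                      cbind(species = sid, ms$evaluation,
                            best = ms$best_learner, flagged = fin$flagged,
                            threshold = fin$threshold))
    res$occ <- occ; res$area = area
    res$final <- fin
    res$flagged <- fin$flagged
    res$current <- project_sdm(fin, cur_stack, area)
    res$future <- lapply(future_stacks, function(st) project_sdm(fin, st, area))
    species[[sid]] <- res
    say(sprintf("  %s: best %s (AUC %.3f)%s", sid, ms$best_learner,
                max(ms$evaluation$auc), if (fin$flagged) " [flagged]" else ""))
  }
  modelled <- names(species)[vapply(species, function(s)
    s$status == "ok" && !isTRUE(s$flagged), TRUE)]
  if (length(modelled) < 2) stop("fewer than 2 modellable species")

  say("stage: diversity")
  trees <- list(PD = sim$tree,
                FD = build_dendrogram(gower_grouped(
                  traits[traits$species %in% modelled, ])))
  cur_comm <- stack_maps(lapply(stats::setNames(nm = modelled), function(s)
    species[[s]]$current$binary))
  facets <- list()
  for (i in seq_len(nrow(sp_grid))) {
    fut_comm <- stack_maps(
      lapply(stats::setNames(nm = modelled), function(s)
        species[[s]]$future[[i]]$binary),
      scenario = sp_grid$scenario[i], period = sp_grid$period[i])
    facets[[paste(sp_grid$scenario[i], sp_grid$period[i], sep = "_")]] <-
      facet_maps(cur_comm, fut_comm, trees)
  }

  say("stage: rangeshift")
  elev_grid <- full_stack$layers$elevation
  shifts <- NULL
  for (s in modelled) {
    for (i in seq_len(nrow(sp_grid))) {
      row <- tryCatch(
        range_metrics(species[[s]]$current$binary,
                      species[[s]]$future[[i]]$binary, elev_grid),
        error = function(e) NULL)
      if (is.null(row)) next
      shifts <- rbind(shifts, cbind(species = s,
                                    scenario = sp_grid$scenario[i],
                                    period = sp_grid$period[i], row))
    }
  }
  shift_summary <- summarise_shifts(shifts)

  say("stage: comparative")
  comparative <- run_comparative_suite(
    shifts, traits, sim$tree,
    subsets = config$subsets,
    n_permutations = config$n_permutations,
    seed = stage_seed(seed, "comparative"))

  result <- list(world = world, pool = pool, traits = traits, trees = trees,
                 filter = flt, species = species, modelled = modelled,
                 evaluation = eval_tab, facets = facets, shifts = shifts,
                 shift_summary = shift_summary, comparative = comparative,
                 config = config,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, "secs")))
  if (!is.null(out_dir)) result$manifest <- write_artefacts(result, out_dir)
  invisible(result)
}

write_artefacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(result$evaluation, p("evaluation.csv"), row.names = FALSE)
  utils::write.csv(result$shifts, p("shift_table.csv"), row.names = FALSE)
  utils::write.csv(result$shift_summary, p("shift_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$filter$log, p("predictor_filter_log.csv"),
                   row.names = FALSE)
  utils::write.csv(result$traits, p("traits.csv"), row.names = FALSE)
  if (!is.null(result$comparative$signal))
    utils::write.csv(result$comparative$signal, p("signal.csv"),
                     row.names = FALSE)
  if (!is.null(result$comparative$pgls))
    utils::write.csv(result$comparative$pgls, p("pgls.csv"),
                     row.names = FALSE)
  ape::write.tree(result$trees$PD, p("phylogeny.nwk"))
  ape::write.tree(result$trees$FD, p("functional_dendrogram.nwk"))
  for (nm in names(result$facets)) {
    fc <- result$facets[[nm]]
    for (facet in intersect(names(fc), c("TD", "FD", "PD")))
      for (layer in names(fc[[facet]]))
        write_ascii_grid(fc[[facet]][[layer]],
                         p(sprintf("%s_%s_%s.asc", layer, facet, nm)))
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("facetshift")),
    seed = result$config$seed,
    n_species = result$config$n_species,
    n_modelled = length(result$modelled),
    species_status = lapply(result$species, function(s)
      if (s$status != "ok") s$status
      else if (isTRUE(s$flagged)) "flagged" else "modelled"),
    record_counts = lapply(result$species, function(s)
      if (is.null(s$occ)) NA else nrow(s$occ$records)),
    elapsed_s = result$elapsed_s,
    files = lapply(stats::setNames(nm = files), function(f)
      unname(tools::md5sum(p(f)))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}

#' Summarise a completed artefact directory
#'
#' Reads the artefacts written by [run_all()] and emits a plain-text digest:
#' the per-scenario shift summary, the PGLS coefficient table and per-facet
#' alpha/beta summary statistics. Missing artefacts are listed instead of
#' silently skipped.
#'
#' @param out_dir artefact directory of a completed run.
#' @return list with `digest` (character lines), `shift_summary`, `pgls`,
#'   `facet_summary`; the digest is also printed.
#' @export
report <- function(out_dir) {
  need <- c("shift_summary.csv", "evaluation.csv", "manifest.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("incomplete run; missing artefacts: ",
         paste(missing, collapse = ", "))
  ss <- utils::read.csv(file.path(out_dir, "shift_summary.csv"))
  pg <- if (file.exists(file.path(out_dir, "pgls.csv")))
    utils::read.csv(file.path(out_dir, "pgls.csv")) else NULL
  asc <- list.files(out_dir, pattern = "^(alpha|beta).*\\.asc$")
  facet_summary <- do.call(rbind, lapply(asc, function(f) {
    g <- read_ascii_grid(file.path(out_dir, f))
    data.frame(layer = sub("\\.asc$", "", f),
               mean = mean(g$values, na.rm = TRUE),
               max = max(g$values, na.rm = TRUE))
  }))
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  digest <- c(
    sprintf("facetshift run digest (seed %s): %s of %s species modelled",
            man$seed, man$n_modelled, man$n_species),
    "", "Range-shift summary (per scenario x period):",
    utils::capture.output(print(ss, row.names = FALSE, digits = 3)),
    "", if (!is.null(pg)) c("PGLS coefficients:",
                            utils::capture.output(
                              print(pg, row.names = FALSE, digits = 3)))
    else "PGLS: skipped (<4 species)",
    "", "Diversity layers (mean / max per map):",
    utils::capture.output(print(facet_summary, row.names = FALSE,
                                digits = 3)))
  cat(digest, sep = "\n")
  invisible(list(digest = digest, shift_summary = ss, pgls = pg,
                 facet_summary = facet_summary))
}
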