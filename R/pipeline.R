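#' Pipeline configuration
#'
#' Bundles stage configurations, a global seed, stage toggles, and the
#' output directory for [run_pipeline()]. The classifier stages are off
#' by default: users with a labeled patch table (from annotation or a
#' previously trained model) can run the spatial and survival science
#' directly.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed propagated to every stochastic stage.
#' @param n_subjects Cohort size for the simulate stage.
#' @param grid_cfg,surv_cfg Stage configs; the global seed overrides
#'   their seeds.
#' @param driving_indicator Indicator driving simulated survival.
#' @param radius,min_neighborhood_size Nest-detection parameters.
#' @param minprop Cutpoint minimum group proportion.
#' @param stages Character subset of `c("simulate", "spatial",
#'   "survive")` to run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("nestmargin_run_"),
                            seed = 1L, n_subjects = 20L,
                            grid_cfg = grid_config(),
                            surv_cfg = survival_sim_config(),
                            driving_indicator = "Lymph_inside",
                            radius = 2, min_neighborhood_size = 4,
                            minprop = 0.1,
                            stages = c("simulate", "spatial", "survive")) {
  stages <- intersect(stages, c("simulate", "spatial", "survive"))
  grid_cfg$seed <- as.integer(seed)
  surv_cfg$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 grid_cfg = grid_cfg, surv_cfg = surv_cfg,
                 driving_indicator = driving_indicator,
                 radius = radius,
                 min_neighborhood_size = min_neighborhood_size,
                 minprop = minprop, stages = stages),
            class = "pipeline_config")
}

#' Run the simulate -> spatial -> survive pipeline
#'
#' Each stage writes versioned CSV outputs under `config$out_dir` and the
#' run ends with a JSON manifest recording parameters, seeds, and file
#' checksums; a rerun with the same config is bit-identical. A failing
#' stage aborts with the stage named. Key fixed parameters (128 um
#' patches, 20-cell labeling rule, clustering radius 2 with
#' min_neighborhood_size 4, 8:2 training split) are logged in the
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      patch_um = 128, min_cells = 20,
      radius = config$radius,
      min_neighborhood_size = config$min_neighborhood_size,
      train_split = 0.8, minprop = config$minprop,
      n_subjects = config$n_subjects,
      driving_indicator = config$driving_indicator),
    outputs = list())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- NULL
  if ("simulate" %in% config$stages) {
    say("stage simulate: generating %d subjects", config$n_subjects)
    run_stage("simulate", function() {
      cohort <<- generate_cohort(
        config$n_subjects, config$grid_cfg, config$surv_cfg,
        driving_indicator = config$driving_indicator,
        radius = config$radius,
        min_neighborhood_size = config$min_neighborhood_size)
      write_patch_table(lapply(cohort$subjects, `[[`, "grid"),
                        file.path(config$out_dir, "patches.csv"))
      utils::write.csv(cohort_survival(cohort),
                       file.path(config$out_dir, "survival.csv"),
                       row.names = FALSE)
    })
    manifest$outputs$patches <- "patches.csv"
    manifest$outputs$survival <- "survival.csv"
  }
  if ("spatial" %in% config$stages) {
    say("stage spatial: computing indicators")
    run_stage("spatial", function() {
      grids <- if (!is.null(cohort)) {
        lapply(cohort$subjects, `[[`, "grid")
      } else {
        read_patch_table(file.path(config$out_dir, "patches.csv"))
      }
      ind <- do.call(rbind, lapply(grids, function(g) {
        sp <- analyze_spatial(
          g, radius = config$radius,
          min_neighborhood_size = config$min_neighborhood_size)
        cbind(subject_id = g$subject_id, as.data.frame(sp$indicators))
      }))
      utils::write.csv(ind,
                       file.path(config$out_dir, "indicators.csv"),
                       row.names = FALSE)
    })
    manifest$outputs$indicators <- "indicators.csv"
  }
  if ("survive" %in% config$stages) {
    say("stage survive: cutpoint + Cox per indicator")
    run_stage("survive", function() {
      ind <- utils::read.csv(file.path(config$out_dir, "indicators.csv"))
      surv <- utils::read.csv(file.path(config$out_dir, "survival.csv"))
      d <- merge(ind, surv, by = "subject_id")
      rows <- lapply(indicator_names(), function(nm) {
        vals <- d[[nm]]
        ok <- !is.na(vals)
        if (sum(ok) < 4L || length(unique(vals[ok])) < 2L ||
            sum(d$event[ok]) < 1L) {
          return(NULL)
        }
        cp <- tryCatch(
          optimal_cutpoint(d$time[ok], d$event[ok], vals[ok],
                           minprop = config$minprop),
          error = function(e) NULL)
        cx <- tryCatch({
          dd <- d[ok, ]
          dd$z <- vals[ok] / 100
          cox_fit(dd, "z")
        }, error = function(e) NULL)
        data.frame(
          indicator = nm, n = sum(ok),
          cutpoint = if (is.null(cp)) NA else cp$cutpoint,
          logrank_p = if (is.null(cp)) NA else cp$p_value,
          hr = if (is.null(cx)) NA else cx$table$hr[1],
          hr_ci_low = if (is.null(cx)) NA else cx$table$ci_low[1],
          hr_ci_high = if (is.null(cx)) NA else cx$table$ci_high[1],
          cox_p = if (is.null(cx)) NA else cx$table$p[1])
      })
      res <- do.call(rbind, rows)
      utils::write.csv(res,
                       file.path(config$out_dir, "survival_results.csv"),
                       row.names = FALSE)
    })
    manifest$outputs$survival_results <- "survival_results.csv"
  }
  files <- unlist(manifest$outputs, use.names = FALSE)
  if (length(files)) {
    sums <- tools::md5sum(file.path(config$out_dir, files))
    manifest$checksums <- as.list(stats::setNames(unname(sums), files))
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: %s", config$out_dir)
  invisible(manifest)
}
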