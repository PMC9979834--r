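# Report-bundle assembly: one entry point that runs the stages (simulate or
# read; validate; environmental intervals; compositional MANOVA with
# contrasts, ternary coordinates and optional LOCO table; dynamic-model fits
# with PSIS-LOO comparison, typical-panel trajectories, effect fields and
# removal diagnostics) and writes plain CSV outputs plus a MANIFEST of
# completed stages. Every reported number is computed by a stage and written
# to its file; nothing is recomputed at render time.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed root seed; all stage seeds derive from it.
#' @param simulate logical: generate a synthetic experiment (default) instead
#'   of reading CSV inputs.
#' @param preset scenario preset name for simulation.
#' @param inputs list(counts, meta, env) of CSV paths when `simulate = FALSE`.
#' @param manova_variant variant used for reported summaries.
#' @param dynamics_variants character vector of dynamic model variants to fit.
#' @param run_loco run leave-one-cluster-out comparison of MANOVA variants
#'   (the slowest stage; off by default).
#' @param manova_control,dynamics_control,loco_control named lists of sampler
#'   settings forwarded to [fit_manova()], [fit_dynamics()], [loco_cv()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = "polypcomp-run", seed = 1, simulate = TRUE,
                       preset = "default", inputs = NULL,
                       manova_variant = "no_interaction",
                       dynamics_variants = c("basic", "overgrowth"),
                       run_loco = FALSE,
                       manova_control = list(), dynamics_control = list(),
                       loco_control = list()) {
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 preset = preset, inputs = inputs,
                 manova_variant = manova_variant,
                 dynamics_variants = dynamics_variants, run_loco = run_loco,
                 manova_control = manova_control,
                 dynamics_control = dynamics_control,
                 loco_control = loco_control),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with any subset of the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes all stages under the configuration and writes the report bundle:
#' `env_intervals.csv`, `manova/summary.csv`, `manova/contrasts.csv`,
#' `manova/ternary.csv` (+ `manova/loco.csv` when requested),
#' `dynamics/loo_table.csv`, per-variant fit summaries, typical-panel
#' trajectories, effect fields, `dynamics/removal_diagnostics.csv`, a
#' `MANIFEST` of completed stages and a `log.txt` with versions, seeds and
#' sampler diagnostics. On a stage failure the partial outputs and MANIFEST
#' are preserved and the error is rethrown.
#'
#' @param config a `run_config` (or path to a JSON config).
#' @return invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "manova"), showWarnings = FALSE)
  dir.create(file.path(out, "dynamics"), showWarnings = FALSE)
  manifest <- character(0)
  logf <- file.path(out, "log.txt")
  note <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  done <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out, "MANIFEST"))
  }
  cat("polypcomp pipeline log\n", file = logf)
  note("package version: ", as.character(utils::packageVersion("polypcomp")))
  note("R version: ", R.version.string)
  note("root seed: ", config$seed)
  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 2, 8)
  results <- list()

  run_stage <- function(stage, expr) {
    note("stage ", stage, " started")
    val <- tryCatch(expr, error = function(e) {
      note("stage ", stage, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note("stage ", stage, " completed")
    done(stage)
    val
  }

  # --- input ---
  tbl <- run_stage("input", {
    if (config$simulate) {
      sim <- generate_dynamics_experiment(scenario_preset(config$preset),
                                          design_spec(),
                                          seed = stage_seeds[1])
      write_experiment(sim$table, file.path(out, "simulated_data"))
      sim$table
    } else {
      ip <- config$inputs
      if (is.null(ip) || !all(file.exists(c(ip$counts, ip$meta, ip$env))))
        stop("missing input file(s): ",
             paste(setdiff(unlist(ip), unlist(ip)[file.exists(unlist(ip))]),
                   collapse = ", "))
      read_experiment(ip$counts, ip$meta, ip$env, ip$applications)
    }
  })
  results$table <- tbl

  run_stage("validate", validate_experiment(tbl))

  results$env <- run_stage("env_intervals", {
    ei <- env_intervals(tbl)
    write.csv(ei, file.path(out, "env_intervals.csv"), row.names = FALSE)
    ei
  })

  results$manova <- run_stage("manova", {
    md <- manova_subset(tbl)
    ctrl <- utils::modifyList(
      list(variant = config$manova_variant, seed = stage_seeds[2]),
      config$manova_control)
    fit <- do.call(fit_manova, c(list(data = md), ctrl))
    sm <- summary(fit)
    write.csv(sm$table, file.path(out, "manova", "summary.csv"),
              row.names = FALSE)
    note("manova max R-hat ", sprintf("%.3f", max(fit$diagnostics$rhat)),
         ", min ESS ", sprintf("%.0f", min(fit$diagnostics$ess)))
    depths <- fit$idx$depths
    ctr <- do.call(rbind, lapply(depths, function(dp) {
      a <- logit_contrast(fit, "aurita", c("O", "C"), dp)
      b <- logit_contrast(fit, "competitors", c("A", "C"), dp)
      data.frame(depth = dp, part = c("aurita", "competitors"),
                 contrast = c("O-C", "A-C"), mean = c(a$mean, b$mean),
                 lower = c(a$lower, b$lower), upper = c(a$upper, b$upper))
    }))
    write.csv(ctr, file.path(out, "manova", "contrasts.csv"),
              row.names = FALSE)
    tern <- do.call(rbind, lapply(depths, function(dp)
      do.call(rbind, lapply(c("C", "A", "O"), function(tr) {
        et <- effect_ternaries(fit, dp, tr)
        amal <- colMeans(et$amalgam); sub <- colMeans(et$subcomp)
        data.frame(depth = dp, treatment = tr,
                   projection = c("amalgam", "subcomposition"),
                   p1 = c(amal[1], sub[1]), p2 = c(amal[2], sub[2]),
                   p3 = c(amal[3], sub[3]))
      }))))
    write.csv(tern, file.path(out, "manova", "ternary.csv"),
              row.names = FALSE)
    list(fit = fit, contrasts = ctr)
  })

  if (config$run_loco) {
    results$loco <- run_stage("loco", {
      md <- manova_subset(tbl)
      ctrl <- utils::modifyList(list(seed = stage_seeds[3]),
                                config$loco_control)
      lc <- do.call(loco_cv, c(list(data = md), ctrl))
      write.csv(as.data.frame(lc), file.path(out, "manova", "loco.csv"),
                row.names = FALSE)
      lc
    })
  }

  results$dynamics <- run_stage("dynamics", {
    dd <- dynamics_dataset(tbl)
    fits <- list()
    for (v in config$dynamics_variants) {
      ctrl <- utils::modifyList(
        list(variant = v, seed = stage_seeds[4] + match(v, .dyn_variants)),
        config$dynamics_control)
      fit <- do.call(fit_dynamics, c(list(data = dd), ctrl))
      fits[[v]] <- fit
      write.csv(summary(fit)$table,
                file.path(out, "dynamics", paste0("fit_", v, ".csv")),
                row.names = FALSE)
      note("dynamics ", v, " acceptance ", sprintf("%.2f", fit$acceptance),
           ", max R-hat ", sprintf("%.3f", max(fit$diagnostics$rhat)))
      tp <- typical_panel_trajectories(fit, ndraws = 100,
                                       seed = stage_seeds[5])
      write.csv(tp, file.path(out, "dynamics",
                              paste0("trajectories_", v, ".csv")),
                row.names = FALSE)
      for (dp in fit$setup$depths) {
        pl <- .params_from_draw(fit, which.max(fit$lp))
        fld <- polyp_effect_field(pl[[match(dp, fit$setup$depths)]])
        write.csv(fld, file.path(out, "dynamics",
                                 sprintf("effect_field_%s_%sm.csv", v, dp)),
                  row.names = FALSE)
      }
    }
    rd <- removal_diagnostics(dd, fits[[length(fits)]])
    write.csv(rd$points,
              file.path(out, "dynamics", "removal_diagnostics.csv"),
              row.names = FALSE)
    write.csv(rd$slopes,
              file.path(out, "dynamics", "removal_slopes.csv"),
              row.names = FALSE)
    if (length(fits) > 1) {
      cmp <- psis_loo_compare(fits)
      write.csv(as.data.frame(cmp),
                file.path(out, "dynamics", "loo_table.csv"),
                row.names = FALSE)
      if (any(cmp$khat_max > 0.7, na.rm = TRUE))
        note("warning: Pareto k > 0.7 present in LOO table")
      list(fits = fits, comparison = cmp)
    } else list(fits = fits)
  })

  done("report")
  note("pipeline completed")
  invisible(c(results, list(out_dir = out, manifest = manifest)))
}
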