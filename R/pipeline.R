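#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the simulation scenario, the
#' estimation scheme, the metric start ages, the standardization toggle,
#' and the output directory. Validated eagerly so misconfiguration fails
#' before any stage runs.
#'
#' @param scenario a [scenario_names()] label.
#' @param n_persons simulated cohort size.
#' @param seed integer seed; mandatory (the run must be reproducible from
#'   config + seed alone).
#' @param scheme stratification scheme for estimation, see
#'   [fit_stratified()].
#' @param start_age,cond_age metric start ages in months.
#' @param standardize if `TRUE`, also compute education-standardized
#'   metrics (requires `scheme = "by_gender_education"`).
#' @param out_dir output directory; created if missing.
#' @param education_probs optional per-period education entry distribution
#'   (5 x 3 matrix) passed to [scenario_config()]; use to induce an
#'   education drift.
#' @param write_panel write the person-period CSV (can be large).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "baseline", n_persons = 20000,
                            seed = NULL,
                            scheme = c("total", "by_gender",
                                       "by_gender_education"),
                            start_age = 480, cond_age = 780,
                            standardize = FALSE,
                            out_dir = tempfile("msexpect-run-"),
                            education_probs = NULL,
                            write_panel = TRUE,
                            log_level = c("info", "quiet")) {
  scheme <- match.arg(scheme)
  log_level <- match.arg(log_level)
  if (!scenario %in% scenario_names()) {
    stop("invalid config field 'scenario': unknown scenario ", scenario)
  }
  if (is.null(seed)) stop("invalid config field 'seed': a seed is mandatory")
  if (standardize && scheme != "by_gender_education") {
    stop("invalid config field 'standardize': requires scheme by_gender_education")
  }
  grid <- age_grid()
  if (!start_age %in% grid$points || start_age >= grid$end) {
    stop("invalid config field 'start_age': must be an on-grid age below ",
         grid$end)
  }
  if (!cond_age %in% grid$points || cond_age >= grid$end) {
    stop("invalid config field 'cond_age': must be an on-grid age below ",
         grid$end)
  }
  structure(
    list(scenario = scenario, n_persons = as.integer(n_persons),
         seed = as.integer(seed), scheme = scheme,
         start_age = start_age, cond_age = cond_age,
         standardize = standardize, out_dir = out_dir,
         education_probs = education_probs, write_panel = write_panel,
         log_level = log_level),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching the [pipeline_config()]
#'   arguments; `education_probs` may be given as a list of five
#'   length-3 rows.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$education_probs)) {
    obj$education_probs <- do.call(rbind, lapply(obj$education_probs, unlist))
  }
  do.call(pipeline_config, obj)
}

# stable FNV-1a hash of the deparsed config, for the run log
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

pipe_stage <- function(stage, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-12s done in %.1fs", stage,
              proc.time()[["elapsed"]] - t0))
  res
}

scheme_contexts <- function(scheme) {
  switch(scheme,
    total = list(total = list()),
    by_gender = {
      s <- lapply(gender_levels(), function(g) list(gender = g))
      names(s) <- gender_levels()
      s
    },
    by_gender_education = {
      s <- list()
      for (g in gender_levels()) for (e in education_levels()) {
        s[[paste(g, e, sep = "_")]] <- list(gender = g, education = e)
      }
      s
    }
  )
}

#' Run the full multistate pipeline
#'
#' Executes the stages simulate -> fit -> predict -> metrics
#' [-> standardize] -> report from a single [pipeline_config()]: simulates
#' the scenario's register, fits the stratified transition models, predicts
#' per-period transition probabilities for every stratum, computes the
#' metrics table, optionally the education-standardized metrics, and the
#' disparity/decomposition report. All tabular outputs are written as
#' headered CSV into the config's output directory together with a config
#' snapshot and a run log (config hash, seed, stage timings). Everything is
#' re-creatable from config + seed alone.
#'
#' @param config a `pipeline_config`.
#' @param last_stage stop after this stage (`"simulate"`, `"fit"`,
#'   `"metrics"`, `"standardize"`, `"report"`); default runs everything.
#' @return Invisibly, a list with the run artifacts (panel or counts,
#'   models, probability contexts, metrics tables, reports, file paths).
#' @export
run_pipeline <- function(config, last_stage = c("report", "simulate", "fit",
                                                "metrics", "standardize")) {
  stopifnot(inherits(config, "pipeline_config"))
  last_stage <- match.arg(last_stage)
  stage_rank <- c(simulate = 1, fit = 2, metrics = 3, standardize = 4,
                  report = 5)
  want <- stage_rank[[last_stage]]
  if (last_stage == "standardize" && !config$standardize) {
    stop("invalid config field 'standardize': must be TRUE to run that stage")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  log(sprintf("run start: scenario=%s n=%d seed=%d scheme=%s hash=%s",
              config$scenario, config$n_persons, config$seed, config$scheme,
              config_hash(config)))
  yaml::write_yaml(
    lapply(unclass(config), function(v) if (is.matrix(v)) {
      lapply(seq_len(nrow(v)), function(i) as.list(v[i, ]))
    } else v),
    file.path(config$out_dir, "config.yaml")
  )
  arts <- list(files = character(0))

  # simulate
  model <- scenario_model(config$scenario)
  cfg_args <- list(n_persons = config$n_persons, seed = config$seed)
  if (!is.null(config$education_probs)) {
    cfg_args$education_probs <- config$education_probs
  }
  sc <- do.call(scenario_config, cfg_args)
  counts <- pipe_stage("simulate", log, {
    cnt <- simulate_individuals(model, sc, format = "counts")
    if (config$write_panel) {
      panel <- simulate_individuals(model, sc, format = "panel")
      pp <- file.path(config$out_dir, "person_periods.csv")
      write_panel_csv(panel, pp)
      arts$files <- c(arts$files, pp)
      arts$panel <- panel
    }
    cnt
  })
  arts$counts <- counts
  if (want < 2) {
    writeLines(log_lines, log_path)
    return(invisible(arts))
  }

  # fit
  models <- pipe_stage("estimation", log, {
    if (nrow(counts) == 0L) stop("no person-period observations to fit")
    fit_stratified(counts, scheme = config$scheme)
  })
  arts$models <- models
  for (nm in names(models)) {
    mp <- file.path(config$out_dir, paste0("model_", nm, ".yaml"))
    write_transition_model(models[[nm]], mp)
    arts$files <- c(arts$files, mp)
  }
  if (want < 3) {
    writeLines(log_lines, log_path)
    return(invisible(arts))
  }

  # predict + metrics
  res <- pipe_stage("metrics", log, {
    ctx <- list()
    for (nm in names(models)) {
      for (per in models[[nm]]$periods) {
        ctx[[paste(per, nm, sep = "|")]] <-
          predict_transition_probs(models[[nm]], period = per, subgroup = nm)
      }
    }
    tab <- build_metrics_table(ctx, start_age = config$start_age,
                               cond_age = config$cond_age)
    list(ctx = ctx, tab = tab)
  })
  arts$probs <- res$ctx
  arts$metrics <- res$tab
  tp_path <- file.path(config$out_dir, "transition_probs.csv")
  write_transition_probs_csv(unname(res$ctx), tp_path)
  mt_path <- file.path(config$out_dir, "metrics.csv")
  write_metrics_csv(res$tab, mt_path)
  arts$files <- c(arts$files, tp_path, mt_path)
  if (want < 4) {
    writeLines(log_lines, log_path)
    return(invisible(arts))
  }

  # standardize
  if (config$standardize) {
    std <- pipe_stage("standardize", log, {
      w <- pooled_education_weights(counts)
      ctx <- list()
      for (g in gender_levels()) {
        for (per in period_labels()) {
          by_edu <- lapply(stats::setNames(education_levels(),
                                           education_levels()), function(e) {
            m <- models[[paste(g, e, sep = "_")]]
            if (!per %in% m$periods) stop("period ", per,
                                          " missing in stratum ", g, "_", e)
            predict_transition_probs(m, period = per,
                                     subgroup = paste(g, e, sep = "_"))
          })
          ctx[[paste(per, g, sep = "|")]] <-
            standardize_transition_probs(by_edu, w)
        }
      }
      tab <- build_metrics_table(ctx, start_age = config$start_age,
                                 cond_age = config$cond_age)
      list(weights = w, tab = tab)
    })
    arts$education_weights <- std$weights
    arts$metrics_standardized <- std$tab
    sp <- file.path(config$out_dir, "metrics_standardized.csv")
    write_metrics_csv(std$tab, sp)
    arts$files <- c(arts$files, sp)
  }
  if (want < 5) {
    writeLines(log_lines, log_path)
    return(invisible(arts))
  }

  # report
  rep <- pipe_stage("report", log, {
    tab <- arts$metrics
    pers <- intersect(period_labels(), unique(as.character(tab$period)))
    first <- pers[1L]; last <- pers[length(pers)]
    gaps <- list()
    if (config$scheme %in% c("by_gender")) {
      for (mtr in c("tle", "e_free", "e_cvd")) {
        gaps[[mtr]] <- disparity_report(tab, mtr, "women", "men", pers)
      }
    }
    dec <- lapply(stats::setNames(unique(as.character(tab$subgroup)),
                                  unique(as.character(tab$subgroup))),
                  function(g) decompose_tle_gain(tab, g, first, last))
    decdf <- data.frame(
      subgroup = names(dec),
      d_tle = vapply(dec, `[[`, numeric(1), "d_tle"),
      d_free = vapply(dec, `[[`, numeric(1), "d_free"),
      d_cvd = vapply(dec, `[[`, numeric(1), "d_cvd"),
      pct_free_of_gain = vapply(dec, `[[`, numeric(1), "pct_free_of_gain")
    )
    list(gaps = gaps, decomposition = decdf)
  })
  arts$report <- rep
  dp <- file.path(config$out_dir, "tle_gain_decomposition.csv")
  utils::write.csv(rep$decomposition, dp, row.names = FALSE, quote = FALSE)
  arts$files <- c(arts$files, dp)
  if (length(rep$gaps) > 0L) {
    gp <- file.path(config$out_dir, "disparity_gaps.csv")
    gdf <- do.call(rbind, lapply(rep$gaps, function(g) {
      data.frame(metric = g$metric, period = names(g$gaps), gap = g$gaps,
                 row.names = NULL)
    }))
    utils::write.csv(gdf, gp, row.names = FALSE, quote = FALSE)
    arts$files <- c(arts$files, gp)
  }
  log("run complete")
  writeLines(log_lines, log_path)
  arts$log <- log_path
  invisible(arts)
}
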