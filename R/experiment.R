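.cohort_keys <- c("n_wt", "n_ko", "between_animal_cv", "noise_sd_um",
                  "sample_rate_hz", "duration_s")
.fitting_keys <- c("free", "max_iterations", "dt")
.config_keys <- c("seed", "output_dir", "protocol", "parameters", "cohort",
                  "fitting")

#' Default end-to-end experiment configuration
#'
#' The canonical WT-vs-KO contrast experiment: published genotype parameter
#' medians, the standard single-burst protocol, cohorts of 4 WT and 5 KO
#' animals with 10% between-animal CV and 0.05 uM measurement noise, 10 Hz
#' acquisition over 12 s, and a two-parameter (`Vm`, `DAP`) fit of each
#' genotype's averaged trace.
#'
#' @param seed global seed; cohort seeds are derived from it with [mix_seed()]
#' @param output_dir directory for the run's output files, or `NULL` to keep
#'   everything in memory
#' @return a nested list accepted by [run_experiment()]
#' @export
default_experiment_config <- function(seed = 1L, output_dir = NULL) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    protocol = list(n_pulses = 30L, frequency_hz = 50, current_ma = 0.4,
                    onset_s = 2),
    parameters = list(
      wt = list(Vm = 7.4, DAP = 0.67),
      ko = list(Vm = 2.0, DAP = 0.31)),
    cohort = list(n_wt = 4L, n_ko = 5L, between_animal_cv = 0.1,
                  noise_sd_um = 0.05, sample_rate_hz = 10, duration_s = 12),
    fitting = list(free = c("Vm", "DAP"), max_iterations = 200, dt = 1e-3)
  )
}

validate_experiment_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("config: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("protocol", "parameters", "cohort"))
    if (is.null(cfg[[blk]])) stop("config: missing block '", blk, "'")
  if (is.null(cfg$seed)) stop("config: missing 'seed'")
  unknown <- setdiff(names(cfg$parameters), c("wt", "ko"))
  if (length(unknown))
    stop("config: unknown parameters block(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(cfg$cohort), .cohort_keys)
  if (length(unknown))
    stop("config: unknown cohort key(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(cfg$fitting), .fitting_keys)
  if (length(unknown))
    stop("config: unknown fitting key(s): ", paste(unknown, collapse = ", "))
  invisible(cfg)
}

#' Read / write an experiment configuration
#'
#' YAML serialisation of the [run_experiment()] configuration. The
#' parse-serialise-parse round trip is lossless; unknown keys are rejected.
#'
#' @param path YAML file
#' @return `read_experiment_config()` returns the validated config list
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
  cfg
}

#' @rdname read_experiment_config
#' @param cfg a configuration list
#' @export
write_experiment_config <- function(cfg, path) {
  validate_experiment_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the end-to-end WT-vs-KO experiment
#'
#' Generates both genotype cohorts, averages the recordings per genotype,
#' fits the kinetic model to each averaged trace, and reports the genotype
#' comparison (percent reductions in `Vm` and `DAP`), the per-animal trace
#' metrics, and a Welch test on the per-animal clearance half-times. Cohort
#' seeds are `mix_seed(seed, 1)` (WT) and `mix_seed(seed, 2)` (KO), so a rerun
#' with the same configuration is bitwise identical. When `output_dir` is set,
#' every artefact (recordings, manifest, averages, fits, comparison, metrics,
#' Welch test, config echo and a structured log) is written there;
#' timestamps are confined to the log.
#'
#' @param config a configuration list as from [default_experiment_config()]
#'   or [read_experiment_config()], or a path to a YAML config file
#' @return a list with `comparison`, `fit_wt`, `fit_ko`, `metrics`
#'   (per-animal data.frame), `welch` (test on clearance half-times),
#'   `averages` and `cohorts`
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  validate_experiment_config(config)

  out_dir <- config$output_dir
  log_lines <- character(0)
  say <- function(stage, msg) {
    log_lines <<- c(log_lines,
                    sprintf("%s | %s | %s",
                            format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      say(stage, paste("ERROR:", conditionMessage(e)))
      stop("run_experiment [", stage, "]: ", conditionMessage(e), call. = FALSE)
    })
  }

  protocol <- run_stage("config", protocol_from_list(config$protocol))
  p_wt <- run_stage("config", params_from_list(config$parameters$wt))
  p_ko <- run_stage("config", params_from_list(config$parameters$ko))
  co <- config$cohort
  fitcfg <- config$fitting %||% list()
  free <- fitcfg$free %||% c("Vm", "DAP")
  dt <- fitcfg$dt %||% 1e-3
  maxit <- fitcfg$max_iterations %||% 200
  say("config", sprintf("seed=%d protocol=%dx%gHz@%gmA onset=%gs",
                        config$seed, protocol$n_pulses, protocol$frequency_hz,
                        protocol$current_ma, protocol$onset_s))
  say("config", sprintf(
    "cohorts: n_wt=%d n_ko=%d cv=%g noise_sd=%g uM rate=%g Hz duration=%g s",
    co$n_wt, co$n_ko, co$between_animal_cv, co$noise_sd_um, co$sample_rate_hz,
    co$duration_s))
  say("config", sprintf("integrator: fixed-step RK4, dt=%g s", dt))

  specs <- list(
    WT = cohort_spec("WT", p_wt, co$between_animal_cv, co$n_wt,
                     co$noise_sd_um, co$sample_rate_hz,
                     seed = mix_seed(config$seed, 1)),
    KO = cohort_spec("KO", p_ko, co$between_animal_cv, co$n_ko,
                     co$noise_sd_um, co$sample_rate_hz,
                     seed = mix_seed(config$seed, 2)))
  cohorts <- lapply(specs, function(s) {
    say("generate", sprintf("genotype=%s n=%d cohort_seed=%d",
                            s$genotype, s$n_animals, s$seed))
    run_stage("generate",
              generate_cohort(s, protocol, duration = co$duration_s, dt = dt))
  })

  averages <- lapply(cohorts, function(x) run_stage("average",
                                                    average_recordings(x)))
  fits <- lapply(names(averages), function(g) {
    params <- if (g == "WT") p_wt else p_ko
    params$free <- free
    f <- run_stage("fit", fit_trace(averages[[g]], protocol, params,
                                    free = free, dt = dt,
                                    max_iterations = maxit))
    say("fit", sprintf("genotype=%s converged=%s r2=%.5f rss=%.5g evals=%d (%s)",
                       g, f$converged, f$r2, f$rss, f$n_evaluations,
                       paste(sprintf("%s=%.6g", f$free_names, f$estimates),
                             collapse = " ")))
    f
  })
  names(fits) <- names(averages)
  comparison <- run_stage("compare", compare_genotypes(fits$WT, fits$KO))
  say("compare", sprintf("pct_reduction_vm=%.3f pct_reduction_dap=%.3f",
                         comparison$pct_reduction_vm,
                         comparison$pct_reduction_dap))

  metrics <- run_stage("metrics", do.call(rbind, unlist(lapply(
    names(cohorts), function(g) {
      lapply(seq_along(cohorts[[g]]), function(i) {
        m <- trace_metrics(cohorts[[g]][[i]], protocol)
        cbind(data.frame(genotype = g, animal = i,
                         seed = cohorts[[g]][[i]]$metadata$seed), m)
      })
    }), recursive = FALSE)))

  th_wt <- metrics$t_half_s[metrics$genotype == "WT" & !is.na(metrics$t_half_s)]
  th_ko <- metrics$t_half_s[metrics$genotype == "KO" & !is.na(metrics$t_half_s)]
  welch <- run_stage("welch", {
    if (sd(th_wt) == 0 && sd(th_ko) == 0 &&
        isTRUE(all.equal(mean(th_wt), mean(th_ko)))) {
      # degenerate noise-free null experiment: identical half-times everywhere
      list(t = 0, df = NA_real_, p = 1, mean_a = mean(th_wt),
           mean_b = mean(th_ko), degenerate = TRUE)
    } else {
      welch_t(th_wt, th_ko)
    }
  })
  say("welch", sprintf("t=%.4g p=%.4g mean_t_half WT=%.4g KO=%.4g",
                       welch$t, welch$p, welch$mean_a, welch$mean_b))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    cfg_echo <- config
    cfg_echo$output_dir <- NULL
    yaml::write_yaml(cfg_echo, cfg_path)
    say("io", sprintf("config written, md5=%s", unname(tools::md5sum(cfg_path))))
    manifest <- list()
    for (g in names(cohorts)) {
      for (i in seq_along(cohorts[[g]])) {
        rec <- cohorts[[g]][[i]]
        write_recording(rec, file.path(out_dir,
                                       sprintf("%s_%02d.csv", tolower(g), i)))
        manifest[[length(manifest) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", tolower(g), i), genotype = g,
          seed = rec$metadata$seed,
          Vm = rec$metadata$params[["Vm"]], DAP = rec$metadata$params[["DAP"]])
      }
      write_recording(averages[[g]],
                      file.path(out_dir, sprintf("average_%s.csv", tolower(g))))
      writeLines(fit_result_json(fits[[g]]),
                 file.path(out_dir, sprintf("fit_%s.json", tolower(g))))
    }
    utils::write.csv(do.call(rbind, manifest),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(list(
      vm_wt = comparison$vm_wt, vm_ko = comparison$vm_ko,
      dap_wt = comparison$dap_wt, dap_ko = comparison$dap_ko,
      pct_reduction_vm = comparison$pct_reduction_vm,
      pct_reduction_dap = comparison$pct_reduction_dap),
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "comparison.json"))
    writeLines(jsonlite::toJSON(welch[c("t", "df", "p", "mean_a", "mean_b")],
                                auto_unbox = TRUE, digits = NA, pretty = TRUE,
                                na = "null"),
               file.path(out_dir, "welch.json"))
    say("io", paste("artefacts written to", out_dir))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  list(comparison = comparison, fit_wt = fits$WT, fit_ko = fits$KO,
       metrics = metrics, welch = welch, averages = averages,
       cohorts = cohorts, log = log_lines)
}

## JSON serialisation of a fit result (fitted params, fit quality, diagnostics)
fit_result_json <- function(fit) {
  jsonlite::toJSON(list(
    estimates = as.list(fit$estimates),
    fixed = stats::setNames(lapply(setdiff(.param_fields, fit$free_names),
                                   function(f) fit$params[[f]]),
                            setdiff(.param_fields, fit$free_names)),
    r2 = fit$r2, rss = fit$rss, n_evaluations = fit$n_evaluations,
    converged = fit$converged, free_names = fit$free_names),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
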