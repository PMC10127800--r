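prot <- stim_protocol(onset_s = 2)

test_that("recording CSV round-trips values and metadata exactly", {
  rec <- generate_recording(wt_params(), prot, noise_sd = 0.03,
                            sample_rate = 10, seed = 8, genotype = "WT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$time, rec$time, tolerance = 1e-12)
  expect_equal(back$da, rec$da, tolerance = 1e-12)
  expect_equal(back$metadata$genotype, "WT")
  expect_equal(back$metadata$sample_rate_hz, 10)
  expect_equal(back$metadata$seed, 8)
  expect_equal(back$metadata$params, rec$metadata$params)
})

test_that("malformed recording files fail with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fscv_recording v1", "time_s,da_um",
               "0,0.1", "0.2,0.2", "0.1,0.3"), path)
  expect_error(read_recording(path), "not strictly increasing at data row 3")
  writeLines(c("# fscv_recording v1", "time_s,da_um",
               "0,0.1", "0.1,NaN"), path)
  expect_error(read_recording(path), "non-finite value at data row 2")
  writeLines(c("# fscv_recording v1", "wrong,header", "0,0.1"), path)
  expect_error(read_recording(path), "malformed header")
  # missing metadata: loads with a warning and empty metadata
  writeLines(c("time_s,da_um", "0,0.1", "0.1,0.2"), path)
  expect_warning(rec <- read_recording(path), "empty metadata")
  expect_length(rec$metadata, 0)
})

test_that("model config files are parsed and unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("protocol:",
               "  n_pulses: 30", "  frequency_hz: 50",
               "  current_ma: 0.4", "  onset_s: 2",
               "parameters:",
               "  Vm: 7.4", "  DAP: 0.67",
               "  free: [Vm, DAP]"), path)
  mc <- read_model_config(path)
  expect_equal(burst_duration(mc$protocol), 0.6)
  expect_equal(mc$parameters$Vm, 7.4)
  expect_equal(mc$parameters$free, c("Vm", "DAP"))
  writeLines(c("protocol:",
               "  n_pulses: 30", "  frequency_hz: 50",
               "  current_ma: 0.4", "  onset_s: 2",
               "  voltage_mv: 300",
               "parameters:",
               "  Vm: 7.4", "  DAP: 0.67"), path)
  expect_error(read_model_config(path), "unknown protocol key.*voltage_mv")
})

test_that("experiment config round-trips losslessly and is validated", {
  cfg <- default_experiment_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_null(back$output_dir)
  keep <- setdiff(names(cfg), "output_dir")
  expect_equal(back[keep], cfg[keep])
  # serialise -> parse -> serialise is a fixed point
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(back, path2)
  expect_identical(readLines(path), readLines(path2))
  cfg$cohort$n_mice <- 4
  expect_error(run_experiment(cfg), "unknown cohort key")
})

test_that("the null experiment reports zero reductions and p = 1", {
  cfg <- default_experiment_config(seed = 5)
  cfg$parameters$ko <- cfg$parameters$wt
  cfg$cohort$between_animal_cv <- 0
  cfg$cohort$noise_sd_um <- 0
  cfg$cohort$n_wt <- 2; cfg$cohort$n_ko <- 2
  cfg$cohort$duration_s <- 8
  res <- run_experiment(cfg)
  expect_equal(res$comparison$pct_reduction_vm, 0, tolerance = 1e-6)
  expect_equal(res$comparison$pct_reduction_dap, 0, tolerance = 1e-6)
  expect_equal(res$welch$t, 0)
  expect_equal(res$welch$p, 1)
})

test_that("reruns of the same experiment config are byte-identical", {
  cfg <- default_experiment_config(seed = 12)
  cfg$cohort$n_wt <- 2; cfg$cohort$n_ko <- 2
  cfg$cohort$duration_s <- 8
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg$output_dir <- d1; run_experiment(cfg)
  cfg$output_dir <- d2; run_experiment(cfg)
  files <- setdiff(list.files(d1), "run.log")  # timestamps live in the log only
  expect_true(length(files) >= 10)
  expect_identical(sort(files), sort(setdiff(list.files(d2), "run.log")))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # the log records every seed and the integrator setting
  log <- readLines(file.path(d1, "run.log"))
  expect_true(any(grepl("cohort_seed", log)))
  expect_true(any(grepl("RK4", log)))
})

test_that("stage failures propagate with the stage name", {
  cfg <- default_experiment_config(seed = 1)
  cfg$parameters$wt$Vm <- -1
  expect_error(run_experiment(cfg), "run_experiment \\[config\\]")
})

test_that("the CLI dispatcher drives every subcommand", {
  dir <- withr::local_tempdir()
  model_cfg <- file.path(dir, "model.yaml")
  writeLines(c("protocol:",
               "  n_pulses: 30", "  frequency_hz: 50",
               "  current_ma: 0.4", "  onset_s: 2",
               "parameters:",
               "  Vm: 7.4", "  DAP: 0.67"), model_cfg)

  trace_csv <- file.path(dir, "trace.csv")
  fscv_cli(c("simulate", "--config", model_cfg, "--out", trace_csv,
             "--duration", "8"))
  tr <- read.csv(trace_csv)
  expect_named(tr, c("time_s", "da_s_um", "da_e_um", "gamma_um"))
  expect_equal(nrow(tr), 8001)

  gen_cfg <- file.path(dir, "cohort.yaml")
  writeLines(c(readLines(model_cfg),
               "cohort:",
               "  genotype: WT", "  n_animals: 2",
               "  between_animal_cv: 0", "  noise_sd_um: 0",
               "  duration_s: 8",
               "seed: 4"), gen_cfg)
  gen_dir <- file.path(dir, "gen")
  fscv_cli(c("generate", "--config", gen_cfg, "--out", gen_dir))
  expect_true(file.exists(file.path(gen_dir, "wt_01.csv")))
  expect_true(file.exists(file.path(gen_dir, "manifest.csv")))

  met_csv <- file.path(dir, "metrics.csv")
  fscv_cli(c("metrics", "--config", model_cfg,
             "--recording", file.path(gen_dir, "wt_01.csv"),
             "--out", met_csv))
  expect_named(read.csv(met_csv),
               c("peak_um", "peak_time_s", "t_half_s", "baseline_um"))

  fit_json <- file.path(dir, "fit_wt.json")
  fscv_cli(c("fit", "--config", model_cfg,
             "--recording", file.path(gen_dir, "wt_01.csv"),
             "--out", fit_json))
  fit <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$estimates$Vm, 7.4, tolerance = 0.01)

  cmp_json <- file.path(dir, "cmp.json")
  fscv_cli(c("compare", "--wt", fit_json, "--ko", fit_json,
             "--out", cmp_json))
  cmp <- jsonlite::read_json(cmp_json, simplifyVector = TRUE)
  expect_equal(cmp$pct_reduction_vm, 0, tolerance = 1e-6)

  expect_error(fscv_cli(c("fit", "--config", model_cfg)), "requires --recording")
  expect_error(fscv_cli("nonsense"), "unknown subcommand")
})
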