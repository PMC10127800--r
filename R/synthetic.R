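#' Deterministic seed mixing
#'
#' Derives a per-animal RNG seed from a cohort seed and the animal index by a
#' fixed linear-congruential mix, `(seed * 69069 + index * 1234567) mod
#' 2147483647`, so that adding animals to a cohort never reshuffles the
#' recordings of earlier animals.
#'
#' @param seed cohort seed (non-negative integer below 2^31)
#' @param index animal index (positive integer)
#' @return a derived seed in `[0, 2^31 - 1)`
#' @export
mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 1234567) %% 2147483647)
}

#' Generate one synthetic FSCV recording
#'
#' Simulates the kinetic model, samples the electrode observable at the
#' acquisition rate, and adds i.i.d. zero-mean Gaussian measurement noise.
#'
#' @param params a [kinetic_params()]
#' @param protocol a [stim_protocol()]
#' @param noise_sd additive measurement noise standard deviation, uM
#' @param sample_rate acquisition rate, Hz
#' @param seed integer seed fixing the noise draw; `NULL` uses the current RNG
#'   stream (for callers that manage seeding themselves)
#' @param duration recording length, s
#' @param dt integration step, s
#' @param genotype optional genotype label stored in the metadata
#' @return an [fscv_recording()] whose metadata records the generating
#'   parameters, seed and noise level
#' @export
generate_recording <- function(params, protocol, noise_sd = 0,
                               sample_rate = 10, seed = NULL, duration = 12,
                               dt = 1e-3, genotype = NA_character_) {
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("generate_recording: noise_sd must be >= 0")
  tr <- simulate_trace(params, protocol, duration, dt)
  rec <- sample_recording(tr, sample_rate)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) rec$da <- rec$da + rnorm(length(rec$da), 0, noise_sd)
  rec$metadata <- list(
    genotype = genotype, sample_rate_hz = sample_rate,
    noise_sd_um = noise_sd, seed = if (is.null(seed)) NA_integer_ else seed,
    params = stats::setNames(vapply(.param_fields, function(f) params[[f]],
                                    numeric(1)), .param_fields))
  rec
}

#' Cohort specification
#'
#' Describes a genotype cohort of animals: shared median kinetic parameters,
#' between-animal variability on the free parameters, per-recording noise,
#' and the seed that fixes all randomness.
#'
#' @param genotype cohort label, e.g. `"WT"`
#' @param mean_params a [kinetic_params()]; the cohort median. Its `free`
#'   mask selects which parameters vary between animals.
#' @param between_animal_cv fractional coefficient of variation of the free
#'   parameters across animals (>= 0); draws are log-normal with median
#'   `mean_params`, so parameters stay positive
#' @param n_animals number of animals (>= 1)
#' @param noise_sd additive measurement noise per recording, uM
#' @param sample_rate acquisition rate, Hz
#' @param seed cohort seed; per-animal seeds are derived with [mix_seed()]
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(genotype, mean_params, between_animal_cv = 0.1,
                        n_animals = 5L, noise_sd = 0, sample_rate = 10,
                        seed = 1L) {
  validate_params(mean_params)
  bad <- function(msg) stop("invalid cohort spec: ", msg, call. = FALSE)
  if (n_animals < 1L) bad("n_animals must be >= 1")
  if (between_animal_cv < 0) bad("between_animal_cv must be >= 0")
  if (noise_sd < 0) bad("noise_sd must be >= 0")
  structure(list(genotype = genotype, mean_params = mean_params,
                 between_animal_cv = between_animal_cv,
                 n_animals = as.integer(n_animals), noise_sd = noise_sd,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic recordings
#'
#' For each animal, draws its free kinetic parameters from a log-normal
#' distribution with median `mean_params` and coefficient of variation
#' `between_animal_cv` (fixed parameters are shared), then generates one
#' noisy recording. The per-animal seed is `mix_seed(spec$seed, animal)`,
#' and both the parameter draw and the noise draw consume that animal's
#' stream, so every animal is reproducible in isolation.
#'
#' @param spec a [cohort_spec()]
#' @param protocol a [stim_protocol()]
#' @param duration recording length, s
#' @param dt integration step, s
#' @return a list of [fscv_recording()]s, one per animal; each recording's
#'   metadata carries the drawn parameters, animal id and derived seed
#' @export
generate_cohort <- function(spec, protocol, duration = 12, dt = 1e-3) {
  stopifnot(inherits(spec, "cohort_spec"))
  sdlog <- sqrt(log(1 + spec$between_animal_cv^2))
  lapply(seq_len(spec$n_animals), function(i) {
    animal_seed <- mix_seed(spec$seed, i)
    set.seed(animal_seed)
    p <- spec$mean_params
    if (length(p$free) && sdlog > 0) {
      draws <- vapply(p$free, function(f)
        p[[f]] * exp(rnorm(1, 0, sdlog)), numeric(1))
      p <- set_params(p, draws)
    }
    rec <- generate_recording(p, protocol, noise_sd = spec$noise_sd,
                              sample_rate = spec$sample_rate, seed = NULL,
                              duration = duration, dt = dt,
                              genotype = spec$genotype)
    rec$metadata$seed <- animal_seed
    rec$metadata$animal <- i
    rec
  })
}

#' Pointwise average of recordings
#'
#' Averages recordings sample-by-sample, mirroring the across-animal trace
#' averaging done before model fitting.
#'
#' @param recs a list of [fscv_recording()]s on identical time grids
#' @return an [fscv_recording()]; metadata records the number of source
#'   recordings and their genotypes
#' @export
average_recordings <- function(recs) {
  stopifnot(length(recs) >= 1L, all(vapply(recs, inherits, logical(1),
                                           "fscv_recording")))
  t0 <- recs[[1L]]$time
  for (r in recs)
    if (length(r$time) != length(t0) || any(abs(r$time - t0) > 1e-9))
      stop("average_recordings: recordings are not on identical time grids")
  da <- rowMeans(vapply(recs, function(r) r$da, numeric(length(t0))))
  gts <- unique(vapply(recs, function(r)
    as.character(r$metadata$genotype %||% NA_character_), character(1)))
  fscv_recording(t0, da, metadata = list(
    n_source = length(recs), genotype = paste(gts, collapse = "+"),
    sample_rate_hz = recs[[1L]]$metadata$sample_rate_hz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
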