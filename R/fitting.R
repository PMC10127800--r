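#' Fit the kinetic model to a recording
#'
#' Constrained nonlinear least squares: the free parameters (default `Vm` and
#' `DAP`) are adjusted to minimise the residual sum of squares between the
#' recording and the model observable evaluated on the recording's grid. The
#' optimiser is bounded Levenberg-Marquardt on the residual vector
#' ([minpack.lm::nls.lm()]); a single deterministic start is used: the
#' supplied `start`, or the geometric midpoint of each parameter's bounds.
#'
#' @param rec an [fscv_recording()] to fit
#' @param protocol the [stim_protocol()] used during acquisition
#' @param params a [kinetic_params()] supplying the fixed parameter values
#'   (and the default free mask)
#' @param free character vector of free parameter names; must be nonempty
#' @param bounds named list of `c(lower, upper)` per free parameter; defaults
#'   from [default_bounds()]
#' @param start named numeric vector of starting values for the free
#'   parameters; default is the geometric midpoint of each parameter's bounds
#' @param dt integration step used for the model evaluations, s
#' @param max_iterations Levenberg-Marquardt iteration cap
#' @return an object of class `fit_result`: `params` (fitted values
#'   substituted), `r2`, `rss` (uM^2), `n_evaluations`, `converged`,
#'   `free_names`, `message`, plus the start and bounds used
#' @examples
#' \donttest{
#' p <- stim_protocol()
#' rec <- sample_recording(simulate_trace(wt_params(), p), 10)
#' fit <- fit_trace(rec, p, wt_params(), start = c(Vm = 11, DAP = 1))
#' fit$params$Vm
#' }
#' @export
fit_trace <- function(rec, protocol, params, free = params$free,
                      bounds = NULL, start = NULL, dt = 1e-3,
                      max_iterations = 200) {
  stopifnot(inherits(rec, "fscv_recording"))
  validate_protocol(protocol)
  validate_params(params)
  free <- as.character(free)
  if (!length(free))
    stop("fit_trace: free parameter mask is empty, nothing to fit")
  if (!all(free %in% .free_allowed))
    stop("fit_trace: unknown free parameter(s): ",
         paste(setdiff(free, .free_allowed), collapse = ", "))
  if (max(rec$time) <= protocol_end(protocol))
    stop("fit_trace: recording ends before the stimulation does")

  all_bounds <- default_bounds()
  if (!is.null(bounds)) all_bounds[names(bounds)] <- bounds
  lower <- vapply(free, function(f) all_bounds[[f]][1], numeric(1))
  upper <- vapply(free, function(f) all_bounds[[f]][2], numeric(1))
  if (is.null(start)) {
    start <- exp((log(lower) + log(upper)) / 2)  # geometric midpoint
    names(start) <- free
  } else {
    if (is.null(names(start)) || !all(free %in% names(start)))
      stop("fit_trace: start must be a named vector covering every free parameter")
    start <- start[free]
  }
  if (any(start < lower) || any(start > upper))
    stop("fit_trace: start lies outside the bounds")

  # model grid must resolve the recording's sample times
  duration <- ceiling(max(rec$time) / dt) * dt
  idx <- round(rec$time / dt) + 1L
  if (any(abs((idx - 1L) * dt - rec$time) > 1e-6))
    stop("fit_trace: recording sample times do not fall on the model dt grid")

  n_eval <- 0L
  residual_fn <- function(theta) {
    n_eval <<- n_eval + 1L
    p <- set_params(params, stats::setNames(theta, free))
    tr <- simulate_from_state(p, protocol, duration, dt)
    rec$da - tr$DA_E[idx]
  }

  res <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = residual_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iterations))
  fitted_values <- stats::setNames(as.numeric(res$par), free)
  fitted_params <- set_params(params, fitted_values)
  fitted_params$free <- free
  model_rec <- predicted_recording(rec, protocol, fitted_params, dt)
  structure(list(
    params = fitted_params,
    estimates = fitted_values,
    r2 = r_squared(rec, model_rec),
    rss = sum(res$fvec^2),
    n_evaluations = n_eval,
    converged = res$info %in% 1:3,
    info = res$info,
    message = res$message,
    free_names = free,
    start = start,
    lower = lower, upper = upper,
    fitted_curve = model_rec,
    protocol = protocol
  ), class = "fit_result")
}

#' Model observable on a recording's grid
#'
#' Convenience wrapper: simulate the model and sample it at exactly the times
#' of an existing recording.
#'
#' @inheritParams fit_trace
#' @return an [fscv_recording()] of the model prediction
#' @export
predicted_recording <- function(rec, protocol, params, dt = 1e-3) {
  duration <- ceiling(max(rec$time) / dt) * dt
  tr <- simulate_from_state(params, protocol, duration, dt)
  idx <- round(rec$time / dt) + 1L
  fscv_recording(rec$time, tr$DA_E[idx], metadata = list(source = "model"))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kinetic model fit (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  for (f in x$free_names)
    cat(sprintf("  %-5s = %.6g  (start %.4g, bounds [%g, %g])\n", f,
                x$estimates[[f]], x$start[[f]],
                x$lower[[which(x$free_names == f)]],
                x$upper[[which(x$free_names == f)]]))
  cat(sprintf("  R2 = %.4f, RSS = %.4g uM^2, %d model evaluations\n",
              x$r2, x$rss, x$n_evaluations))
  invisible(x)
}

#' Compare fitted genotypes
#'
#' Computes the percent reductions of the free parameters of interest between
#' a reference (wild-type) fit and a comparison (knockout) fit:
#' `100 * (WT - KO) / WT` for `Vm` and `DAP`.
#'
#' @param fit_wt,fit_ko `fit_result` objects from [fit_trace()], or
#'   [kinetic_params()] objects holding the fitted values directly
#' @return an object of class `genotype_comparison` with `vm_wt`, `vm_ko`,
#'   `dap_wt`, `dap_ko`, `pct_reduction_vm`, `pct_reduction_dap`
#' @examples
#' compare_genotypes(wt_params(), ko_params())
#' @export
compare_genotypes <- function(fit_wt, fit_ko) {
  get_par <- function(x, who) {
    if (inherits(x, "fit_result")) {
      if (!x$converged)
        stop("compare_genotypes: the ", who, " fit did not converge")
      x$params
    } else if (inherits(x, "kinetic_params")) x
    else stop("compare_genotypes: expected a fit_result or kinetic_params")
  }
  pw <- get_par(fit_wt, "WT"); pk <- get_par(fit_ko, "KO")
  if (inherits(fit_wt, "fit_result") && inherits(fit_ko, "fit_result")) {
    fixed <- setdiff(.param_fields, union(fit_wt$free_names, fit_ko$free_names))
    mism <- fixed[vapply(fixed, function(f) !isTRUE(all.equal(pw[[f]], pk[[f]])),
                         logical(1))]
    if (length(mism))
      stop("compare_genotypes: fits used different fixed parameter values for ",
           paste(mism, collapse = ", "))
  }
  if (pw$Vm <= 0 || pw$DAP <= 0)
    stop("compare_genotypes: percent reduction undefined for non-positive WT value")
  structure(list(
    vm_wt = pw$Vm, vm_ko = pk$Vm, dap_wt = pw$DAP, dap_ko = pk$DAP,
    pct_reduction_vm = 100 * (pw$Vm - pk$Vm) / pw$Vm,
    pct_reduction_dap = 100 * (pw$DAP - pk$DAP) / pw$DAP
  ), class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat("Genotype comparison (WT vs KO):\n")
  cat(sprintf("  Vm : %.3g -> %.3g uM/s   (%.1f%% reduction, ~%d%%)\n",
              x$vm_wt, x$vm_ko, x$pct_reduction_vm, round(x$pct_reduction_vm)))
  cat(sprintf("  DAP: %.3g -> %.3g uM/mA  (%.1f%% reduction, ~%d%%)\n",
              x$dap_wt, x$dap_ko, x$pct_reduction_dap, round(x$pct_reduction_dap)))
  invisible(x)
}
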