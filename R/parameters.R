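## Names of the numeric kinetic parameters, in canonical order.
.param_fields <- c("DAP", "Vm", "Km", "L", "kS", "kE", "kGamma",
                   "k1ads", "k2ads", "k3ads")

## Parameters that may be declared free during fitting (kGamma excluded:
## it is a structural constant of the electrode model).
.free_allowed <- setdiff(.param_fields, "kGamma")

#' Kinetic parameters of the dopamine release/reuptake/electrode model
#'
#' The full parameter vector of the four-equation model. `DAP` (dopamine
#' released per electrical pulse per unit current, uM/mA) and `Vm` (maximal
#' DAT reuptake velocity, uM/s) are the parameters of scientific interest and
#' are free by default. The remaining parameters describe reuptake affinity,
#' tissue dead-space loss, and the carbon-fiber electrode's transfer and
#' adsorption kinetics; their defaults are declared implementation choices
#' (see the methods vignette) and are shared between simulation and fitting.
#'
#' @param Vm maximal reuptake velocity, uM/s (>= 0)
#' @param DAP dopamine released per stimulus pulse, uM/mA (>= 0)
#' @param Km Michaelis affinity constant of reuptake, uM (> 0)
#' @param L dimensionless dead-space loss factor, in (0, 1]
#' @param kS transfer rate from striatum to electrode, 1/s (>= 0)
#' @param kE transfer rate away from the electrode, 1/s (>= 0)
#' @param kGamma transfer rate of desorbed dopamine back into the measured
#'   signal, 1/s (>= 0; fixed at 1 by convention)
#' @param k1ads adsorption kinetic rate constant, 1/s (>= 0)
#' @param k2ads concentration-dependent desorption rate constant, 1/(uM s) (>= 0)
#' @param k3ads first-order desorption rate constant, 1/s (>= 0)
#' @param free character vector naming the parameters treated as free during
#'   fitting; any subset of DAP, Vm, Km, L, kS, kE, k1ads, k2ads, k3ads
#' @return an object of class `kinetic_params`
#' @seealso [wt_params()], [ko_params()] for the published genotype presets
#' @examples
#' kinetic_params(Vm = 7.4, DAP = 0.67)
#' @export
kinetic_params <- function(Vm, DAP, Km = 0.2, L = 1.0, kS = 5, kE = 5,
                           kGamma = 1, k1ads = 0.1, k2ads = 0.05, k3ads = 0.1,
                           free = c("Vm", "DAP")) {
  p <- structure(
    list(DAP = as.numeric(DAP), Vm = as.numeric(Vm), Km = as.numeric(Km),
         L = as.numeric(L), kS = as.numeric(kS), kE = as.numeric(kE),
         kGamma = as.numeric(kGamma), k1ads = as.numeric(k1ads),
         k2ads = as.numeric(k2ads), k3ads = as.numeric(k3ads),
         free = as.character(free)),
    class = "kinetic_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!inherits(p, "kinetic_params"))
    stop("invalid kinetic parameters: not a kinetic_params object")
  bad <- function(msg) stop("invalid kinetic parameters: ", msg, call. = FALSE)
  for (f in .param_fields) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v)) bad(paste0(f, " must be a finite scalar"))
    if (v < 0) bad(paste0(f, " must be >= 0"))
  }
  if (p$Km <= 0) bad("Km must be > 0")
  if (p$L <= 0 || p$L > 1) bad("L must lie in (0, 1]")
  if (length(p$free) && !all(p$free %in% .free_allowed))
    bad(paste0("free mask contains unknown parameter(s): ",
               paste(setdiff(p$free, .free_allowed), collapse = ", ")))
  invisible(p)
}

#' Published wild-type parameter preset
#'
#' Kinetic parameters with the wild-type fitted values Vm = 7.4 uM/s and
#' DAP = 0.67 uM/mA; all other parameters at package defaults.
#'
#' @param ... overrides passed on to [kinetic_params()]; may also override
#'   `Vm`/`DAP`
#' @return a `kinetic_params` object
#' @export
wt_params <- function(...) {
  args <- utils::modifyList(list(Vm = 7.4, DAP = 0.67), list(...))
  do.call(kinetic_params, args)
}

#' Published auxilin-knockout parameter preset
#'
#' Kinetic parameters with the auxilin-KO fitted values Vm = 2.0 uM/s and
#' DAP = 0.31 uM/mA; all other parameters at package defaults.
#'
#' @param ... overrides passed on to [kinetic_params()]; may also override
#'   `Vm`/`DAP`
#' @return a `kinetic_params` object
#' @export
ko_params <- function(...) {
  args <- utils::modifyList(list(Vm = 2.0, DAP = 0.31), list(...))
  do.call(kinetic_params, args)
}

## Replace the named free parameters with new values, revalidating.
set_params <- function(params, values) {
  stopifnot(!is.null(names(values)), all(names(values) %in% .param_fields))
  for (nm in names(values)) params[[nm]] <- as.numeric(values[[nm]])
  validate_params(params)
  params
}

#' Default fitting bounds for each kinetic parameter
#'
#' Box constraints used by [fit_trace()] when no bounds are supplied. The
#' bounds for `Vm` and `DAP` bracket the physiological range by more than an
#' order of magnitude on each side.
#'
#' @return a named list of `c(lower, upper)` pairs
#' @export
default_bounds <- function() {
  list(Vm    = c(0.01, 50),   DAP   = c(0.001, 10),
       Km    = c(0.01, 10),   L     = c(0.01, 1),
       kS    = c(0.1, 100),   kE    = c(0.1, 100),
       k1ads = c(1e-4, 10),   k2ads = c(1e-4, 10),
       k3ads = c(1e-4, 10))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (uM, s, mA units):\n")
  for (f in .param_fields) {
    tag <- if (f %in% x$free) " [free]" else ""
    cat(sprintf("  %-7s %g%s\n", f, x[[f]], tag))
  }
  invisible(x)
}
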