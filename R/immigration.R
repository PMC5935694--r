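#' Immigration (or emigration) term for one population
#'
#' Describes the inflow added to one side of the predator-prey system:
#' nothing, a constant rate `c` (individuals/time), a density-dependent rate
#' `c / n` where `n` is the receiving population, or a piecewise-constant rate
#' redrawn uniformly at regular intervals. A negative `sign` turns immigration
#' into migration (an outflow), which is only meaningful for the constant and
#' density-dependent modes.
#'
#' @param mode One of `"none"`, `"constant"`, `"density_dependent"`,
#'   `"random_pulse"`.
#' @param magnitude Non-negative rate (the `c` or `d` of the model).
#'   Individuals/time for `"constant"`; individuals^2/time for
#'   `"density_dependent"`. Ignored for `"none"` and `"random_pulse"`.
#' @param sign `+1` for immigration, `-1` for migration. `"random_pulse"`
#'   is always an inflow.
#' @param interval Redraw interval for `"random_pulse"` (time units).
#' @param low,high Uniform bounds for `"random_pulse"` draws,
#'   `0 <= low <= high` (equal bounds give a constant pulsed rate).
#'
#' @return An object of class `lv_immigration`.
#' @examples
#' immigration("constant", magnitude = 0.01)
#' immigration("density_dependent", magnitude = 0.01, sign = -1)
#' immigration("random_pulse", low = 0.001, high = 1)
#' @export
immigration <- function(mode = c("none", "constant", "density_dependent",
                                 "random_pulse"),
                        magnitude = 0, sign = 1,
                        interval = 1, low = 0, high = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      !is.finite(magnitude) || magnitude < 0)
    stop("'magnitude' must be a single non-negative number", call. = FALSE)
  if (!sign %in% c(-1, 1))
    stop("'sign' must be +1 or -1", call. = FALSE)
  if (mode == "density_dependent" && sign > 0 && magnitude <= 0)
    stop("density-dependent immigration requires magnitude > 0", call. = FALSE)
  if (mode == "random_pulse") {
    if (sign < 0)
      stop("random_pulse is an inflow; sign must be +1", call. = FALSE)
    if (!(interval > 0))
      stop("'interval' must be positive", call. = FALSE)
    # low == high is allowed: the degenerate distribution collapses the
    # pulsed term to a constant rate, which is useful as a consistency check
    if (!(low >= 0 && high >= low))
      stop("random_pulse requires 0 <= low <= high", call. = FALSE)
  }
  structure(
    list(mode = mode, magnitude = magnitude, sign = sign,
         interval = interval, low = low, high = high),
    class = "lv_immigration"
  )
}

#' Evaluate an immigration term
#'
#' Returns the rate contribution of an immigration specification to the
#' receiving population's time derivative: 0 for `"none"`,
#' `sign * magnitude` for `"constant"`, `sign * magnitude / density` for
#' `"density_dependent"` and the active drawn rate for `"random_pulse"`.
#'
#' @param spec An [immigration()] object.
#' @param density Current abundance of the receiving population.
#' @param draw Rate drawn for the active interval (`"random_pulse"` only).
#' @param floor Positivity guard for the density-dependent mode: densities
#'   below it raise an error rather than producing a near-singular rate.
#' @param who Population name used in guard diagnostics.
#'
#' @return A single rate (1/time contribution).
#' @export
immigration_term <- function(spec, density, draw = NULL, floor = 1e-6,
                             who = "population") {
  stopifnot(inherits(spec, "lv_immigration"))
  switch(spec$mode,
    none = 0,
    constant = spec$sign * spec$magnitude,
    density_dependent = {
      if (density < floor) {
        stop(structure(
          class = c("lv_positivity_error", "error", "condition"),
          list(message = sprintf(
                 "%s density %.3g fell below the positivity guard %.3g while evaluating a density-dependent immigration term",
                 who, density, floor),
               call = sys.call(-1), population = who, density = density)))
      }
      spec$sign * spec$magnitude / density
    },
    random_pulse = {
      if (is.null(draw))
        stop("random_pulse mode needs the drawn rate for the active interval",
             call. = FALSE)
      draw
    }
  )
}

#' @export
print.lv_immigration <- function(x, ...) {
  desc <- switch(x$mode,
    none = "none",
    constant = sprintf("%s constant rate %g",
                       if (x$sign > 0) "inflow" else "outflow", x$magnitude),
    density_dependent = sprintf("%s density-dependent rate %g / n",
                                if (x$sign > 0) "inflow" else "outflow",
                                x$magnitude),
    random_pulse = sprintf(
      "random pulses ~ Uniform(%g, %g), redrawn every %g time units",
      x$low, x$high, x$interval))
  cat("Immigration term:", desc, "\n")
  invisible(x)
}
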