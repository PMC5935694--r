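#' Trajectory container
#'
#' Holds a simulated orbit on a strictly increasing time grid. Normally
#' produced by [lv_integrate()]; the constructor is exported so that decay
#' estimation can also be applied to externally produced series.
#'
#' @param times Strictly increasing time grid.
#' @param x,y Prey and predator series, same length as `times`.
#' @param model The [lv_model()] that generated the orbit, or `NULL`.
#' @param solver_stats Optional list of solver diagnostics.
#' @return An object of class `lv_trajectory`.
#' @export
lv_trajectory <- function(times, x, y, model = NULL, solver_stats = list()) {
  stopifnot(length(times) == length(x), length(x) == length(y),
            all(diff(times) > 0))
  structure(list(times = times, x = x, y = y, model = model,
                 solver_stats = solver_stats),
            class = "lv_trajectory")
}

#' @export
as.data.frame.lv_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$x, y = x$y)
}

#' @export
print.lv_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Trajectory: %d points on t in [%g, %g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  final state: x = %.6g, y = %.6g\n", x$x[n], x$y[n]))
  st <- x$solver_stats
  if (!is.null(st$nsteps))
    cat(sprintf("  solver: %d steps (%d rejected), %d field evaluations\n",
                st$nsteps, st$nrejected, st$nfev))
  if (isTRUE(!st$complete))
    cat("  NOTE: positivity guard hit; trajectory is partial\n")
  invisible(x)
}

#' Integrate the deterministic system
#'
#' Adaptive Dormand-Prince 5(4) integration of the modified predator-prey
#' field with relative tolerance `1e-9` and absolute tolerance `1e-12` by
#' default. Output is sampled on a uniform grid. Density-dependent
#' immigration terms carry a positivity guard: if the receiving population
#' falls below `model$x_floor` the run stops and the returned (partial)
#' trajectory is flagged, because the model is not defined there.
#'
#' @param model An [lv_model()] with deterministic immigration modes only.
#' @param x0,y0 Positive initial abundances.
#' @param t_end Integration horizon (time units).
#' @param n_out Number of output points after t = 0; the grid is
#'   `seq(0, t_end, length.out = n_out + 1)`. Defaults to 10 points per time
#'   unit.
#' @param rtol,atol Solver tolerances.
#' @return An [lv_trajectory()].
#' @examples
#' mod <- case_model(lv_params(0.1, 0.1, 0.3, 0.2), "A1", c = 0.01)
#' tr <- lv_integrate(mod, 5, 5, t_end = 100)
#' tail(as.data.frame(tr))
#' @export
lv_integrate <- function(model, x0, y0, t_end,
                         n_out = max(10L, ceiling(10 * t_end)),
                         rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(model, "lv_model"), x0 > 0, y0 > 0, t_end > 0)
  if (model$prey$mode == "random_pulse" || model$pred$mode == "random_pulse")
    stop("random_pulse models are integrated with simulate_random_immigration()",
         call. = FALSE)
  p <- model$params
  prey <- model$prey
  pred <- model$pred
  f <- function(t, s) .rhs_raw(s[1], s[2], p, prey, pred)
  floors <- c(if (prey$mode == "density_dependent") model$x_floor else -Inf,
              if (pred$mode == "density_dependent") model$x_floor else -Inf)
  t_out <- seq(0, t_end, length.out = n_out + 1)[-1]
  sol <- .rk45(f, c(x0, y0), 0, t_out, rtol = rtol, atol = atol,
               floors = floors)
  stats <- list(rtol = rtol, atol = atol, nsteps = sol$nsteps,
                nrejected = sol$nrejected, nfev = sol$nfev,
                complete = sol$complete, guard = sol$guard)
  lv_trajectory(c(0, sol$t), c(x0, sol$y[, 1]), c(y0, sol$y[, 2]),
                model = model, solver_stats = stats)
}

#' First integral of the classical system
#'
#' For the unmodified type I system the quantity
#' \eqn{V(x, y) = b x - m \log x + a y - r \log y}
#' is conserved along orbits and minimized at the coexistence equilibrium
#' `(m/b, r/a)`. It serves as an integration oracle: drift in V measures
#' accumulated solver error.
#'
#' @param params An [lv_params()] object (the type I rates are used).
#' @param x,y Positive abundances (vectorized).
#' @return V, same length as the inputs.
#' @examples
#' conserved_quantity(lv_params(0.1, 0.1, 0.3, 0.2), 5, 5)  # 1.517172
#' @export
conserved_quantity <- function(params, x, y) {
  stopifnot(inherits(params, "lv_params"))
  if (any(x <= 0) || any(y <= 0))
    stop("the first integral is defined for positive abundances only",
         call. = FALSE)
  params$b * x - params$m * log(x) + params$a * y - params$r * log(y)
}
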