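#' Ensemble simulation under randomly pulsed immigration
#'
#' Realizes the pulsed-immigration protocol: time is divided into `n_steps`
#' consecutive intervals of the random term's `interval` length; at the start
#' of each interval a fresh rate is drawn uniformly from `[low, high]` for
#' every side in `"random_pulse"` mode (prey first, then predator), the ODE is
#' integrated across the interval with that constant rate, and the solver is
#' restarted at the boundary (the forcing is discontinuous there). The drawn
#' rate is a piecewise-constant immigration *rate*, not an instantaneous jump
#' in abundance, which keeps the ODE well-posed.
#'
#' Each run uses its own RNG substream derived from `seed`, so the ensemble is
#' reproducible draw-for-draw and runs are mutually independent.
#'
#' @param model An [lv_model()] with at least one `"random_pulse"` side.
#' @param x0,y0 Positive initial abundances (shared by all runs).
#' @param n_steps Number of intervals.
#' @param n_runs Ensemble size.
#' @param seed Integer seed (mandatory: ensembles are reproducible by
#'   contract).
#' @param points_per_interval Output samples per interval (>= 1; the interval
#'   end point is always included).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `lv_ensemble`: `times` (shared grid including
#'   t = 0), `runs` (list of [lv_trajectory()]), `mean_x`, `mean_y`
#'   (pointwise arithmetic means) and `draw_log`
#'   (`data.frame(run, interval, c_draw, d_draw)`).
#' @examples
#' p <- lv_params(0.2, 0.1, 0.3, 0.2)
#' rnd <- immigration("random_pulse", low = 0.001, high = 1)
#' ens <- simulate_random_immigration(lv_model(p, prey = rnd, pred = rnd),
#'                                    5, 5, n_steps = 50, n_runs = 3,
#'                                    seed = 1)
#' @export
simulate_random_immigration <- function(model, x0, y0, n_steps, n_runs, seed,
                                        points_per_interval = 1L,
                                        rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(model, "lv_model"), x0 > 0, y0 > 0,
            n_steps >= 1, n_runs >= 1, points_per_interval >= 1)
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is required for ensemble runs", call. = FALSE)
  prey_rand <- model$prey$mode == "random_pulse"
  pred_rand <- model$pred$mode == "random_pulse"
  if (!prey_rand && !pred_rand)
    stop("no random_pulse side in this model; use lv_integrate()",
         call. = FALSE)
  dt <- if (prey_rand) model$prey$interval else model$pred$interval
  if (prey_rand && pred_rand && model$prey$interval != model$pred$interval)
    stop("both random_pulse sides must share the same interval", call. = FALSE)

  p <- model$params
  prey <- model$prey
  pred <- model$pred
  floors <- c(if (prey$mode == "density_dependent") model$x_floor else -Inf,
              if (pred$mode == "density_dependent") model$x_floor else -Inf)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  rel <- seq_len(points_per_interval) / points_per_interval * dt
  times <- c(0, as.vector(outer(rel, (seq_len(n_steps) - 1) * dt, "+")))
  runs <- vector("list", n_runs)
  logs <- vector("list", n_runs)
  sum_x <- numeric(length(times))
  sum_y <- numeric(length(times))

  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    # draw order is c then d within each interval; a side that is not
    # random_pulse consumes no draws
    if (prey_rand && pred_rand) {
      u <- matrix(stats::runif(2 * n_steps), nrow = 2)
      cs <- prey$low + u[1, ] * (prey$high - prey$low)
      ds <- pred$low + u[2, ] * (pred$high - pred$low)
    } else {
      cs <- if (prey_rand) stats::runif(n_steps, prey$low, prey$high)
            else rep(NA_real_, n_steps)
      ds <- if (pred_rand) stats::runif(n_steps, pred$low, pred$high)
            else rep(NA_real_, n_steps)
    }
    xs <- numeric(length(times)); ys <- numeric(length(times))
    xs[1] <- x0; ys[1] <- y0
    state <- c(x0, y0)
    nfev <- 0L; nsteps_tot <- 0L
    idx <- 2L
    complete <- TRUE
    for (k in seq_len(n_steps)) {
      cd <- if (prey_rand) cs[k] else NULL
      dd <- if (pred_rand) ds[k] else NULL
      f <- function(t, s) .rhs_raw(s[1], s[2], p, prey, pred, cd, dd)
      t0 <- (k - 1) * dt
      sol <- .rk45(f, state, t0, t0 + rel, rtol = rtol, atol = atol,
                   floors = floors)
      nout <- length(sol$t)
      if (nout > 0) {
        xs[idx:(idx + nout - 1)] <- sol$y[, 1]
        ys[idx:(idx + nout - 1)] <- sol$y[, 2]
      }
      nfev <- nfev + sol$nfev
      nsteps_tot <- nsteps_tot + sol$nsteps
      if (!sol$complete) { complete <- FALSE; idx <- idx + nout; break }
      state <- sol$y[nout, ]
      idx <- idx + nout
    }
    keep <- seq_len(idx - 1L)
    runs[[run]] <- lv_trajectory(times[keep], xs[keep], ys[keep],
                                 model = model,
                                 solver_stats = list(nfev = nfev,
                                                     nsteps = nsteps_tot,
                                                     nrejected = NA,
                                                     complete = complete))
    if (!complete)
      stop("a run hit the positivity guard; the ensemble grid is no longer shared",
           call. = FALSE)
    logs[[run]] <- data.frame(run = run, interval = seq_len(n_steps),
                              c_draw = cs, d_draw = ds)
    sum_x <- sum_x + xs
    sum_y <- sum_y + ys
  }

  structure(list(times = times, runs = runs,
                 mean_x = sum_x / n_runs, mean_y = sum_y / n_runs,
                 draw_log = do.call(rbind, logs),
                 seed = as.integer(seed)),
            class = "lv_ensemble")
}

#' @export
as.data.frame.lv_ensemble <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$runs), function(i) {
    cbind(as.data.frame(x$runs[[i]]), run = i)
  }))
}

#' @export
print.lv_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d runs on t in [%g, %g] (%d grid points), seed %d\n",
              length(x$runs), x$times[1], x$times[length(x$times)],
              length(x$times), x$seed))
  invisible(x)
}

#' Peak-to-trough oscillation amplitude over a time window
#'
#' Convenience summary used when comparing early against late behaviour of a
#' (mean) series: `max - min` of the values with `t` in `[from, to]`.
#'
#' @param times Time grid.
#' @param series Values on the grid.
#' @param from,to Window bounds (inclusive).
#' @return A single non-negative number.
#' @export
oscillation_amplitude <- function(times, series, from, to) {
  sel <- times >= from & times <= to
  if (!any(sel)) stop("empty window", call. = FALSE)
  max(series[sel]) - min(series[sel])
}
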