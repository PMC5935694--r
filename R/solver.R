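# Adaptive explicit Dormand-Prince 5(4) integrator, plain R.
#
# Small and self-contained on purpose: the vector field here is a cheap
# two-dimensional smooth system, so an embedded RK pair with PI-free step
# control is entirely adequate and keeps the package dependency-light.
# Output points are hit exactly by capping the step, which also keeps the
# conserved-quantity oracle honest (no interpolation error in the samples).

.dp_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_c <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
# 5th-order weights equal the last A row (FSAL); embedded 4th-order weights:
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# f(t, y) -> dy/dt (length-2 numeric). floors: abort thresholds per
# component (-Inf disables). Returns times/states sampled at t_out, solver
# counters, and a guard record if a floor was breached (partial output).
.rk45 <- function(f, y0, t0, t_out, rtol = 1e-9, atol = 1e-12,
                  floors = c(-Inf, -Inf), max_steps = 5e6,
                  who = c("prey", "predator")) {
  stopifnot(length(t_out) >= 1, all(diff(t_out) > 0), t_out[1] > t0)
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(t_out), ncol = n)
  t <- t0
  y <- y0
  k1 <- f(t, y)
  nfev <- 1L
  nsteps <- 0L
  nrej <- 0L
  guard <- NULL
  t_end <- t_out[length(t_out)]

  # initial step size: crude curvature probe (Hairer-style, simplified)
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2))
  d1 <- sqrt(mean((k1 / sc)^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6
  h <- min(h, t_end - t0)
  y1 <- y + h * k1
  k2 <- f(t + h, y1)
  nfev <- nfev + 1L
  d2 <- sqrt(mean(((k2 - k1) / sc)^2)) / h
  if (max(d1, d2) > 1e-15)
    h <- min(h, (0.01 / max(d1, d2))^(1 / 5))
  h <- max(h, 1e-10)

  i_out <- 1L
  ks <- matrix(0, nrow = n, ncol = 7)
  repeat {
    if (nsteps + nrej > max_steps)
      stop(structure(class = c("lv_solver_error", "error", "condition"),
                     list(message = sprintf(
                            "integrator exceeded %d steps at t = %.6g (last state %.6g, %.6g)",
                            max_steps, t, y[1], y[2]),
                          call = NULL, t = t, y = y)))
    hit_out <- FALSE
    h_try <- h
    if (t + h_try >= t_out[i_out] - 1e-14 * max(1, abs(t))) {
      h_try <- t_out[i_out] - t
      hit_out <- TRUE
    }

    ks[, 1] <- k1
    for (s in 1:6) {
      ys <- y + h_try * as.vector(ks[, 1:s, drop = FALSE] %*% .dp_A[[s]])
      ks[, s + 1] <- f(t + .dp_c[s] * h_try, ys)
    }
    nfev <- nfev + 6L
    y5 <- ys                       # stage 7 input = 5th order solution (FSAL)
    err_vec <- h_try * as.vector(ks %*% .dp_b4) - (y5 - y)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / sc)^2))

    if (err <= 1) {
      t_new <- if (hit_out) t_out[i_out] else t + h_try
      y <- y5
      k1 <- ks[, 7]
      t <- t_new
      nsteps <- nsteps + 1L
      if (any(y < floors)) {
        ib <- which(y < floors)[1]
        guard <- list(population = who[ib], t = t, state = y,
                      floor = floors[ib])
        break
      }
      if (hit_out) {
        out[i_out, ] <- y
        i_out <- i_out + 1L
        if (i_out > length(t_out)) break
      }
      fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
      h <- h_try * fac
    } else {
      nrej <- nrej + 1L
      h <- h_try * max(0.1, 0.9 * err^(-0.2))
    }
  }

  keep <- seq_len(i_out - 1L)
  list(t = t_out[keep], y = out[keep, , drop = FALSE],
       nsteps = nsteps, nrejected = nrej, nfev = nfev,
       guard = guard, complete = is.null(guard))
}
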