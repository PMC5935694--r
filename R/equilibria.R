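#' Equilibrium container
#'
#' @keywords internal
.new_equilibrium <- function(x_star, y_star, case_label, feasible, residual) {
  structure(list(x_star = x_star, y_star = y_star, case_label = case_label,
                 feasible = feasible, residual = residual),
            class = "lv_equilibrium")
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium [%s]: (x*, y*) = (%.8g, %.8g)  %s  residual %.2e\n",
              x$case_label, x$x_star, x$y_star,
              if (x$feasible) "feasible" else "INFEASIBLE", x$residual))
  invisible(x)
}

#' Closed-form coexistence equilibria (type I response)
#'
#' The linear-response system admits printed equilibria for the four
#' immigration cases and the classical baseline:
#' \describe{
#'   \item{classical}{`(m/b, r/a)`}
#'   \item{A1 (constant prey inflow c)}{`(m/b, (m r + b c)/(a m))`}
#'   \item{B1 (constant predator inflow d)}{`((m r - a d)/(b r), r/a)`,
#'     feasible when `m r > a d`}
#'   \item{C1 (prey inflow c/x)}{`(m/b, (m^2 r + b^2 c)/(a m^2))`}
#'   \item{D1 (predator inflow d/y)}{`((m r^2 - a^2 d)/(b r^2), r/a)`,
#'     feasible when `m r^2 > a^2 d`}
#' }
#' Infeasible parameters give `feasible = FALSE` (not an error). The residual
#' of the corresponding vector field at the point is attached.
#'
#' @param params Type I [lv_params()] (`h = 0`, `alpha = 0`).
#' @param case One of `"classical"`, `"A1"`, `"B1"`, `"C1"`, `"D1"`.
#' @param magnitude The case's immigration magnitude (`c` for A1/C1, `d` for
#'   B1/D1; ignored for `"classical"`).
#' @return An `lv_equilibrium`.
#' @examples
#' p <- lv_params(0.1, 0.1, 0.3, 0.2)
#' equilibrium_closed_form(p, "A1", 0.01)  # (0.666667, 1.15)
#' @export
equilibrium_closed_form <- function(params,
                                    case = c("classical", "A1", "B1",
                                             "C1", "D1"),
                                    magnitude = 0) {
  stopifnot(inherits(params, "lv_params"))
  case <- match.arg(case)
  if (response_type(params) != "I")
    stop(structure(class = c("lv_unsupported_case", "error", "condition"),
                   list(message = "closed-form equilibria exist for the type I response only; use equilibrium_numeric()",
                        call = sys.call(-1))))
  if (magnitude < 0) stop("'magnitude' must be non-negative", call. = FALSE)
  r <- params$r; a <- params$a; b <- params$b; m <- params$m
  pt <- switch(case,
    classical = c(m / b, r / a),
    A1 = c(m / b, (m * r + b * magnitude) / (a * m)),
    B1 = c((m * r - a * magnitude) / (b * r), r / a),
    C1 = c(m / b, (m^2 * r + b^2 * magnitude) / (a * m^2)),
    D1 = c((m * r^2 - a^2 * magnitude) / (b * r^2), r / a))
  feasible <- pt[1] > 0 && pt[2] > 0
  # at zero magnitude every case degenerates to the unmodified system (a
  # density-dependent spec with magnitude 0 is not even constructible)
  model_case <- if (case == "classical" || magnitude == 0) "none" else case
  mod <- case_model(params, model_case, c = magnitude, d = magnitude)
  residual <- if (feasible) max(abs(lv_rhs(pt[1], pt[2], mod))) else NA_real_
  .new_equilibrium(pt[1], pt[2], case, feasible, residual)
}

## no-immigration coexistence point for any response type; used as the
## Newton starting guess. b*g(x) = m gives x = (m/(b - h m))^(1/(1+alpha))
## (positive only when b > h m); y follows from the prey nullcline.
.baseline_guess <- function(params) {
  p <- params
  if (p$b > p$h * p$m) {
    x <- (p$m / (p$b - p$h * p$m))^(1 / (1 + p$alpha))
    y <- p$r * x / (p$a * .g(x, p))
    c(x, y)
  } else {
    c(p$m / p$b, p$r / p$a)
  }
}

#' Numerical coexistence equilibrium
#'
#' Newton iteration on the deterministic vector field using the analytic
#' Jacobian, started from the no-immigration coexistence point of the model's
#' response type (or a supplied guess) with a retry ladder of multiplicative
#' perturbations (x0.5, x2, x5 on both coordinates). A root is accepted when
#' `max |rhs| <= 1e-10` and both coordinates are positive; a converged root
#' with a non-positive coordinate is returned with `feasible = FALSE`
#' (no positive root). Failure to converge from every start raises an error
#' of class `lv_no_convergence`.
#'
#' @param model An [lv_model()] with deterministic immigration modes.
#' @param guess Optional length-2 positive starting point `c(x, y)`.
#' @param residual_tol Acceptance residual (rate units).
#' @return An `lv_equilibrium` with `case_label = "numeric"`.
#' @examples
#' p2 <- lv_params(0.1, 0.1, 0.3, 0.2, h = 0.1)
#' equilibrium_numeric(lv_model(p2))  # (0.714286, 1.071429)
#' @export
equilibrium_numeric <- function(model, guess = NULL, residual_tol = 1e-10) {
  stopifnot(inherits(model, "lv_model"))
  if (model$prey$mode == "random_pulse" || model$pred$mode == "random_pulse")
    stop("equilibria are defined for the deterministic system only",
         call. = FALSE)
  p <- model$params
  base <- if (is.null(guess)) .baseline_guess(p) else as.numeric(guess)
  stopifnot(length(base) == 2, all(base > 0))

  newton <- function(start) {
    z <- start
    for (it in 1:60) {
      fz <- .rhs_raw(z[1], z[2], p, model$prey, model$pred)
      if (!all(is.finite(fz))) return(NULL)
      if (max(abs(fz)) <= residual_tol * 1e-2 && it > 1) break
      J <- .jacobian_raw(model, z[1], z[2])
      step <- tryCatch(solve(J, fz), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      # damp steps that would cross zero; the field is singular there for
      # density-dependent terms and the root of interest is interior
      lam <- 1
      while (lam > 1e-6 && any(z - lam * step <= 0 & z > 0)) lam <- lam / 2
      z <- z - lam * step
    }
    fz <- .rhs_raw(z[1], z[2], p, model$prey, model$pred)
    if (all(is.finite(fz)) && max(abs(fz)) <= residual_tol) {
      list(z = z, residual = max(abs(fz)))
    } else NULL
  }

  for (fac in c(1, 0.5, 2, 5)) {
    res <- newton(base * fac)
    if (!is.null(res)) {
      feasible <- all(res$z > 0)
      return(.new_equilibrium(res$z[1], res$z[2], "numeric",
                              feasible, res$residual))
    }
  }
  stop(structure(class = c("lv_no_convergence", "error", "condition"),
                 list(message = "equilibrium solver did not converge from any start in the retry ladder",
                      call = sys.call(-1))))
}
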