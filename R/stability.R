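## Analytic Jacobian of the deterministic field at (x, y), no validation.
## With g(x) = x^(1+a)/(1 + h x^(1+a)):
##   J11 = r - a g'(x) y + C'(x),  J12 = -a g(x)
##   J21 = b g'(x) y,              J22 = b g(x) - m + D'(y)
## where C'(x) = 0 (constant) or -sign*c/x^2 (density-dependent), D' alike.
.jacobian_raw <- function(model, x, y) {
  p <- model$params
  g <- .g(x, p)
  gp <- .gprime(x, p)
  matrix(c(p$r - p$a * gp * y + .imm_deriv(model$prey, x),
           p$b * gp * y,
           -p$a * g,
           p$b * g - p$m + .imm_deriv(model$pred, y)),
         nrow = 2)
}

#' Analytic Jacobian of the modified system
#'
#' Evaluates the 2x2 Jacobian of the deterministic vector field at a point
#' with both coordinates positive. Random-pulse immigration has no
#' deterministic linearization and is rejected.
#'
#' @param model An [lv_model()] object.
#' @param x,y Evaluation point, both positive.
#' @return A 2x2 numeric matrix.
#' @examples
#' p <- lv_params(0.1, 0.1, 0.3, 0.2)
#' jacobian_analytic(lv_model(p), x = p$m / p$b, y = p$r / p$a)
#' @export
jacobian_analytic <- function(model, x, y) {
  stopifnot(inherits(model, "lv_model"))
  if (model$prey$mode == "random_pulse" || model$pred$mode == "random_pulse")
    stop("stability analysis is defined for the deterministic system only",
         call. = FALSE)
  if (!(x > 0 && y > 0))
    stop("the Jacobian is evaluated at interior points (x > 0, y > 0)",
         call. = FALSE)
  .jacobian_raw(model, x, y)
}

#' Closed-form amplitude decay rates (type I immigration cases)
#'
#' Near each immigration-shifted equilibrium of the linear-response system the
#' oscillation amplitude shrinks like `exp(-gamma * t)` with
#' \describe{
#'   \item{A1}{`gamma = b c / (2 m)`}
#'   \item{B1}{`gamma = a d / (2 r)`}
#'   \item{C1}{`gamma = b^2 c / m^2`}
#'   \item{D1}{`gamma = a^2 d / r^2`}
#' }
#' all strictly positive for positive magnitude — the analytic statement that
#' small immigration turns the neutral cycles into a stable focus.
#'
#' @param params Type I [lv_params()].
#' @param magnitude Immigration magnitude (`c` or `d` of the case).
#' @param case One of `"A1"`, `"B1"`, `"C1"`, `"D1"`.
#' @return The decay rate (1/time).
#' @examples
#' gamma_closed_form(lv_params(0.1, 0.1, 0.3, 0.2), 0.01, "A1")  # 0.0075
#' @export
gamma_closed_form <- function(params, magnitude, case = c("A1", "B1",
                                                          "C1", "D1")) {
  stopifnot(inherits(params, "lv_params"))
  case <- match.arg(case)
  if (response_type(params) != "I")
    stop("closed-form decay rates are for the type I response only",
         call. = FALSE)
  if (magnitude < 0) stop("'magnitude' must be non-negative", call. = FALSE)
  r <- params$r; a <- params$a; b <- params$b; m <- params$m
  switch(case,
    A1 = b * magnitude / (2 * m),
    B1 = a * magnitude / (2 * r),
    C1 = b^2 * magnitude / m^2,
    D1 = a^2 * magnitude / r^2)
}

#' Stability criterion for the sigmoid response without immigration
#'
#' Returns `beta = r b - h m r`. Positivity of beta is the local stability
#' condition of the type III coexistence equilibrium in the absence of
#' immigration.
#'
#' @param params An [lv_params()] object.
#' @return beta.
#' @examples
#' beta_criterion(lv_params(0.1, 0.1, 0.3, 0.2, h = 0.1, alpha = 1))  # 0.028
#' @export
beta_criterion <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  params$r * params$b - params$h * params$m * params$r
}

#' Classify an equilibrium by its Jacobian spectrum
#'
#' Applies the trace/determinant rule for two-dimensional systems: with
#' neutrality tolerance `tol`,
#' `Tr(J) < -tol` and `Det(J) > tol` give `"asymptotically_stable"`;
#' `Det(J) < -tol` a `"saddle"`; `Tr(J) > tol` `"unstable"`;
#' `|Tr(J)| <= tol` with `Det(J) > tol` a `"neutral_center"`. Infeasible
#' equilibria are labelled `"infeasible"` without linearization. For the
#' type I immigration cases the closed-form decay rate is attached; the
#' numeric counterpart `-max(Re(lambda))` (the slow mode, which governs the
#' asymptotic envelope) is always reported.
#'
#' The default `tol = 1e-12` is deliberately tight: the classical
#' linear-response center has exactly zero trace analytically and must not be
#' pushed into a spurious stable/unstable verdict by floating-point noise.
#'
#' @param model An [lv_model()] object.
#' @param eq An `lv_equilibrium` (closed-form or numeric).
#' @param tol Neutrality tolerance on trace and determinant.
#' @return An object of class `lv_stability` with fields `jacobian`,
#'   `eigenvalues`, `trace`, `determinant`, `classification`,
#'   `gamma_analytic` (or `NA`), `gamma_numeric`, `beta`.
#' @examples
#' p <- lv_params(0.1, 0.1, 0.3, 0.2)
#' eq <- equilibrium_closed_form(p, "A1", 0.01)
#' classify_equilibrium(case_model(p, "A1", c = 0.01), eq)
#' @export
classify_equilibrium <- function(model, eq, tol = 1e-12) {
  stopifnot(inherits(model, "lv_model"), inherits(eq, "lv_equilibrium"))
  beta <- beta_criterion(model$params)
  if (!isTRUE(eq$feasible)) {
    return(structure(list(jacobian = NULL, eigenvalues = NULL,
                          trace = NA_real_, determinant = NA_real_,
                          classification = "infeasible",
                          gamma_analytic = NA_real_,
                          gamma_numeric = NA_real_, beta = beta,
                          equilibrium = eq),
                     class = "lv_stability"))
  }
  J <- jacobian_analytic(model, eq$x_star, eq$y_star)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  lam <- eigen(J, only.values = TRUE)$values
  lam <- lam[order(-Re(lam))]
  classification <-
    if (dt < -tol) "saddle"
    else if (tr < -tol && dt > tol) "asymptotically_stable"
    else if (tr > tol) "unstable"
    else if (abs(tr) <= tol && dt > tol) "neutral_center"
    else "unstable"  # degenerate det ~ 0 with nonpositive trace
  ga <- NA_real_
  if (eq$case_label %in% c("A1", "B1", "C1", "D1") &&
      response_type(model$params) == "I") {
    mag <- if (eq$case_label %in% c("A1", "C1")) model$prey$magnitude
           else model$pred$magnitude
    ga <- gamma_closed_form(model$params, mag, eq$case_label)
  }
  structure(list(jacobian = J, eigenvalues = lam,
                 trace = tr, determinant = dt,
                 classification = classification,
                 gamma_analytic = ga,
                 gamma_numeric = -Re(lam[1]),
                 beta = beta, equilibrium = eq),
            class = "lv_stability")
}

#' @export
print.lv_stability <- function(x, ...) {
  cat(sprintf("Stability: %s\n", x$classification))
  if (!is.null(x$jacobian)) {
    cat(sprintf("  Tr(J) = %.6g, Det(J) = %.6g\n", x$trace, x$determinant))
    cat(sprintf("  eigenvalues: %.6g %+.6gi, %.6g %+.6gi\n",
                Re(x$eigenvalues[1]), Im(x$eigenvalues[1]),
                Re(x$eigenvalues[2]), Im(x$eigenvalues[2])))
    cat(sprintf("  gamma: numeric %.6g", x$gamma_numeric))
    if (!is.na(x$gamma_analytic))
      cat(sprintf(", analytic %.6g", x$gamma_analytic))
    cat("\n")
  }
  cat(sprintf("  beta = %.6g\n", x$beta))
  invisible(x)
}
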