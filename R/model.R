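#' Assemble the full dynamical system
#'
#' Couples a parameter set with the prey-side and predator-side immigration
#' terms. The resulting system is
#' \deqn{dx/dt = r x - a g(x) y + C(x), \quad dy/dt = b g(x) y - m y + D(y)}
#' with intake \eqn{g(x) = x^{1+\alpha}/(1 + h x^{1+\alpha})} and C, D given
#' by the two [immigration()] specifications.
#'
#' @param params An [lv_params()] object.
#' @param prey Immigration term added to the prey equation.
#' @param pred Immigration term added to the predator equation.
#' @param x_floor Positivity guard (individuals) used when either side has a
#'   density-dependent term; the model assumes the receiving population never
#'   vanishes, and a trajectory touching the guard aborts with a diagnostic
#'   rather than being clipped.
#'
#' @return An object of class `lv_model`.
#' @examples
#' demo <- lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2)
#' lv_model(demo, prey = immigration("constant", 0.01))
#' @export
lv_model <- function(params,
                     prey = immigration("none"),
                     pred = immigration("none"),
                     x_floor = 1e-6) {
  stopifnot(inherits(params, "lv_params"),
            inherits(prey, "lv_immigration"),
            inherits(pred, "lv_immigration"))
  needs_floor <- prey$mode == "density_dependent" ||
    pred$mode == "density_dependent"
  if (needs_floor && !(is.numeric(x_floor) && x_floor > 0))
    stop("'x_floor' must be positive when a density-dependent term is present",
         call. = FALSE)
  structure(
    list(params = params, prey = prey, pred = pred, x_floor = x_floor),
    class = "lv_model"
  )
}

#' Per-predator prey intake g(x)
#'
#' The functional response \eqn{g(x) = x^{1+\alpha}/(1 + h x^{1+\alpha})}:
#' linear when `h = 0, alpha = 0`, saturating hyperbolic (type II) when
#' `h > 0, alpha = 0`, sigmoid (type III) when `h > 0, alpha > 0`.
#'
#' @param x Prey abundance, non-negative (vectorized).
#' @param params An [lv_params()] object.
#' @return g(x), same length as `x`; bounded above by `1/h` when `h > 0`.
#' @examples
#' functional_response(5, lv_params(0.1, 0.1, 0.3, 0.2, h = 0.1))
#' @export
functional_response <- function(x, params) {
  stopifnot(inherits(params, "lv_params"))
  if (any(x < 0)) stop("prey abundance must be non-negative", call. = FALSE)
  .g(x, params)
}

## unchecked kernels shared by the public surface, the integrator and the
## Newton solver; must stay branch-free in x so solver stages that graze
## zero evaluate without error
.g <- function(x, p) {
  u <- x^(1 + p$alpha)
  u / (1 + p$h * u)
}

.gprime <- function(x, p) {
  u <- x^(1 + p$alpha)
  (1 + p$alpha) * x^p$alpha / (1 + p$h * u)^2
}

## immigration rate and its derivative wrt the receiving density, no guards
.imm_rate <- function(spec, n, draw) {
  switch(spec$mode,
    none = 0,
    constant = spec$sign * spec$magnitude,
    density_dependent = spec$sign * spec$magnitude / n,
    random_pulse = if (is.null(draw)) 0 else draw)
}

.imm_deriv <- function(spec, n) {
  if (spec$mode == "density_dependent") -spec$sign * spec$magnitude / n^2
  else 0
}

#' Vector field of the modified system
#'
#' Evaluates (dx/dt, dy/dt) at a state. With both immigration modes `"none"`
#' and a type I response this reduces exactly to the classical Lotka-Volterra
#' field `(r x - a x y, b x y - m y)`.
#'
#' @param x,y Prey and predator abundances, non-negative.
#' @param model An [lv_model()] object.
#' @param draws Named list or vector with elements `c` (prey side) and `d`
#'   (predator side): the active rates for any `"random_pulse"` terms.
#' @return Numeric vector `c(dx, dy)`.
#' @examples
#' mod <- lv_model(lv_params(0.1, 0.1, 0.3, 0.2))
#' lv_rhs(5, 5, mod)  # (-2, 6.5)
#' @export
lv_rhs <- function(x, y, model, draws = NULL) {
  stopifnot(inherits(model, "lv_model"))
  if (x < 0 || y < 0)
    stop("abundances must be non-negative", call. = FALSE)
  cx <- immigration_term(model$prey, x, draw = draws[["c"]],
                         floor = model$x_floor, who = "prey")
  dy_term <- immigration_term(model$pred, y, draw = draws[["d"]],
                              floor = model$x_floor, who = "predator")
  p <- model$params
  g <- .g(x, p)
  c(p$r * x - p$a * g * y + cx,
    p$b * g * y - p$m * y + dy_term)
}

## fast unchecked field used inside the integrator; draws are plain numbers
.rhs_raw <- function(x, y, p, prey, pred, cdraw = NULL, ddraw = NULL) {
  g <- .g(x, p)
  c(p$r * x - p$a * g * y + .imm_rate(prey, x, cdraw),
    p$b * g * y - p$m * y + .imm_rate(pred, y, ddraw))
}

#' Build a model for one of the canonical immigration cases
#'
#' Shorthand used throughout the scenario suite. Cases follow the usual
#' labelling: `A1` constant prey inflow `c`, `B1` constant predator inflow
#' `d`, `C1` density-dependent prey inflow `c/x`, `D1` density-dependent
#' predator inflow `d/y`; `A2`-`D2` are the sign-flipped (migration)
#' counterparts; `both` applies constant inflows on both sides; `none` is the
#' unmodified system.
#'
#' @param params An [lv_params()] object.
#' @param case Case label.
#' @param c,d Prey-side and predator-side magnitudes.
#' @param x_floor Positivity guard, see [lv_model()].
#' @return An [lv_model()] object.
#' @export
case_model <- function(params,
                       case = c("none", "A1", "B1", "C1", "D1",
                                "A2", "B2", "C2", "D2", "both"),
                       c = 0.01, d = 0.01, x_floor = 1e-6) {
  case <- match.arg(case)
  none <- immigration("none")
  prey <- switch(case,
    A1 = immigration("constant", c),
    C1 = immigration("density_dependent", c),
    A2 = immigration("constant", c, sign = -1),
    C2 = immigration("density_dependent", c, sign = -1),
    both = immigration("constant", c),
    none)
  pred <- switch(case,
    B1 = immigration("constant", d),
    D1 = immigration("density_dependent", d),
    B2 = immigration("constant", d, sign = -1),
    D2 = immigration("density_dependent", d, sign = -1),
    both = immigration("constant", d),
    none)
  lv_model(params, prey = prey, pred = pred, x_floor = x_floor)
}

#' @export
print.lv_model <- function(x, ...) {
  print(x$params)
  cat("Prey side:     "); print(x$prey)
  cat("Predator side: "); print(x$pred)
  invisible(x)
}

# ---------------------------------------------------------------------------
# flat-config serialization

#' Serialize a model (plus initial state) to a flat configuration
#'
#' The flat representation uses the keys `r, a, b, m, h, alpha, prey_mode,
#' prey_c, prey_sign, pred_mode, pred_d, pred_sign, interval, low, high,
#' x0, y0, x_floor` and round-trips through JSON.
#'
#' @param model An [lv_model()] object.
#' @param x0,y0 Initial abundances stored alongside the model.
#' @return A named list of scalars.
#' @seealso [model_from_config()], [read_model_config()]
#' @export
model_to_config <- function(model, x0 = 5, y0 = 5) {
  p <- model$params
  list(r = p$r, a = p$a, b = p$b, m = p$m, h = p$h, alpha = p$alpha,
       prey_mode = model$prey$mode, prey_c = model$prey$magnitude,
       prey_sign = model$prey$sign,
       pred_mode = model$pred$mode, pred_d = model$pred$magnitude,
       pred_sign = model$pred$sign,
       interval = model$prey$interval, low = model$prey$low,
       high = model$prey$high,
       x0 = x0, y0 = y0, x_floor = model$x_floor)
}

#' Rebuild a model from a flat configuration
#'
#' @param config Named list as produced by [model_to_config()]; missing keys
#'   fall back to their defaults.
#' @return A list with elements `model`, `x0`, `y0`.
#' @export
model_from_config <- function(config) {
  get_or <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else v
  }
  params <- lv_params(r = config$r, a = config$a, b = config$b, m = config$m,
                      h = get_or("h", 0), alpha = get_or("alpha", 0))
  mk <- function(mode, mag, sign) {
    if (mode == "random_pulse")
      immigration(mode, interval = get_or("interval", 1),
                  low = get_or("low", 0), high = get_or("high", 1))
    else if (mode == "none") immigration("none")
    else immigration(mode, magnitude = mag, sign = sign)
  }
  prey <- mk(get_or("prey_mode", "none"), get_or("prey_c", 0),
             get_or("prey_sign", 1))
  pred <- mk(get_or("pred_mode", "none"), get_or("pred_d", 0),
             get_or("pred_sign", 1))
  list(model = lv_model(params, prey = prey, pred = pred,
                        x_floor = get_or("x_floor", 1e-6)),
       x0 = get_or("x0", 5), y0 = get_or("y0", 5))
}

#' Read / write a model configuration file (JSON, flat keys)
#'
#' @param path File path.
#' @return `read_model_config()` returns what [model_from_config()] returns.
#' @export
read_model_config <- function(path) {
  model_from_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_model_config
#' @param model An [lv_model()] object.
#' @param x0,y0 Initial abundances.
#' @export
write_model_config <- function(model, path, x0 = 5, y0 = 5) {
  jsonlite::write_json(model_to_config(model, x0 = x0, y0 = y0), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
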