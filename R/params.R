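#' Rate constants of the predator-prey model
#'
#' Bundles the per-capita rates of the two-species system together with the
#' shape of the functional response. The per-predator intake of prey is
#' \eqn{g(x) = x^{1+\alpha} / (1 + h x^{1+\alpha})}: `h = 0, alpha = 0` gives
#' the linear (type I) response, `h > 0, alpha = 0` the hyperbolic (type II)
#' response and `h > 0, alpha > 0` the sigmoid (type III) response. The
#' validated surface uses `alpha` in `{0, 1}`; other non-negative exponents
#' are accepted but flagged as unvalidated.
#'
#' @param r Prey reproduction rate (1/time), positive.
#' @param a Predation (consumption) rate coefficient (1/(predator * time)),
#'   positive.
#' @param b Predator birth rate per captured prey (1/(prey * time)), positive.
#' @param m Predator mortality rate (1/time), positive.
#' @param h Functional-response saturation coefficient; `h * x^(1+alpha)` is
#'   dimensionless. Default 0 (type I).
#' @param alpha Hill exponent, non-negative. Default 0.
#'
#' @return An object of class `lv_params`.
#' @examples
#' p <- lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2)
#' response_type(p)
#' @export
lv_params <- function(r, a, b, m, h = 0, alpha = 0) {
  for (nm in c("r", "a", "b", "m", "h", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (r <= 0 || a <= 0 || b <= 0 || m <= 0)
    stop("rate constants r, a, b, m must all be positive", call. = FALSE)
  if (h < 0) stop("'h' must be non-negative", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  if (alpha > 0 && h == 0)
    warning("alpha > 0 with h = 0 is outside the named response types",
            call. = FALSE)
  out <- structure(
    list(r = r, a = a, b = b, m = m, h = h, alpha = alpha),
    class = "lv_params"
  )
  if (!(alpha %in% c(0, 1)))
    attr(out, "unvalidated_alpha") <- TRUE
  out
}

#' Functional-response type of a parameter set
#'
#' @param params An [lv_params()] object.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
response_type <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  if (params$h == 0 && params$alpha == 0) "I"
  else if (params$h > 0 && params$alpha == 0) "II"
  else "III"
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf(
    "Lotka-Volterra parameters (type %s response)\n", response_type(x)))
  cat(sprintf("  r = %g, a = %g, b = %g, m = %g, h = %g, alpha = %g\n",
              x$r, x$a, x$b, x$m, x$h, x$alpha))
  invisible(x)
}
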