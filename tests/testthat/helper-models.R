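# Parameter sets used throughout: the worked-example values for the three
# response types and the faster-prey set used by the random-pulse protocol.
demo_params <- function() lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2)
pulse_params <- function() lv_params(r = 0.2, a = 0.1, b = 0.3, m = 0.2)
type2_params <- function() lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2,
                                     h = 0.1)
type3_params <- function() lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2,
                                     h = 0.1, alpha = 1)

# random type I parameter draw on the grid used by the equivalence and
# gamma-identity properties
draw_params <- function() {
  v <- stats::runif(4, 0.05, 1)
  lv_params(r = v[1], a = v[2], b = v[3], m = v[4])
}

# central finite-difference Jacobian of the vector field: the independent
# oracle for the analytic Jacobian
fd_jacobian <- function(model, x, y, eps = 1e-6) {
  f <- function(x, y) lv_rhs(x, y, model)
  hx <- eps * max(1, abs(x))
  hy <- eps * max(1, abs(y))
  J <- matrix(0, 2, 2)
  J[, 1] <- (f(x + hx, y) - f(x - hx, y)) / (2 * hx)
  J[, 2] <- (f(x, y + hy) - f(x, y - hy)) / (2 * hy)
  J
}
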