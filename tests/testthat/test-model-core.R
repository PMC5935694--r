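test_that("parameter validation enforces the rate-constant invariants", {
  expect_error(lv_params(-0.1, 0.1, 0.3, 0.2), "positive")
  expect_error(lv_params(0.1, 0.1, 0.3, 0.2, h = -1), "non-negative")
  expect_error(lv_params(0.1, 0.1, 0.3, 0.2, alpha = -0.5), "non-negative")
  expect_identical(response_type(demo_params()), "I")
  expect_identical(response_type(type2_params()), "II")
  expect_identical(response_type(type3_params()), "III")
})

test_that("functional response matches the closed form for all three types", {
  expect_identical(functional_response(0, type3_params()), 0)
  expect_identical(functional_response(5, demo_params()), 5)
  expect_equal(functional_response(5, type2_params()), 5 / 1.5)
  expect_equal(functional_response(2, type3_params()), 4 / 1.4)
  expect_error(functional_response(-1, demo_params()), "non-negative")
})

test_that("functional response is nondecreasing and bounded by 1/h", {
  x <- seq(0, 50, by = 0.25)
  for (p in list(demo_params(), type2_params(), type3_params())) {
    g <- functional_response(x, p)
    expect_true(all(diff(g) >= 0))
    if (p$h > 0) expect_true(all(g < 1 / p$h))
  }
})

test_that("immigration terms evaluate per mode, sign and density", {
  expect_identical(immigration_term(immigration("none"), 5), 0)
  expect_equal(immigration_term(immigration("constant", 0.01), 5), 0.01)
  expect_equal(
    immigration_term(immigration("density_dependent", 0.01), 5), 0.002)
  expect_equal(
    immigration_term(immigration("constant", 0.01, sign = -1), 5), -0.01)
  expect_equal(
    immigration_term(immigration("random_pulse", low = 0, high = 1), 5,
                     draw = 0.37), 0.37)
  expect_error(
    immigration_term(immigration("random_pulse", low = 0, high = 1), 5),
    "drawn rate")
})

test_that("density-dependent terms guard positivity and name the population", {
  spec <- immigration("density_dependent", 0.01)
  err <- expect_error(
    immigration_term(spec, 1e-9, floor = 1e-6, who = "predator"),
    class = "lv_positivity_error")
  expect_match(conditionMessage(err), "predator")
})

test_that("immigration spec validation", {
  expect_error(immigration("constant", -1), "non-negative")
  expect_error(immigration("density_dependent", 0), "magnitude > 0")
  expect_error(immigration("random_pulse", sign = -1), "inflow")
  expect_error(immigration("random_pulse", low = 2, high = 1), "low <= high")
  expect_silent(immigration("random_pulse", low = 0.01, high = 0.01))
})

test_that("vector field reproduces hand-substituted values", {
  mod <- lv_model(demo_params())
  expect_equal(lv_rhs(5, 5, mod), c(-2, 6.5))
  mod_c <- case_model(demo_params(), "A1", c = 0.01)
  expect_equal(lv_rhs(5, 5, mod_c), c(-1.99, 6.5))
  eq <- equilibrium_closed_form(demo_params(), "A1", 0.01)
  expect_lt(max(abs(lv_rhs(eq$x_star, eq$y_star, mod_c))), 1e-12)
})

test_that("type I with no immigration reduces exactly to the classical field", {
  mod <- lv_model(demo_params())
  p <- demo_params()
  set.seed(11)
  for (i in 1:25) {
    x <- runif(1, 0.01, 20)
    y <- runif(1, 0.01, 20)
    expect_identical(lv_rhs(x, y, mod),
                     c(p$r * x - p$a * x * y, p$b * x * y - p$m * y))
  }
})

test_that("axes are invariant for the unmodified system", {
  mod <- lv_model(demo_params())
  f <- lv_rhs(7, 0, mod)
  expect_identical(f[2], 0)
  expect_equal(f[1], demo_params()$r * 7)
  expect_identical(lv_rhs(0, 3, mod)[1], 0)
})

test_that("prey derivative is monotone in the immigration magnitude", {
  p <- demo_params()
  dx_at <- function(mag, sgn) {
    mod <- lv_model(p, prey = immigration("constant", mag, sign = sgn))
    lv_rhs(2, 3, mod)[1]
  }
  mags <- c(0.001, 0.01, 0.1, 1)
  expect_true(all(diff(vapply(mags, dx_at, 1, sgn = 1)) > 0))
  expect_true(all(diff(vapply(mags, dx_at, 1, sgn = -1)) < 0))
})

test_that("model configuration round-trips through the flat form and JSON", {
  mod <- lv_model(type3_params(),
                  prey = immigration("density_dependent", 0.02),
                  pred = immigration("constant", 0.05, sign = -1),
                  x_floor = 1e-5)
  back <- model_from_config(model_to_config(mod, x0 = 4, y0 = 2))
  expect_equal(back$model, mod)
  expect_equal(c(back$x0, back$y0), c(4, 2))

  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(mod, path, x0 = 4, y0 = 2)
  back2 <- read_model_config(path)
  expect_equal(back2$model, mod)

  rnd <- lv_model(pulse_params(),
                  prey = immigration("random_pulse", low = 0.001, high = 1),
                  pred = immigration("random_pulse", low = 0.001, high = 1))
  expect_equal(model_from_config(model_to_config(rnd))$model, rnd)
})
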