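test_that("analytic Jacobian matches hand algebra at the type I equilibria", {
  p <- demo_params()
  # classical center: diagonal vanishes
  J <- jacobian_analytic(lv_model(p), p$m / p$b, p$r / p$a)
  expect_equal(J, matrix(c(0, p$b * p$r / p$a, -p$a * p$m / p$b, 0), 2),
               tolerance = 1e-12)
  # constant prey inflow: J11 = -b c / m
  eq <- equilibrium_closed_form(p, "A1", 0.01)
  J <- jacobian_analytic(case_model(p, "A1", c = 0.01), eq$x_star, eq$y_star)
  expect_equal(J[1, 1], -0.015, tolerance = 1e-12)
  # density-dependent prey inflow: J11 = -2 b^2 c / m^2
  eq <- equilibrium_closed_form(p, "C1", 0.01)
  J <- jacobian_analytic(case_model(p, "C1", c = 0.01), eq$x_star, eq$y_star)
  expect_equal(J[1, 1], -0.045, tolerance = 1e-12)
})

test_that("analytic Jacobian agrees with finite differences everywhere", {
  set.seed(7)
  cases <- c("none", "A1", "B1", "C1", "D1", "A2", "B2", "C2", "D2", "both")
  for (i in 1:30) {
    p <- if (i %% 3 == 0) draw_params()
         else lv_params(runif(1, 0.05, 1), runif(1, 0.05, 1),
                        runif(1, 0.05, 1), runif(1, 0.05, 1),
                        h = runif(1, 0, 0.3),
                        alpha = sample(c(0, 1), 1))
    mod <- case_model(p, sample(cases, 1), c = runif(1, 0.001, 0.1),
                      d = runif(1, 0.001, 0.1))
    x <- runif(1, 0.2, 5)
    y <- runif(1, 0.2, 5)
    Ja <- jacobian_analytic(mod, x, y)
    Jn <- fd_jacobian(mod, x, y)
    expect_equal(Ja, Jn, tolerance = 1e-6)
  }
})

test_that("Jacobian rejects boundary points and random-pulse models", {
  mod <- lv_model(demo_params())
  expect_error(jacobian_analytic(mod, 0, 1), "interior")
  rnd <- lv_model(pulse_params(),
                  prey = immigration("random_pulse", low = 0, high = 1))
  expect_error(jacobian_analytic(rnd, 1, 1), "deterministic")
})

test_that("closed-form decay rates and the beta criterion", {
  p <- demo_params()
  expect_equal(gamma_closed_form(p, 0.01, "A1"), 0.0075)
  expect_equal(gamma_closed_form(p, 0.01, "B1"), 0.005)
  expect_equal(gamma_closed_form(p, 0.01, "C1"), 0.0225)
  expect_equal(gamma_closed_form(p, 0.01, "D1"), 0.01)
  for (case in c("A1", "B1", "C1", "D1")) {
    expect_identical(gamma_closed_form(p, 0, case), 0)
    expect_true(all(diff(vapply(c(0.001, 0.01, 0.05, 0.1),
                                gamma_closed_form, 1,
                                params = p, case = case)) > 0))
  }
  expect_equal(beta_criterion(type3_params()), 0.028)
  expect_equal(beta_criterion(lv_params(0.1, 0.1, 0.3, 0.2, h = 1.5)), 0)
  expect_gt(beta_criterion(demo_params()), 0)  # type I limit: r b
})

test_that("classifier reproduces the canonical verdicts", {
  p <- demo_params()
  rep <- classify_equilibrium(lv_model(p),
                              equilibrium_closed_form(p, "classical"))
  expect_identical(rep$classification, "neutral_center")
  expect_lte(max(abs(Re(rep$eigenvalues))), 1e-12)
  expect_equal(sort(Im(rep$eigenvalues)), c(-1, 1) * sqrt(p$r * p$m),
               tolerance = 1e-8)

  mod2 <- lv_model(type2_params())
  rep2 <- classify_equilibrium(mod2, equilibrium_numeric(mod2))
  expect_identical(rep2$classification, "unstable")
  expect_equal(rep2$trace, 0.1 * 0.5 / 7.5, tolerance = 1e-8)  # r h x*/(1+h x*)

  mod3 <- lv_model(type3_params())
  rep3 <- classify_equilibrium(mod3, equilibrium_numeric(mod3))
  expect_identical(rep3$classification, "asymptotically_stable")
  expect_gt(rep3$beta, 0)

  modA2 <- case_model(p, "A2", c = 0.01)
  repA2 <- classify_equilibrium(modA2, equilibrium_numeric(modA2))
  expect_false(repA2$classification == "asymptotically_stable")

  inf <- equilibrium_closed_form(p, "B1", 10)  # far past the boundary
  expect_identical(classify_equilibrium(case_model(p, "B1", d = 10),
                                        inf)$classification, "infeasible")
})

test_that("trace and determinant track the eigenvalues", {
  set.seed(19)
  for (i in 1:20) {
    p <- draw_params()
    mag <- runif(1, 0.001, 0.1 * min(p$r, p$m))
    case <- sample(c("A1", "B1", "C1", "D1"), 1)
    eq <- equilibrium_closed_form(p, case, mag)
    rep <- classify_equilibrium(case_model(p, case, c = mag, d = mag), eq)
    expect_equal(rep$trace, Re(sum(rep$eigenvalues)), tolerance = 1e-10)
    expect_equal(rep$determinant, Re(prod(rep$eigenvalues)),
                 tolerance = 1e-10)
  }
})

test_that("gamma identity: -Tr/2 always, -Re(lambda) when underdamped", {
  set.seed(23)
  for (i in 1:40) {
    p <- draw_params()
    mag <- runif(1, 0.001, 0.1 * min(p$r, p$m))
    for (case in c("A1", "B1", "C1", "D1")) {
      eq <- equilibrium_closed_form(p, case, mag)
      if (!eq$feasible) next
      gam <- gamma_closed_form(p, mag, case)
      rep <- classify_equilibrium(case_model(p, case, c = mag, d = mag), eq)
      expect_equal(-rep$trace / 2, gam, tolerance = 1e-10)
      if (abs(Im(rep$eigenvalues[1])) > 0)
        expect_equal(rep$gamma_numeric, gam, tolerance = 1e-8)
      expect_identical(rep$classification, "asymptotically_stable")
      expect_equal(rep$gamma_analytic, gam)
    }
  }
})

test_that("flipping immigration to migration flips the trace perturbation", {
  set.seed(31)
  for (i in 1:15) {
    p <- draw_params()
    mag <- runif(1, 0.001, 0.1 * min(p$r, p$m))
    for (pair in list(c("A1", "A2"), c("B1", "B2"),
                      c("C1", "C2"), c("D1", "D2"))) {
      eq_in <- equilibrium_closed_form(p, pair[1], mag)
      if (!eq_in$feasible) next  # immigration case itself lost positivity
      mod_in <- case_model(p, pair[1], c = mag, d = mag)
      mod_out <- case_model(p, pair[2], c = mag, d = mag)
      eq_out <- tryCatch(equilibrium_numeric(mod_out),
                         lv_no_convergence = function(e) NULL)
      rep_in <- classify_equilibrium(mod_in, eq_in)
      expect_identical(rep_in$classification, "asymptotically_stable")
      if (!is.null(eq_out) && eq_out$feasible) {
        rep_out <- classify_equilibrium(mod_out, eq_out)
        expect_false(rep_out$classification == "asymptotically_stable")
        expect_equal(rep_out$trace, -rep_in$trace, tolerance = 1e-8)
      }
    }
  }
})
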