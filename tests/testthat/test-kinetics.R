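test_that("predict_biomass satisfies the boundary conditions of the balance", {
  p <- retentostat_params()
  expect_identical(predict_biomass(p, 0), p$Cx0)
  # maintenance-only fixed point: all glucose spent on maintenance
  cx_inf <- p$D * (p$Cs_in - p$Cs) / p$ms_g
  expect_equal(predict_biomass(p, 1e6), cx_inf, tolerance = 1e-12)
  expect_error(retentostat_params(D = -1), "positive")
  expect_error(retentostat_params(Cs = 60), "below the feed")
  expect_error(predict_biomass(p, -5), ">= 0")
})

test_that("closed form matches numerical integration of the stated ODE", {
  skip_if_not_installed("deSolve")
  p <- retentostat_params()
  times <- c(0, 48, 216, 384, 528)
  ode <- integrate_biomass_ode(p, times)
  expect_lt(max(abs(predict_biomass(p, times) / ode - 1)), 1e-6)
  # 20 random valid parameter sets over the full 22-day window
  set.seed(101)
  for (i in 1:20) {
    pr <- retentostat_params(D = runif(1, 0.005, 0.1),
                             Cs_in = runif(1, 10, 80),
                             Cs = runif(1, 0, 0.5),
                             ms_mmol = runif(1, 0.1, 2),
                             Ysx_max = runif(1, 0.05, 0.4))
    tt <- seq(0, 528, length.out = 12)
    expect_lt(max(abs(predict_biomass(pr, tt) / integrate_biomass_ode(pr, tt) - 1)),
              1e-6)
    cx <- predict_biomass(pr, tt)
    cx_inf <- pr$D * (pr$Cs_in - pr$Cs) / pr$ms_g
    if (pr$Cx0 < cx_inf) {   # biomass accumulates towards the asymptote
      expect_true(all(diff(cx) >= 0))   # non-strict: exp term underflows
      expect_true(all(cx <= cx_inf + 1e-9))
    }
  }
})

test_that("chemostat steady state follows the maintenance-corrected yield", {
  # vanishing maintenance: observed yield approaches the maximum yield
  p0 <- retentostat_params(ms_mmol = 1e-9)
  expect_equal(chemostat_steady_state_biomass(p0), p0$Cs_in * p0$Ysx_max,
               tolerance = 1e-6)
  # increasing D monotonically approaches Cs_in * Ysx_max from below
  cx <- vapply(c(0.01, 0.05, 0.2, 1, 10, 1000), function(D)
    chemostat_steady_state_biomass(retentostat_params(D = D)), numeric(1))
  expect_true(all(diff(cx) > 0))
  expect_true(all(cx < 50 * 0.097))
  # oracle: solve the coupled glucose/biomass balances numerically.
  # qs = D/Ysx_max + ms_g and D * (Cs_in - Cs) = qs * Cx at steady state.
  p <- retentostat_params()
  f <- function(Cx) p$D * (p$Cs_in - p$Cs) - (p$D / p$Ysx_max + p$ms_g) * Cx
  cx_oracle <- uniroot(f, c(1e-6, 100), tol = 1e-12)$root
  expect_equal(chemostat_steady_state_biomass(p), cx_oracle,
               tolerance = 1e-9)
})

test_that("fit_biomass_curve recovers exponential coefficients", {
  t <- seq(0, 528, by = 24)
  A <- -10.28; B <- -0.00874; C <- 13.87
  y <- A * exp(B * t) + C
  fit <- fit_biomass_curve(biomass_series(t, y))
  expect_true(fit$converged)
  expect_equal(fit$A, A, tolerance = 1e-4)
  expect_equal(fit$B, B, tolerance = 1e-4)
  expect_equal(fit$C, C, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)
})

test_that("fit_biomass_curve handles degenerate and short input", {
  t <- seq(0, 200, by = 20)
  flat <- fit_biomass_curve(biomass_series(t, rep(7, length(t))))
  expect_lt(abs(flat$A * exp(flat$B * 0)), 1e-6 * 7)
  expect_equal(flat$C + flat$A, 7, tolerance = 1e-6)
  expect_error(fit_biomass_curve(biomass_series(c(0, 1, 2), c(1, 2, 3))),
               "at least 4")
})

test_that("asymptote recovery is robust to 2% multiplicative noise", {
  p <- retentostat_params()
  t <- seq(0, 528, length.out = 20)
  truth <- predict_biomass(p, t)
  C_true <- p$D * (p$Cs_in - p$Cs) / p$ms_g
  set.seed(31)
  sdlog <- sqrt(log(1 + 0.02^2))
  C_hat <- replicate(100, {
    y <- truth * exp(rnorm(20, 0, sdlog))
    fit_biomass_curve(biomass_series(t, y))$C
  })
  expect_lt(abs(median(C_hat) / C_true - 1), 0.05)
})

test_that("specific growth rate matches the ideal closed form", {
  p <- retentostat_params()
  k <- p$ms_g * p$Ysx_max
  cx_inf <- p$D * (p$Cs_in - p$Cs) / p$ms_g
  # exact ideal-model coefficients, full viability
  fit <- structure(list(A = p$Cx0 - cx_inf, B = -k, C = cx_inf, sse = 0,
                        converged = TRUE, n = 12), class = "biomass_fit")
  t <- c(0, 48, 216, 384, 528)
  series <- biomass_series(t, predict_biomass(p, t))
  prof <- specific_growth_rate(fit, series)
  mu_closed <- k * (cx_inf - predict_biomass(p, t)) / predict_biomass(p, t)
  expect_equal(prof$mu, mu_closed, tolerance = 1e-8)
  expect_true(all(diff(prof$mu) < 0))  # mu decays towards zero
})

test_that("specific growth rate obeys the viability proportionality", {
  t <- seq(0, 100, by = 10)
  fit <- structure(list(A = -5, B = -0.01, C = 12, sse = 0,
                        converged = TRUE, n = 11), class = "biomass_fit")
  cx <- fit$A * exp(fit$B * t) + fit$C
  full <- specific_growth_rate(fit, biomass_series(t, cx, rep(1, 11)))
  half <- specific_growth_rate(fit, biomass_series(t, cx, rep(0.5, 11)))
  expect_equal(half$mu, 2 * full$mu, tolerance = 1e-12)
  # flat fit: no biomass accumulation, mu identically zero
  flat <- structure(list(A = 0, B = -0.01, C = 12, sse = 0,
                         converged = TRUE, n = 11), class = "biomass_fit")
  expect_true(all(specific_growth_rate(flat, biomass_series(t, cx))$mu == 0))
  dead <- biomass_series(t, cx, c(rep(1, 10), 0))
  expect_error(specific_growth_rate(fit, dead), "100")
})

test_that("doubling time is ln(2)/mu with an infinite sentinel", {
  expect_equal(doubling_time(0.005), 138.6, tolerance = 1e-3)
  expect_equal(round(doubling_time(0.005)), 139)
  expect_equal(doubling_time(0.001), 693.1, tolerance = 1e-3)
  expect_gt(doubling_time(0.001), 600)
  expect_identical(doubling_time(log(2)), 1)
  mu <- 10^runif(50, -4, 0)
  expect_equal(doubling_time(mu) * mu, rep(log(2), 50), tolerance = 1e-12)
  expect_identical(doubling_time(c(0, -1)), c(Inf, Inf))
})

test_that("glucose partition splits fluxes as ms*Cx and mu*Cx/Ysx", {
  p <- retentostat_params()
  expect_equal(glucose_partition(p, 5, 0)$frac_maintenance, 1)
  # balance point: growth demand equals maintenance demand
  bal <- glucose_partition(p, 5, p$ms_g * p$Ysx_max)
  expect_equal(bal$frac_maintenance, 0.5, tolerance = 1e-12)
  # chemostat start of the retentostat: hand arithmetic with the
  # standard parameters (Cx = 3.5939 g/L, mu = D)
  cx0 <- chemostat_steady_state_biomass(p)
  part <- glucose_partition(p, cx0, p$D)
  maint <- 0.50 * 0.18016 * cx0
  growth <- 0.025 * cx0 / 0.097
  expect_equal(part$maintenance_flux, maint, tolerance = 1e-12)
  expect_equal(part$growth_flux, growth, tolerance = 1e-12)
  expect_equal(part$frac_maintenance, maint / (maint + growth),
               tolerance = 1e-12)
  # fractions always sum to one; zero-flux case is flagged
  set.seed(5)
  r <- glucose_partition(p, runif(30, 0, 20), 10^runif(30, -4, -1))
  expect_true(all(abs(r$frac_maintenance + r$frac_growth - 1) < 1e-9))
  degen <- glucose_partition(p, 0, 0)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$frac_maintenance))
})

test_that("residual glucose follows the inverted Monod relation", {
  p <- retentostat_params()
  # growth rate at which qs is exactly half of qs_max gives Cs = Ks
  qs_max <- 15; Ks <- 3.8
  mu_half <- (qs_max / 2 - p$ms_mmol) * p$Ysx_max * p$mw_glucose
  expect_equal(residual_glucose_monod(mu_half, qs_max, Ks, p), Ks,
               tolerance = 1e-12)
  # maintenance keeps a positive residual-glucose floor as mu -> 0,
  # near the ~0.13 mM level observed at near-zero growth
  floor_cs <- Ks * p$ms_mmol / (qs_max - p$ms_mmol)
  expect_equal(residual_glucose_monod(0, qs_max, Ks, p), floor_cs)
  expect_gt(floor_cs, 0.12)
  expect_lt(floor_cs, 0.14)
  mu_grid <- seq(0, 0.2, length.out = 40)   # full design range
  cs <- residual_glucose_monod(mu_grid, qs_max, Ks, p)
  expect_true(all(diff(cs) > 0))
  expect_error(residual_glucose_monod(5, qs_max, Ks, p), "saturates")
})
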