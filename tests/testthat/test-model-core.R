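test_that("mass-action derivatives match hand evaluation and conserve mass", {
  r <- rate_constants(k_on = 4.5e-3, k_off = 0.7, k_clv = 0.3,
                      k_lig = 0.05, k_rls = 2, k_bin = 0.02)
  # only association active from a fresh start: flux k_on*S*E = 4.5
  d <- mass_action_rhs(c(S = 100, E = 10, ES = 0, EP = 0, P = 0), r)
  expect_equal(unname(d[c("S", "E", "ES", "EP", "P")]),
               c(-4.5, -4.5, 4.5, 0, 0))

  # empty system is at rest
  d0 <- mass_action_rhs(c(S = 0, E = 0, ES = 0, EP = 0, P = 0), r)
  expect_equal(unname(d0), rep(0, 5))

  # conservation holds for random states and rates
  set.seed(11)
  for (i in 1:25) {
    rr <- rate_constants(k_on = runif(1), k_off = runif(1), k_clv = runif(1),
                         k_lig = runif(1), k_rls = runif(1), k_bin = runif(1))
    st <- setNames(runif(5, 0, 100), c("S", "E", "ES", "EP", "P"))
    dd <- mass_action_rhs(st, rr)
    expect_equal(unname(dd[["S"]] + dd[["ES"]] + dd[["EP"]] + dd[["P"]]), 0)
    expect_equal(unname(dd[["E"]] + dd[["ES"]] + dd[["EP"]]), 0)
  }

  expect_error(rate_constants(k_on = -1, k_off = 1, k_clv = 1,
                              k_rls = 1, k_bin = 1), "non-negative")
})

test_that("model variants clamp the right constants", {
  r <- rate_constants(k_on = 1e-3, k_off = 0.1, k_clv = 0.2,
                      k_lig = 0.002, k_rls = 5, k_bin = 0.1)
  expect_identical(apply_variant(r, "full_equilibrium"), r)
  nl <- apply_variant(r, "no_ligation")
  expect_equal(nl[["k_lig"]], 0)
  expect_equal(unclass(nl)[c("k_on", "k_off", "k_clv", "k_rls", "k_bin")],
               unclass(r)[c("k_on", "k_off", "k_clv", "k_rls", "k_bin")])
  nb <- apply_variant(r, "no_binding")
  expect_equal(nb[["k_lig"]], 0)
  expect_equal(nb[["k_bin"]], 0)
  # override: clamp k_bin alone
  custom <- model_variant("no_binding", clamped = "k_bin")
  nb2 <- apply_variant(r, custom)
  expect_equal(nb2[["k_lig"]], 0.002)
  expect_equal(nb2[["k_bin"]], 0)
  expect_error(model_variant("nonsense"))
  expect_error(model_variant("no_ligation", clamped = "k_foo"), "unknown")
})

test_that("simulation reaches the closed-form reversible-binding equilibrium", {
  # binding only: k_on*S*E = k_off*ES at equilibrium, totals conserved
  r <- rate_constants(k_on = 4.5e-3, k_off = 0.15, k_clv = 0, k_lig = 0,
                      k_rls = 0, k_bin = 0)
  s_tot <- 500; e_tot <- 10
  tr <- simulate_reaction(r, s_tot, e_tot, times = seq(0, 5000, 100))
  fin <- tr[nrow(tr), ]
  # closed form: ES solves k_on*(S-x)(E-x) = k_off*x
  kd <- r[["k_off"]] / r[["k_on"]]
  a <- 1; b <- -(s_tot + e_tot + kd); cc <- s_tot * e_tot
  es_eq <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_rel_equal(fin$ES, es_eq, 1e-3)
  expect_rel_equal(fin$S, s_tot - es_eq, 1e-3)
  expect_lt(abs(r[["k_on"]] * fin$S * fin$E - r[["k_off"]] * fin$ES) /
              (r[["k_off"]] * fin$ES), 1e-3)
})

test_that("all-zero rates give a constant trajectory", {
  r <- rate_constants(k_on = 0, k_off = 0, k_clv = 0, k_lig = 0,
                      k_rls = 0, k_bin = 0)
  tr <- simulate_reaction(r, 100, 10, times = seq(0, 300, 30))
  expect_true(all(tr$S == 100))
  expect_true(all(tr$E == 10))
  expect_true(all(tr$observable == 0))
})

test_that("excess-enzyme irreversible chain matches the linear closed form", {
  # k_off = k_lig = k_bin = 0, E >> S: S -> ES -> EP -> P with effective
  # first-order rates a = k_on*E0, b = k_clv, c = k_rls (Bateman solution)
  e0 <- 5000; s0 <- 1
  r <- rate_constants(k_on = 4.5e-4, k_off = 0, k_clv = 0.05, k_lig = 0,
                      k_rls = 0.4, k_bin = 0)
  a <- r[["k_on"]] * e0; b <- r[["k_clv"]]; cc <- r[["k_rls"]]
  times <- seq(0, 120, 5)
  tr <- simulate_reaction(r, s0, e0, times)
  bateman_p <- function(t) {
    s0 * (1 - (b * cc * exp(-a * t) / ((b - a) * (cc - a)) +
               a * cc * exp(-b * t) / ((a - b) * (cc - b)) +
               a * b * exp(-cc * t) / ((a - cc) * (b - cc))))
  }
  p_exact <- vapply(times[-1], bateman_p, numeric(1))
  expect_lt(max(abs(tr$P[-1] - p_exact)) / s0, 0.005)
})

test_that("adaptive solver agrees with the fixed-step reference integrator", {
  r <- reference_rates()
  times <- seq(0, 600, 30)
  tr <- simulate_reaction(r, 1000, 10, times)
  or <- simulate_reaction_rk4(r, 1000, 10, times, dt = 1e-3)
  expect_lt(max(abs(as.matrix(tr[, 2:6]) - as.matrix(or[, 2:6]))), 1e-6)
})

test_that("trajectories conserve totals, stay non-negative, and the
           observable is monotone without ligation", {
  r <- reference_rates()
  for (s0 in c(100, 1000)) {
    tr <- simulate_reaction(r, s0, 10, seq(0, 1500, 30))
    expect_lt(max(abs(tr$S + tr$ES + tr$EP + tr$P - s0)) / s0, 1e-6)
    expect_lt(max(abs(tr$E + tr$ES + tr$EP - 10)) / 10, 1e-6)
    expect_true(all(as.matrix(tr[, 2:6]) > -1e-10))
    expect_true(all(diff(tr$observable) > -1e-8))
    expect_equal(tr$observable, tr$EP + tr$P)
  }
})

test_that("the complete reaction converts all realized substrate", {
  # No Ligation with fast release: observable tends to ErrS * S0
  r <- rate_constants(k_on = 4.5e-3, k_off = 0.15, k_clv = 0.25, k_lig = 0,
                      k_rls = 20, k_bin = 0.01)
  tr <- simulate_reaction(r, 1000, 10, times = c(0, 6000), err_s = 0.5)
  expect_rel_equal(tr$observable[nrow(tr)], 0.5 * 1000, 1e-3)
})

test_that("observable sums enzyme-bound and free product", {
  expect_equal(observable(c(EP = 3, P = 7)), 10)
  expect_equal(observable(c(EP = 0, P = 0)), 0)
  df <- data.frame(EP = c(1, 2), P = c(3, 4))
  expect_equal(observable(df), c(4, 6))
})

test_that("compiled and plain-R derivatives integrate identically", {
  r <- reference_rates()
  t1 <- simulate_reaction(r, 500, 10, seq(0, 600, 60))
  t2 <- simulate_reaction(r, 500, 10, seq(0, 600, 60), compiled = FALSE)
  expect_equal(t1$observable, t2$observable, tolerance = 1e-8)
})

test_that("trajectory export writes a tidy CSV", {
  tr <- simulate_reaction(reference_rates(), 100, 10, seq(0, 300, 30))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_named(back, c("time_s", "S", "E", "ES", "EP", "P", "observable"))
  expect_equal(back$observable, tr$observable, tolerance = 1e-10)
})
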