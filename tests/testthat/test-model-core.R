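# Structural model: disposition constants, closed-form concentrations,
# superposition, composite absorption rate.

test_that("disposition constants reproduce the quadratic-root values", {
  d <- disposition_constants(dex_typical())
  # frozen from the root formula applied to the DEX typical values
  expect_equal(d$k10, 9.29 / 51.3, tolerance = 1e-12)
  expect_equal(d$beta, 0.09480217, tolerance = 1e-6)
  expect_gt(d$alpha, d$beta)
  expect_gt(d$beta, 0)
  # terminal disposition half-life ~ 7.3 h
  expect_equal(log(2) / d$beta, 7.31, tolerance = 0.01)

  b <- disposition_constants(bet_typical())
  expect_equal(b$beta, 0.03345269, tolerance = 1e-6)

  # roots satisfy their defining quadratic for random parameter sets
  for (p in random_params(20, seed = 42)) {
    dd <- disposition_constants(p)
    for (root in c(dd$alpha, dd$beta))
      expect_equal(root^2 - (dd$k10 + dd$k12 + dd$k21) * root +
                     dd$k10 * dd$k21, 0, tolerance = 1e-10)
  }
})

test_that("no distribution collapses to one-compartment elimination", {
  p <- dex_typical()
  p$cld <- 1e-12  # effectively no peripheral exchange
  d <- disposition_constants(p)
  expect_equal(d$alpha, p$cl / p$vp, tolerance = 1e-6)
  expect_equal(d$beta, d$k21, tolerance = 1e-6)
})

test_that("invalid structural parameters are rejected", {
  expect_error(pk_params(cl = -1, vp = 50, cld = 0.5, vt = 5,
                         ka_im = 0.5, ka_po = 1, fr = 1), "positive")
  expect_error(pk_params(cl = 9, vp = 50, cld = 0.5, vt = 5,
                         ka_im = 0.5, ka_po = 1, fr = 1, ka_ima = 0.01),
               "together")
})

test_that("closed-form profile matches adaptive ODE integration", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 96, 150, 250, 400)
  cases <- list(
    list(p = dex_typical(), d = treatment_doses("A")),
    list(p = dex_typical(), d = treatment_doses("D")),
    list(p = bet_typical(), d = treatment_doses("C")),
    list(p = bet_typical(), d = dose_events(c(0, 24), c(12, 12),
                                            "IM_PHOSPHATE")))
  for (cs in cases) {
    cf <- pk_profile(cs$p, cs$d, tt)$cp
    od <- ode_oracle(cs$p, cs$d, tt)$cp
    expect_equal(cf, od, tolerance = 1e-8)
  }
  # random parameter draws, both drugs' structures
  for (p in c(random_params(15, seed = 7), random_params(10, seed = 8,
                                                         acetate = TRUE))) {
    d <- if (is.null(p$ka_ima)) treatment_doses("A") else treatment_doses("C")
    cf <- pk_profile(p, d, tt)$cp
    od <- ode_oracle(p, d, tt)$cp
    expect_lt(profile_rel_err(cf, od), 1e-6)
  }
})

test_that("profile is zero with no doses and before the first dose", {
  pr <- pk_profile(dex_typical(), dose_events(numeric(0), numeric(0)),
                   seq(0, 48, 4))
  expect_true(all(pr$cp == 0))
  pr2 <- pk_profile(dex_typical(), dose_events(24, 6), c(0, 6, 12, 23.9))
  expect_true(all(pr2$cp == 0))
})

test_that("superposition: dose linearity and time-shift equivariance", {
  p <- bet_typical()
  tt <- seq(0, 96, 1.5)
  one6 <- pk_profile(p, dose_events(0, 6), tt)$cp
  two3 <- pk_profile(p, dose_events(c(0, 0), c(3, 3)), tt)$cp
  expect_equal(two3, one6, tolerance = 1e-12)
  scaled <- pk_profile(p, dose_events(0, 15), tt)$cp
  expect_equal(scaled, 2.5 * one6, tolerance = 1e-12)
  # shift all doses by 12 h -> profile shifts by 12 h
  shifted <- pk_profile(p, dose_events(12, 6), tt + 12)$cp
  expect_equal(shifted, one6, tolerance = 1e-12)
})

test_that("absorption rate equal to a disposition exponent is handled", {
  p <- dex_typical()
  d <- disposition_constants(p)
  p_alpha <- p; p_alpha$ka_im <- d$alpha
  p_beta <- p; p_beta$ka_im <- d$beta
  tt <- seq(0.5, 96, 0.5)
  for (pp in list(p_alpha, p_beta)) {
    cf <- pk_profile(pp, treatment_doses("A"), tt)$cp
    expect_true(all(is.finite(cf)))
    od <- ode_oracle(pp, treatment_doses("A"), tt)$cp
    expect_lt(max(abs(cf - od) / od), 1e-5)
  }
})

test_that("mass balance holds across the model's independent expressions", {
  # absorbed-so-far must equal drug in plasma + tissue + cleared-so-far;
  # the three terms come from different closed-form pieces (state
  # solution, peripheral solution, exact integral), so agreement is a
  # real consistency check, and the state itself is ODE-verified above
  p <- bet_typical()
  doses <- treatment_doses("C")
  tt <- seq(0, 300, 2)
  st <- pk_profile(p, doses, tt, full = TRUE)
  absorbed_input <- function(t) { # ug absorbed by time t
    1000 * sum(vapply(seq_len(nrow(doses)), function(j) {
      ka <- switch(doses$depot[j], IM_PHOSPHATE = p$ka_im, ORAL = p$ka_po,
                   IM_ACETATE = p$ka_ima)
      Fv <- switch(doses$depot[j], IM_PHOSPHATE = 1, ORAL = p$fr,
                   IM_ACETATE = p$fra)
      if (t < doses$time[j]) 0
      else doses$amount[j] * Fv * (1 - exp(-ka * (t - doses$time[j])))
    }, numeric(1)))
  }
  cum_cl <- p$cl * vapply(tt, function(t)
    dexbetpk:::.auc_exact(p, doses, 0, t), numeric(1))
  lhs <- p$vp * st$cp + p$vt * st$ct + cum_cl
  rhs <- vapply(tt, absorbed_input, numeric(1))
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
  # depot amounts non-increasing between doses
  expect_true(all(diff(st$a_ima[tt > 0]) <= 1e-12))
})

test_that("composite ka is the weighted harmonic mean", {
  expect_equal(composite_ka(1, 0.46), 0.46)
  expect_equal(composite_ka(c(2, 5), c(0.7, 0.7)), 0.7)
  b <- bet_typical()
  kac <- composite_ka(c(1, b$fra), c(b$ka_im, b$ka_ima))
  expect_equal(1 / kac, 71.14, tolerance = 1e-3)  # MAT, frozen arithmetic
  expect_error(composite_ka(c(0, 0), c(1, 1)), "zero")
  expect_error(composite_ka(c(1, -1), c(1, 1)), ">= 0")
})
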