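# Secondary descriptors: exposure, peaks, half-lives, residence times,
# and the orthogonal clearance comparison.

test_that("exact AUC matches trapezoid refinement and the CL identity", {
  p <- dex_typical()
  d <- treatment_doses("A")
  pr <- pk_profile(p, d, seq(0, 96, 0.05))
  expect_equal(auc(pr, "exact"), auc(pr, "trapezoid"), tolerance = 1e-4)
  # single-dose AUC to infinity = absorbed dose / clearance
  expect_equal(auc_inf(p, d), 6000 / 9.29, tolerance = 1e-12)
  expect_equal(auc_inf(p, d), 645.9, tolerance = 1e-4)
  # zero profile
  pr0 <- pk_profile(p, dose_events(numeric(0), numeric(0)), 0:96)
  expect_equal(auc(pr0), 0)
  # additivity over superposed doses
  d2 <- dose_events(c(0, 12), c(6, 6))
  expect_equal(auc_inf(p, d2), 2 * auc_inf(p, d), tolerance = 1e-12)
  tt <- seq(0, 400, 0.5)
  expect_equal(auc(pk_profile(p, d2, tt), "exact"),
               auc(pk_profile(p, dose_events(0, 6), tt), "exact") +
                 auc(pk_profile(p, dose_events(12, 6), tt), "exact"),
               tolerance = 1e-10)
})

test_that("peak metrics follow the grid convention", {
  p <- dex_typical()
  d <- treatment_doses("A")
  fine <- cmax_tmax(p, d, grid_step = 0.01)
  expect_equal(unname(fine["tmax"]), 3.28, tolerance = 1e-2)
  expect_equal(unname(fine["cmax"]), 62.76, tolerance = 1e-3)
  hourly <- cmax_tmax(p, d, grid_step = 1)
  expect_lt(abs(hourly["tmax"] - fine["tmax"]), 1)
  expect_lte(hourly["cmax"], fine["cmax"])
  # near-bolus input declines from the first positive grid point
  pb <- p; pb$ka_im <- 500
  expect_equal(unname(cmax_tmax(pb, d, grid_step = 1)["tmax"]), 1)
})

test_that("95-96 h half-life matches the terminal exponent when pure", {
  # effectively one-compartment, near-instant absorption: terminal decline
  # at k10 by 95 h
  p <- pk_params(cl = 9, vp = 50, cld = 1e-8, vt = 1, ka_im = 50,
                 ka_po = 1, fr = 1)
  th <- thalf_95_96(p, treatment_doses("A"))
  expect_equal(th, log(2) / (9 / 50), tolerance = 1e-4)
  # BET-PA typicals: flip-flop terminal phase, frozen closed-form value
  expect_equal(thalf_95_96(bet_typical(), treatment_doses("C")), 93.27,
               tolerance = 1e-3)
  # still-rising profile has no defined terminal half-life
  expect_warning(
    th2 <- thalf_95_96(bet_typical(), dose_events(94, 6), t1 = 95, t2 = 96),
    "undefined")
  expect_true(is.na(th2))
})

test_that("absorption half-lives reproduce the published conversions", {
  expect_equal(round(absorption_half_life(0.936), 2), 0.74)
  expect_equal(round(absorption_half_life(1.21), 2), 0.57)
  expect_equal(round(absorption_half_life(0.460), 2), 1.51)
  expect_equal(round(absorption_half_life(0.971), 2), 0.71)
  expect_equal(round(absorption_half_life(0.00638)), 109)
  expect_equal(absorption_half_life(log(2)), 1)
})

test_that("mean residence time adds disposition and absorption times", {
  p <- dex_typical()
  expect_equal(mrt(p, "IM"), (51.3 + 5.06) / 9.29 + 1 / 0.46,
               tolerance = 1e-12)
  expect_equal(mrt(p, "IM"), 8.24, tolerance = 1e-3)
  # IV-bolus limit: huge ka leaves only the disposition residence time
  pfast <- p; pfast$ka_im <- 1e9
  expect_equal(mrt(pfast, "IM"), (p$vp + p$vt) / p$cl, tolerance = 1e-6)
  b <- bet_typical()
  expect_equal(mrt(b, "IM_PA"), 83.31, tolerance = 1e-3)
  expect_gte(mrt(b, "IM_PA"), (b$vp + b$vt) / b$cl)
  # the literal printed form is dimensionally inconsistent; kept only
  # behind the flag
  expect_equal(mrt(p, "IM", literal = TRUE),
               9.29 / (51.3 + 5.06) - 1 / 0.46, tolerance = 1e-12)
})

test_that("steady-state volume sums and weight normalization", {
  d <- vss_normalized(dex_typical(), 56.8)
  expect_equal(round(unname(d["vss"]), 1), 56.4)
  expect_equal(round(unname(d["cl_per_kg"]), 2), 0.16)
  expect_equal(round(unname(d["vss_per_kg"]), 2), 0.99)
  b <- vss_normalized(bet_typical(), 56.8)
  expect_equal(round(unname(b["vss"]), 1), 72.4)
  expect_equal(round(unname(b["cl_per_kg"]), 2), 0.10)
  expect_equal(round(unname(b["vss_per_kg"]), 2), 1.28)
  w1 <- vss_normalized(dex_typical(), 1)
  expect_equal(unname(w1["cl_per_kg"]), dex_typical()$cl)
})

test_that("orthogonal regression is symmetric and matches the eigenvector", {
  x <- seq(1, 10, 0.5)
  f <- orthogonal_slope(x, 2 * x)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  set.seed(8)
  cl_dex <- exp(rnorm(32, log(9.3), 0.17))
  cl_bet <- exp(log(cl_dex) * 0.8 + rnorm(32, -0.6, 0.12))
  a <- orthogonal_slope(cl_dex, cl_bet)
  b <- orthogonal_slope(cl_bet, cl_dex)
  expect_equal(a$slope, 1 / b$slope, tolerance = 1e-10)
  # eigen-decomposition oracle: major axis of the covariance ellipse
  S <- stats::cov(cbind(cl_dex, cl_bet))
  v <- eigen(S)$vectors[, 1]
  expect_equal(a$slope, v[2] / v[1], tolerance = 1e-10)
})

test_that("the descriptor table is coherent per treatment", {
  tab <- secondary_descriptors(bet_typical(), "C")
  expect_equal(tab$vss, bet_typical()$vp + bet_typical()$vt)
  expect_gte(tab$mrt, tab$vss / bet_typical()$cl)
  expect_lte(tab$auc_0_96, tab$auc_inf)
  expect_gte(tab$tmax, 0)
})
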