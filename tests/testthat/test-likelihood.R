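# Random-effects model, M3 censored likelihood, Laplace marginal
# likelihood and the population objective.

test_that("individual parameters follow the log-normal IIV model", {
  pop <- dex_population()
  expect_equal(unlist(individual_params(pop, c(0, 0, 0))),
               unlist(pop$theta))
  ip <- individual_params(pop, c(log(2), 0, 0))
  expect_equal(ip$cl, 2 * pop$theta$cl)
  expect_equal(ip$vp, pop$theta$vp)
  # log-normal median property: median over sampled etas ~ typical value
  set.seed(99)
  etas <- MASS::mvrnorm(1e5, rep(0, 3), pop$omega)
  cls <- pop$theta$cl * exp(etas[, 1])
  expect_equal(stats::median(cls), pop$theta$cl, tolerance = 0.01)
})

test_that("observation likelihood implements M3 censoring", {
  s2 <- 0.0455
  # BLQ with prediction at the LLOQ: exactly half the mass is censored
  expect_equal(obs_loglik(0.1, blq = TRUE, lloq = 0.1, sigma2 = s2),
               log(0.5))
  # prediction one residual-sd above the LLOQ on the log scale
  sd <- 0.2
  pred <- exp(log(0.1) + sd)
  expect_equal(obs_loglik(pred, blq = TRUE, lloq = 0.1, sigma2 = sd^2),
               stats::pnorm(-1, log.p = TRUE))
  expect_equal(exp(obs_loglik(pred, blq = TRUE, lloq = 0.1, sigma2 = sd^2)),
               0.1587, tolerance = 1e-3)
  # quantified record at the prediction: the density normalizing constant
  expect_equal(obs_loglik(5, dv = 5, sigma2 = s2),
               -0.5 * log(2 * pi * s2))
  expect_error(obs_loglik(5, dv = -1, sigma2 = s2), "positive observed")
})

test_that("censored probability is monotone and has the right limits", {
  s2 <- 0.04
  preds <- 10^seq(-8, 3, length.out = 40)
  ll <- obs_loglik(preds, blq = TRUE, lloq = 0.1, sigma2 = s2)
  p <- exp(ll)
  expect_true(all(diff(ll) <= 0))
  mid <- p > 1e-10 & p < 1 - 1e-10  # strictly decreasing off the
  expect_true(all(diff(ll[mid]) < 0))  # floating-point saturation zones
  expect_equal(p[1], 1, tolerance = 1e-6)
  expect_lt(p[length(p)], 1e-10)
})

test_that("Laplace equals the closed-form marginal for a log-linear model", {
  # a random effect on relative oral bioavailability scales the profile,
  # so log-concentration is exactly linear in eta: the marginal is an
  # exchangeable-normal closed form and Laplace must be exact
  p <- dex_typical()
  dat <- make_subject_data(seq(0.5, 96, 0.5), treatment_doses("D"), p,
                           seed = 12, sigma2 = 0.02, trt = "D")
  dat <- dat[dat$BLQ == 0, ]
  w2 <- 0.1
  s2 <- 0.02
  pop <- pop_params(p, c(fr = w2), s2, "fr")
  obs <- dat[dat$EVID == 0, ]
  m <- log(pk_profile(p, treatment_doses("D"), obs$TIME)$cp)
  r <- log(obs$DV) - m
  n <- length(r)
  Sig <- diag(s2, n) + w2
  ll_exact <- -0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(Sig)$modulus) +
                        drop(t(r) %*% solve(Sig, r)))
  lap <- laplace_subject_loglik(dat, pop)
  expect_true(lap$converged)
  expect_equal(lap$loglik, ll_exact, tolerance = 1e-9)
  # and agrees with adaptive quadrature
  expect_lt(abs(-2 * lap$loglik - -2 * quad_marginal(dat, pop)), 1e-6)
})

test_that("Laplace matches adaptive quadrature on 1- and 2-eta subjects", {
  p <- dex_typical()
  rich <- make_subject_data(seq(0.5, 96, 0.5), treatment_doses("A"), p,
                            seed = 11, sigma2 = 0.02)
  pop1 <- pop_params(p, c(cl = 0.04), 0.02, "cl")
  expect_lt(abs(-2 * laplace_subject_loglik(rich, pop1)$loglik -
                  -2 * quad_marginal(rich, pop1)), 1e-4)
  po <- make_subject_data(seq(0.5, 96, 0.5), treatment_doses("D"), p,
                          seed = 41, sigma2 = 0.005, trt = "D")
  pop2 <- pop_params(p, c(cl = 0.0265, fr = 0.0182), 0.005, c("cl", "fr"))
  expect_lt(abs(-2 * laplace_subject_loglik(po, pop2)$loglik -
                  -2 * quad_marginal(po, pop2)), 1e-4)
})

test_that("vanishing IIV reduces the marginal to the eta = 0 likelihood", {
  p <- dex_typical()
  dat <- make_subject_data(c(1, 2, 4, 8, 24, 48, 96), treatment_doses("A"),
                           p, seed = 5, sigma2 = 0.05)
  pop0 <- pop_params(p, c(cl = 1e-12), 0.05, "cl")
  obs <- dat[dat$EVID == 0, ]
  pred <- pk_profile(p, treatment_doses("A"), obs$TIME)$cp
  direct <- sum(obs_loglik(pred, obs$DV, obs$BLQ == 1, lloq = 0.1,
                           sigma2 = 0.05))
  expect_equal(laplace_subject_loglik(dat, pop0)$loglik, direct,
               tolerance = 1e-6)
})

test_that("the objective is additive over subjects and order-invariant", {
  study <- generate_study(design = study_design(n_per_sequence = 1),
                          seed = 21)
  dex <- drug_dataset(study, "DEX")
  pop <- dex_population()
  ids <- unique(dex$ID)
  total <- total_ofv(dex, pop)
  parts <- vapply(ids, function(id)
    as.numeric(total_ofv(dex[dex$ID == id, ], pop)), numeric(1))
  expect_equal(as.numeric(total), sum(parts), tolerance = 1e-8)
  # agreement with the quadrature-based OFV on a 1-eta model, 3 subjects
  pop1 <- pop_params(dex_typical(), c(cl = 0.0265), 0.0455, "cl")
  sub3 <- dex[dex$ID %in% ids[1:3], ]
  ofv_lap <- as.numeric(total_ofv(sub3, pop1))
  ofv_quad <- -2 * sum(vapply(ids[1:3], function(id)
    quad_marginal(dex[dex$ID == id, ], pop1), numeric(1)))
  # ~6e-4/subject is the Laplace approximation's own accuracy at the
  # study's sampling richness (implementation exactness is pinned down
  # by the sharper fixtures in this file)
  expect_lt(abs(ofv_lap - ofv_quad), 5e-3)
  shuffled <- dex[order(match(dex$ID, rev(ids)), dex$TIME, -dex$EVID), ]
  expect_equal(as.numeric(total_ofv(shuffled, pop)), as.numeric(total),
               tolerance = 1e-8)
})

test_that("inactive random effects are marginalized exactly", {
  # an IM-only subject carries no information about ka_po: including the
  # ka_po eta must not change the marginal likelihood
  p <- dex_typical()
  dat <- make_subject_data(c(1, 3, 6, 12, 24, 48), treatment_doses("A"), p,
                           seed = 31, sigma2 = 0.04)
  pop_a <- pop_params(p, c(cl = 0.03), 0.04, "cl")
  pop_b <- pop_params(p, c(cl = 0.03, ka_po = 0.4), 0.04, c("cl", "ka_po"))
  expect_equal(laplace_subject_loglik(dat, pop_a)$loglik,
               laplace_subject_loglik(dat, pop_b)$loglik, tolerance = 1e-8)
})
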