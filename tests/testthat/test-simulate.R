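# Population simulation, VPC construction, and regimen simulation.

test_that("simulation without variability returns the typical profile", {
  pop0 <- pop_params(dex_typical(), diag(0, 3), 0,
                     iiv = c("cl", "ka_im", "ka_po"))
  study <- generate_study(design = study_design(n_per_sequence = 1),
                          seed = 3)
  dex <- drug_dataset(study, "DEX")
  sim <- simulate_population(pop0, dex, seed = 1)
  s1 <- sim[sim$ID == sim$ID[1] & sim$EVID == 0, ]
  typ <- pk_profile(dex_typical(), treatment_doses(s1$TRT[1]), s1$TIME)$cp
  expect_equal(s1$.latent, typ, tolerance = 1e-12)
})

test_that("simulation is deterministic given the seed", {
  pop <- dex_population()
  study <- generate_study(design = study_design(n_per_sequence = 1),
                          seed = 3)
  dex <- drug_dataset(study, "DEX")
  expect_identical(simulate_population(pop, dex, seed = 42),
                   simulate_population(pop, dex, seed = 42))
})

test_that("log-concentration variance matches the delta method", {
  # small-IIV regime: Var(log C) ~ g' Omega g + sigma2 with g the
  # gradient of log C in eta
  pop <- dex_population()
  t_star <- 12
  doses <- treatment_doses("A")
  g <- vapply(seq_along(pop$iiv), function(k) {
    h <- 1e-4
    ep <- rep(0, 3); ep[k] <- h
    em <- rep(0, 3); em[k] <- -h
    (log(pk_profile(individual_params(pop, ep), doses, t_star)$cp) -
       log(pk_profile(individual_params(pop, em), doses, t_star)$cp)) /
      (2 * h)
  }, numeric(1))
  pred_var <- drop(t(g) %*% pop$omega %*% g) + pop$sigma2
  set.seed(14)
  n <- 3000
  etas <- MASS::mvrnorm(n, rep(0, 3), pop$omega)
  lc <- vapply(seq_len(n), function(i)
    log(pk_profile(individual_params(pop, etas[i, ]), doses, t_star)$cp),
    numeric(1)) + stats::rnorm(n, 0, sqrt(pop$sigma2))
  expect_equal(stats::var(lc), pred_var, tolerance = 0.1)
})

test_that("VPC construction behaves at its edges", {
  pop <- dex_population()
  study <- generate_study(design = study_design(n_per_sequence = 2),
                          seed = 5)
  dex <- drug_dataset(study, "DEX")
  # single replicate: bands collapse onto that replicate's percentiles
  v1 <- vpc(dex, pop, n_replicates = 1, seed = 9)
  expect_equal(v1$lo_p50, v1$hi_p50)
  expect_equal(v1$lo_p5, v1$hi_p5)
  # pre-dose bin is all BLQ: no numeric percentile, censored fraction 1
  predose <- v1[v1$bin == 0, ]
  expect_true(is.na(predose$obs_p50))
  expect_equal(predose$cens_frac, 1)
  # band ordering where defined
  v <- vpc(dex, pop, n_replicates = 50, seed = 9)
  ok <- !is.na(v$lo_p50)
  expect_true(all(v$lo_p50[ok] <= v$hi_p50[ok]))
  expect_true(all(v$lo_p5[ok] <= v$hi_p5[ok] + 1e-12))
})

test_that("VPC bands widen as IIV grows", {
  study <- generate_study(design = study_design(n_per_sequence = 2),
                          seed = 15)
  dex <- drug_dataset(study, "DEX")
  narrow <- dex_population()
  wide <- pop_params(narrow$theta, narrow$omega * 4, narrow$sigma2,
                     narrow$iiv)
  vn <- vpc(dex, narrow, n_replicates = 80, seed = 2)
  vw <- vpc(dex, wide, n_replicates = 80, seed = 2)
  mid <- which(vn$bin %in% c(6, 12, 24))
  spread_n <- vn$hi_p95[mid] - vn$lo_p5[mid]
  spread_w <- vw$hi_p95[mid] - vw$lo_p5[mid]
  expect_true(all(spread_w >= spread_n))
})

test_that("regimen schedules superpose single doses exactly", {
  reg <- who_regimens()$dex_p
  doses <- regimen_doses(reg)
  expect_equal(nrow(doses), 4)
  expect_equal(sum(doses$amount), 24)
  tt <- seq(0, 132, 0.5)
  p <- dex_typical()
  full <- pk_profile(p, doses, tt)$cp
  parts <- Reduce(`+`, lapply(doses$time, function(t0)
    pk_profile(p, dose_events(t0, 6), tt)$cp))
  expect_equal(full, parts, tolerance = 1e-12)
  # single administration reduces to the single-dose profile
  reg1 <- regimen("DEX", "P", 6, 12, 1)
  expect_equal(pk_profile(p, regimen_doses(reg1), tt)$cp,
               pk_profile(p, dose_events(0, 6), tt)$cp)
})

test_that("regimen metrics reproduce the analytic exposure identity", {
  reg <- who_regimens()$dex_p
  # eta = 0: total AUC to infinity is total absorbed dose / CL
  expect_equal(auc_inf(dex_typical(), regimen_doses(reg)), 24000 / 9.29,
               tolerance = 1e-12)
  expect_equal(auc_inf(dex_typical(), regimen_doses(reg)), 2583.4,
               tolerance = 1e-4)
  rs <- regimen_metrics(dex_population(), reg, n_subjects = 30, seed = 2)
  expect_equal(nrow(rs$metrics), 30)
  expect_true(all(rs$metrics$cmax >= rs$metrics$ctrough))
  expect_true(all(rs$metrics$auc_inf >= rs$metrics$auc_window))
  # median exposure in the neighbourhood of the typical-value identity
  expect_equal(rs$summary$median[rs$summary$metric == "auc_inf"],
               2583.4, tolerance = 0.15)
  # percentile band ordering everywhere
  expect_true(all(rs$profile$p5 <= rs$profile$median + 1e-12))
  expect_true(all(rs$profile$median <= rs$profile$p95 + 1e-12))
})

test_that("acetate flip-flop keeps late BET-PA troughs above BET-P", {
  regs <- who_regimens()
  tt <- seq(96, 240, 4)
  bp <- pk_profile(bet_typical(), regimen_doses(regs$bet_p), tt)$cp
  bpa <- pk_profile(bet_typical(), regimen_doses(regs$bet_pa), tt)$cp
  expect_true(all(bpa[tt > 150] > bp[tt > 150]))
  expect_gt(quantifiable_until(bet_population(), regs$bet_pa),
            quantifiable_until(bet_population(), regs$bet_p))
})
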