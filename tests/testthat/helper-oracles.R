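# Independent oracles and small fixture builders shared across tests.

# Adaptive ODE integration of the structural model (deSolve); the
# independent reference for the closed-form solution.
ode_oracle <- function(params, doses, times, rtol = 1e-10, atol = 1e-12) {
  ka <- c(params$ka_im, params$ka_po,
          if (is.null(params$ka_ima)) 1 else params$ka_ima)
  Fv <- c(1, params$fr, if (is.null(params$fra)) 1 else params$fra)
  depot_idx <- match(doses$depot, c("IM_PHOSPHATE", "ORAL", "IM_ACETATE"))
  deriv <- function(t, y, parms) {
    inp <- ka[1] * y[1] + ka[2] * y[2] + ka[3] * y[3]
    dcp <- (inp - (params$cl + params$cld) * y[4] + params$cld * y[5]) /
      params$vp
    dct <- params$cld * (y[4] - y[5]) / params$vt
    list(c(-ka[1] * y[1], -ka[2] * y[2], -ka[3] * y[3], dcp, dct))
  }
  evt <- data.frame(var = c("a1", "a2", "a3")[depot_idx],
                    time = doses$time,
                    value = 1000 * doses$amount * Fv[depot_idx],
                    method = "add")
  tt <- sort(unique(c(times, doses$time)))
  out <- deSolve::ode(c(a1 = 0, a2 = 0, a3 = 0, cp = 0, ct = 0), tt, deriv,
                      NULL, events = list(data = evt),
                      rtol = rtol, atol = atol)
  list(cp = out[match(times, out[, "time"]), "cp"],
       ct = out[match(times, out[, "time"]), "ct"])
}

# One-subject analysis dataset simulated from `params` (deterministic
# concentrations perturbed by log-normal noise), in the standard schema.
make_subject_data <- function(times, doses, params, seed, sigma2,
                              lloq = 0.1, drug = "DEX", trt = "A") {
  set.seed(seed)
  conc <- pk_profile(params, doses, times)$cp
  lat <- conc * exp(stats::rnorm(length(times), 0, sqrt(sigma2)))
  blq <- as.integer(lat < lloq)
  data.frame(ID = 1,
             TIME = c(doses$time, times),
             EVID = c(rep(1L, nrow(doses)), rep(0L, length(times))),
             AMT = c(doses$amount, rep(NA_real_, length(times))),
             CMT = c(doses$depot, rep(NA_character_, length(times))),
             DV = c(rep(NA_real_, nrow(doses)), ifelse(blq == 1, NA, lat)),
             MDV = c(rep(1L, nrow(doses)), rep(0L, length(times))),
             BLQ = c(rep(0L, nrow(doses)), blq),
             LLOQ = lloq, DRUG = drug, TRT = trt, SEQ = "AB", PERIOD = 1L,
             WT = 55, stringsAsFactors = FALSE)
}

# Marginal likelihood of one subject by mode-centred adaptive quadrature
# over the random effects (1 or 2 dimensions); the reference for the
# Laplace approximation. Returns the log marginal likelihood.
quad_marginal <- function(subject, pop, half = 8) {
  lap <- laplace_subject_loglik(subject, pop)
  ss <- dexbetpk:::.subject_struct(subject)
  ctx <- dexbetpk:::.lik_ctx(pop)
  ne <- length(pop$iiv)
  stopifnot(ne %in% 1:2)
  om <- dexbetpk:::.omega_sub(pop$omega, 0:(ne - 1))
  nj <- function(e) dexbetpk:::cpp_neg_joint_loglik(
    e, 0:(ne - 1), ctx$pmap, ctx$theta9, ss, om$oinv, om$ldet, ctx$sigma)
  mode <- unname(lap$eta)
  h <- 1e-3
  H <- matrix(0, ne, ne)
  f0 <- nj(mode)
  for (i in seq_len(ne)) {
    ep <- mode; ep[i] <- ep[i] + h
    em <- mode; em[i] <- em[i] - h
    H[i, i] <- (nj(ep) - 2 * f0 + nj(em)) / h^2
    if (i < ne) for (j in (i + 1):ne) {
      epp <- mode; epp[c(i, j)] <- epp[c(i, j)] + h
      epm <- mode; epm[i] <- epm[i] + h; epm[j] <- epm[j] - h
      emp <- mode; emp[i] <- emp[i] - h; emp[j] <- emp[j] + h
      emm <- mode; emm[c(i, j)] <- emm[c(i, j)] - h
      H[i, j] <- H[j, i] <- (nj(epp) - nj(epm) - nj(emp) + nj(emm)) /
        (4 * h^2)
    }
  }
  sds <- sqrt(diag(solve(H)))  # marginal posterior scales
  if (ne == 1) {
    f <- Vectorize(function(e) exp(-nj(e) - lap$loglik))
    q <- stats::integrate(f, mode - half * sds, mode + half * sds,
                          rel.tol = 1e-12)$value
  } else {
    inner <- function(x) stats::integrate(
      Vectorize(function(y) exp(-nj(c(x, y)) - lap$loglik)),
      mode[2] - half * sds[2], mode[2] + half * sds[2],
      rel.tol = 1e-10)$value
    q <- stats::integrate(Vectorize(inner),
                          mode[1] - half * sds[1], mode[1] + half * sds[1],
                          rel.tol = 1e-9)$value
  }
  lap$loglik + log(q)
}

# Relative discrepancy between a closed-form and an ODE profile, floored
# at 1e-6 of the peak: below that the ODE solution is absolute-tolerance
# noise (atol ~ 1e-12 on values spanning 15+ orders of magnitude) and a
# relative comparison is meaningless.
profile_rel_err <- function(cf, od) {
  max(abs(cf - od) / pmax(od, 1e-6 * max(od)))
}

# Random structurally valid parameter sets spanning both drugs' ranges.
random_params <- function(n, seed = 1, acetate = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      p <- try(pk_params(
        cl = stats::runif(1, 2, 20),
        vp = stats::runif(1, 20, 120),
        cld = stats::runif(1, 0.05, 5),
        vt = stats::runif(1, 1, 60),
        ka_im = stats::runif(1, 0.05, 3),
        ka_po = stats::runif(1, 0.05, 3),
        fr = stats::runif(1, 0.3, 1.5),
        ka_ima = if (acetate) stats::runif(1, 0.002, 0.5) else NULL,
        fra = if (acetate) stats::runif(1, 0.3, 1.2) else NULL),
        silent = TRUE)
      if (!inherits(p, "try-error")) return(p)
    }
  })
}
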