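# Population simulation, visual predictive checks, and dosing-regimen
# simulation.

#' Simulate a population dataset under a fitted/assumed model
#'
#' Replicates the design of an analysis dataset (same subjects, doses and
#' sampling times) under the population model: one random-effect vector
#' per subject from `omega`, log-scale residual error from `sigma2`, LLOQ
#' censoring as in the template. Fully reproducible from `seed`.
#'
#' @param pop A [pop_params].
#' @param data Template analysis dataset (one drug).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param residual Include residual error (`TRUE`, the observation model)
#'   or simulate the latent concentrations only.
#' @return Dataset of the same shape with new `DV`/`BLQ`/`.latent`.
#' @export
simulate_population <- function(pop, data, seed = NULL, residual = TRUE) {
  stopifnot(inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- data
  if (!".latent" %in% names(out)) out$.latent <- NA_real_
  for (id in unique(out$ID)) {
    rows <- which(out$ID == id)
    s <- .subject_struct(out[rows, ])
    eta <- as.numeric(MASS::mvrnorm(1, rep(0, length(pop$iiv)), pop$omega))
    ip <- individual_params(pop, eta)
    conc <- cpp_conc(s$obs_t, s$dose_t, s$dose_amt, s$dose_depot,
                     .p9_vector(ip))
    eps <- if (residual && pop$sigma2 > 0)
      stats::rnorm(length(conc), 0, sqrt(pop$sigma2)) else 0
    lat <- conc * exp(eps)
    obs_rows <- rows[out$EVID[rows] == 0]
    out$.latent[obs_rows] <- lat
    out$DV[obs_rows] <- lat
    out$BLQ[obs_rows] <- 0L
  }
  lloq <- unique(out$LLOQ[out$EVID == 0])[1]
  censor_lloq(out, lloq)
}

#' Visual predictive check
#'
#' Computes observed 5th/50th/95th percentiles of concentration per
#' nominal-time bin and simulation-based confidence bands for each
#' percentile: the design is re-simulated `n_replicates` times under
#' `pop`, each replicate's binned percentiles are collected, and the band
#' is the 2.5-97.5 percentile range of each. Values below the LLOQ
#' (observed and simulated alike) enter the percentile computation as
#' LLOQ/2, and the censored fraction is reported per bin; a bin that is
#' entirely BLQ gets no numeric percentile.
#'
#' @param observed Analysis dataset (one drug).
#' @param pop A [pop_params].
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer seed.
#' @param conf Band coverage (default 0.95).
#' @return Object of class `pk_vpc`: a data.frame with per-bin observed
#'   percentiles, band bounds, and censored fractions; attributes carry
#'   the LLOQ and settings.
#' @export
vpc <- function(observed, pop, n_replicates = 500, seed = 1, conf = 0.95) {
  stopifnot(n_replicates >= 1)
  obs <- observed[observed$EVID == 0, ]
  lloq <- unique(obs$LLOQ)[1]
  bins <- sort(unique(obs$TIME))
  probs <- c(0.05, 0.5, 0.95)

  binned_pct <- function(time, dv, blq) {
    val <- ifelse(blq == 1, lloq / 2, dv)
    t(vapply(bins, function(b) {
      i <- which(time == b)
      if (length(i) == 0 || all(blq[i] == 1))
        return(c(rep(NA_real_, 3), cens = if (length(i)) 1 else NA_real_))
      c(stats::quantile(val[i], probs, names = FALSE, type = 7),
        cens = mean(blq[i] == 1))
    }, numeric(4)))
  }

  ob <- binned_pct(obs$TIME, obs$DV, obs$BLQ)
  if (!is.null(seed)) set.seed(seed)
  sims <- array(NA_real_, dim = c(length(bins), 3, n_replicates))
  for (r in seq_len(n_replicates)) {
    sd_ <- simulate_population(pop, observed, seed = NULL)
    so <- sd_[sd_$EVID == 0, ]
    sims[, , r] <- binned_pct(so$TIME, so$DV, so$BLQ)[, 1:3]
  }
  a <- (1 - conf) / 2
  qs <- apply(sims, c(1, 2), function(z)
    if (all(is.na(z))) c(NA_real_, NA_real_)
    else stats::quantile(z, c(a, 1 - a), na.rm = TRUE, names = FALSE))
  out <- data.frame(
    bin = bins,
    obs_p5 = ob[, 1], obs_p50 = ob[, 2], obs_p95 = ob[, 3],
    lo_p5 = qs[1, , 1], hi_p5 = qs[2, , 1],
    lo_p50 = qs[1, , 2], hi_p50 = qs[2, , 2],
    lo_p95 = qs[1, , 3], hi_p95 = qs[2, , 3],
    cens_frac = ob[, 4])
  structure(out, class = c("pk_vpc", "data.frame"),
            lloq = lloq, n_replicates = n_replicates, conf = conf)
}

#' Fraction of observed percentile points inside their simulated bands
#'
#' @param v A [vpc] result.
#' @return Proportion in `[0, 1]` over all non-missing percentile points.
#' @export
vpc_coverage <- function(v) {
  stopifnot(inherits(v, "pk_vpc"))
  inside <- c(v$obs_p5 >= v$lo_p5 & v$obs_p5 <= v$hi_p5,
              v$obs_p50 >= v$lo_p50 & v$obs_p50 <= v$hi_p50,
              v$obs_p95 >= v$lo_p95 & v$obs_p95 <= v$hi_p95)
  mean(inside, na.rm = TRUE)
}

#' @export
plot.pk_vpc <- function(x, log = "y", ...) {
  lloq <- attr(x, "lloq")
  ok <- !is.na(x$obs_p50)
  ylim <- range(c(x$lo_p5[ok], x$hi_p95[ok], x$obs_p5[ok], x$obs_p95[ok]),
                na.rm = TRUE)
  if (grepl("y", log)) ylim[1] <- max(ylim[1], lloq / 4)
  graphics::plot(NA, xlim = range(x$bin), ylim = ylim, log = log,
                 xlab = "Time (h)", ylab = "Concentration (ng/mL)", ...)
  band <- function(lo, hi, col) {
    i <- ok & !is.na(lo) & !is.na(hi)
    graphics::polygon(c(x$bin[i], rev(x$bin[i])),
                      c(pmax(lo[i], ylim[1]), rev(pmax(hi[i], ylim[1]))),
                      col = col, border = NA)
  }
  band(x$lo_p5, x$hi_p5, grDevices::adjustcolor("steelblue", 0.3))
  band(x$lo_p95, x$hi_p95, grDevices::adjustcolor("steelblue", 0.3))
  band(x$lo_p50, x$hi_p50, grDevices::adjustcolor("firebrick", 0.3))
  graphics::lines(x$bin[ok], x$obs_p50[ok])
  graphics::lines(x$bin[ok], x$obs_p5[ok], lty = 2)
  graphics::lines(x$bin[ok], x$obs_p95[ok], lty = 2)
  graphics::abline(h = lloq, lty = 3)
  invisible(x)
}

# --- dosing regimens ------------------------------------------------------

#' Dosing regimens
#'
#' `regimen()` declares a repeated-dose schedule; `who_regimens()` returns
#' the three recommended antenatal corticosteroid regimens: DEX-P 6 mg IM
#' every 12 h x4, BET-P 12 mg IM every 24 h x2, and BET-PA 12 mg IM every
#' 24 h x2 (each administration half phosphate, half acetate). All three
#' total 24 mg.
#'
#' @param drug `"DEX"` or `"BET"`.
#' @param formulation `"P"` (phosphate solution) or `"PA"` (one-to-one
#'   phosphate/acetate suspension, BET only).
#' @param amount Dose per administration, mg.
#' @param interval Dosing interval, h.
#' @param n Number of administrations.
#' @return Object of class `pk_regimen`.
#' @export
regimen <- function(drug = c("DEX", "BET"), formulation = c("P", "PA"),
                    amount, interval, n) {
  drug <- match.arg(drug)
  formulation <- match.arg(formulation)
  if (drug == "DEX" && formulation == "PA")
    stop("no acetate formulation for DEX", call. = FALSE)
  if (amount <= 0 || interval <= 0 || n < 1)
    stop("need amount > 0, interval > 0, n >= 1", call. = FALSE)
  structure(list(drug = drug, formulation = formulation,
                 amount = amount, interval = interval, n = as.integer(n),
                 label = sprintf("%s-%s %g mg IM q%gh x%d", drug,
                                 formulation, amount, interval, n)),
            class = "pk_regimen")
}

#' @rdname regimen
#' @export
who_regimens <- function() {
  list(dex_p = regimen("DEX", "P", 6, 12, 4),
       bet_p = regimen("BET", "P", 12, 24, 2),
       bet_pa = regimen("BET", "PA", 12, 24, 2))
}

#' @rdname regimen
#' @param x A `pk_regimen`.
#' @return `regimen_doses()`: the `pk_doses` event table of the schedule.
#' @export
regimen_doses <- function(x) {
  stopifnot(inherits(x, "pk_regimen"))
  t0 <- (seq_len(x$n) - 1) * x$interval
  if (x$formulation == "PA")
    dose_events(rep(t0, each = 2), rep(x$amount / 2, 2 * x$n),
                rep(c("IM_PHOSPHATE", "IM_ACETATE"), x$n))
  else
    dose_events(t0, rep(x$amount, x$n), "IM_PHOSPHATE")
}

#' Simulate a dosing regimen
#'
#' Simulates `n_subjects` individual profiles under the regimen (hourly
#' grid by default) and summarizes Cmax, trough concentration at the end
#' of the last dosing interval, AUC over the window and to infinity, with
#' median and 5th/95th percentiles, plus the percentile band profile.
#' By default the bands reflect inter-individual variability only;
#' `residual = TRUE` adds the observation-level error.
#'
#' @param pop A [pop_params] for the regimen's drug.
#' @param reg A [regimen].
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed.
#' @param t_end End of the simulation window, h (default: last dose +
#'   96 h).
#' @param grid_step Grid spacing, h.
#' @param residual Add residual error to the band profiles.
#' @return List of class `pk_regimen_sim`: `metrics` (per-subject),
#'   `summary`, `profile` (time, median, p5, p95), `typical` (eta = 0
#'   profile), `regimen`.
#' @export
regimen_metrics <- function(pop, reg, n_subjects = 200, seed = 1,
                            t_end = NULL, grid_step = 1, residual = FALSE) {
  stopifnot(inherits(pop, "pop_params"), inherits(reg, "pk_regimen"))
  doses <- regimen_doses(reg)
  last_dose <- max(doses$time)
  if (is.null(t_end)) t_end <- last_dose + 96
  times <- seq(0, t_end, by = grid_step)
  if (!is.null(seed)) set.seed(seed)
  prof <- matrix(NA_real_, length(times), n_subjects)
  met <- data.frame(subject = seq_len(n_subjects), cmax = NA_real_,
                    tmax = NA_real_, ctrough = NA_real_,
                    auc_window = NA_real_, auc_inf = NA_real_)
  trough_t <- last_dose + reg$interval
  for (i in seq_len(n_subjects)) {
    eta <- as.numeric(MASS::mvrnorm(1, rep(0, length(pop$iiv)), pop$omega))
    ip <- individual_params(pop, eta)
    pr <- pk_profile(ip, doses, times)
    cp <- pr$cp
    if (residual && pop$sigma2 > 0)
      cp <- cp * exp(stats::rnorm(length(cp), 0, sqrt(pop$sigma2)))
    prof[, i] <- cp
    j <- which.max(pr$cp)
    met$cmax[i] <- pr$cp[j]
    met$tmax[i] <- times[j]
    met$ctrough[i] <- .conc_p9(.p9_vector(ip), doses, trough_t)
    met$auc_window[i] <- auc(pr)
    met$auc_inf[i] <- auc_inf(ip, doses)
  }
  qs <- function(z) stats::quantile(z, c(0.05, 0.5, 0.95), names = FALSE)
  summary_tab <- do.call(rbind, lapply(
    c("cmax", "ctrough", "auc_window", "auc_inf"), function(nm) {
      q <- qs(met[[nm]])
      data.frame(metric = nm, p5 = q[1], median = q[2], p95 = q[3])
    }))
  pq <- t(apply(prof, 1, qs))
  structure(list(
    metrics = met,
    summary = summary_tab,
    profile = data.frame(time = times, p5 = pq[, 1], median = pq[, 2],
                         p95 = pq[, 3]),
    typical = pk_profile(pop$theta, doses, times),
    regimen = reg), class = "pk_regimen_sim")
}

#' @export
print.pk_regimen_sim <- function(x, ...) {
  cat(x$regimen$label, "-", nrow(x$metrics), "simulated subjects\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Last time a typical-value profile stays quantifiable
#'
#' Scans an hourly grid and returns the last time at which the eta = 0
#' profile of the regimen is at or above the LLOQ.
#'
#' @param pop A [pop_params].
#' @param reg A [regimen].
#' @param lloq LLOQ, ng/mL.
#' @param t_max Scan horizon, h.
#' @return Time (h), or 0 if never quantifiable.
#' @export
quantifiable_until <- function(pop, reg, lloq = 0.1, t_max = 1000) {
  doses <- regimen_doses(reg)
  times <- seq(0, t_max, by = 1)
  cp <- pk_profile(pop$theta, doses, times)$cp
  i <- which(cp >= lloq)
  if (length(i) == 0) 0 else times[max(i)]
}
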