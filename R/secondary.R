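# Model-based secondary PK descriptors.

#' Area under the concentration-time curve
#'
#' `auc()` integrates a profile: exactly (per-exponential closed form)
#' when the profile was model-generated ([pk_profile] keeps its parameters
#' and doses), by the trapezoid rule otherwise. `auc_inf()` is the
#' analytic single/multiple-dose total exposure, absorbed amount / CL.
#'
#' @param profile A [pk_profile] (or any data.frame with `time`, `cp`).
#' @param method `"auto"` (exact when possible), `"exact"`, `"trapezoid"`.
#' @return AUC from the first to the last time of the profile, ng*h/mL.
#' @export
auc <- function(profile, method = c("auto", "exact", "trapezoid")) {
  method <- match.arg(method)
  params <- attr(profile, "params")
  doses <- attr(profile, "doses")
  exact_possible <- !is.null(params) && !is.null(doses)
  if (method == "exact" && !exact_possible)
    stop("exact AUC needs a model-generated profile", call. = FALSE)
  if (method == "trapezoid" || !exact_possible) {
    t <- profile$time
    c <- profile$cp
    return(sum(diff(t) * (utils::head(c, -1) + c[-1]) / 2))
  }
  .auc_exact(params, doses, min(profile$time), max(profile$time))
}

# closed-form AUC(t0, t1) by integrating each dose's tri-exponential
.auc_exact <- function(params, doses, t0, t1) {
  d <- disposition_constants(params)
  p9 <- .p9_vector(params)
  total <- 0
  for (j in seq_len(nrow(doses))) {
    depot <- .DEPOTS[[doses$depot[j]]]
    ka <- switch(depot + 1L, p9[5], p9[6], p9[7])
    F <- switch(depot + 1L, 1, p9[8], p9[9])
    if (abs(ka - d$alpha) < 1e-9 * d$alpha) ka <- d$alpha * (1 + 1e-7)
    if (abs(ka - d$beta) < 1e-9 * d$beta) ka <- d$beta * (1 + 1e-7)
    a0 <- 1000 * doses$amount[j] * F
    co <- c((d$k21 - d$alpha) / ((ka - d$alpha) * (d$beta - d$alpha)),
            (d$k21 - d$beta) / ((ka - d$beta) * (d$alpha - d$beta)),
            (d$k21 - ka) / ((d$alpha - ka) * (d$beta - ka)))
    lam <- c(d$alpha, d$beta, ka)
    lo <- max(t0, doses$time[j]) - doses$time[j]
    hi <- t1 - doses$time[j]
    if (hi <= 0) next
    total <- total + a0 * ka / params$vp *
      sum(co / lam * (exp(-lam * lo) - exp(-lam * hi)))
  }
  total
}

#' @rdname auc
#' @param params A [pk_params] object.
#' @param doses A `pk_doses` table.
#' @export
auc_inf <- function(params, doses) {
  p9 <- .p9_vector(params)
  Fv <- c(1, p9[8], p9[9])[.DEPOTS[doses$depot] + 1L]
  sum(1000 * doses$amount * Fv) / params$cl
}

#' Peak concentration and peak time on a simulation grid
#'
#' Simulates the profile on a regular grid (default 1 h, the reporting
#' convention) and takes the maximum; ties broken by the earliest time.
#'
#' @param params A [pk_params].
#' @param doses A `pk_doses` table.
#' @param grid_step Grid spacing, h.
#' @param t_end End of the grid, h.
#' @return Named vector `c(cmax = , tmax = )` (ng/mL, h).
#' @export
cmax_tmax <- function(params, doses, grid_step = 1, t_end = 96) {
  times <- seq(0, t_end, by = grid_step)
  cp <- .conc_p9(.p9_vector(params), doses, times)
  i <- which.max(cp)  # which.max returns the first maximum
  c(cmax = cp[i], tmax = times[i])
}

#' Terminal half-life from the 95 and 96 h points
#'
#' The reporting convention for these profiles:
#' `t1/2 = log(2) / log(Cp(95) / Cp(96))` per hour of decline. A profile
#' still rising at 95-96 h has no defined terminal half-life and yields
#' `NA` with a warning.
#'
#' @inheritParams cmax_tmax
#' @param t1,t2 The two evaluation times (h).
#' @return Half-life, h (or `NA` if undefined).
#' @export
thalf_95_96 <- function(params, doses, t1 = 95, t2 = 96) {
  cp <- .conc_p9(.p9_vector(params), doses, c(t1, t2))
  if (cp[1] <= cp[2] || cp[2] <= 0) {
    warning("concentration not declining over the window; half-life undefined",
            call. = FALSE)
    return(NA_real_)
  }
  log(2) * (t2 - t1) / log(cp[1] / cp[2])
}

#' Absorption half-life
#'
#' @param ka First-order absorption rate constant(s), 1/h.
#' @return `log(2) / ka`, h.
#' @examples
#' absorption_half_life(0.936) # 0.74 h
#' @export
absorption_half_life <- function(ka) {
  if (any(ka <= 0)) stop("ka must be positive", call. = FALSE)
  log(2) / ka
}

#' Mean residence time
#'
#' Disposition residence time plus mean absorption time:
#' `MRT = (Vss/F)/(CL/F) + 1/ka`, with the absorbed-fraction-weighted
#' composite ka ([composite_ka]) for the phosphate/acetate suspension.
#' `literal = TRUE` evaluates the dimensionally inconsistent form
#' `(CL/F)/(Vss/F) - 1/ka` instead (kept only for comparison; do not use).
#'
#' @param params A [pk_params].
#' @param route `"IM"`, `"PO"`, or `"IM_PA"` (phosphate + acetate).
#' @param literal Evaluate the inconsistent textbook-printed variant.
#' @return MRT, h.
#' @examples
#' mrt(dex_typical(), "IM") # 8.24 h
#' @export
mrt <- function(params, route = c("IM", "PO", "IM_PA"), literal = FALSE) {
  route <- match.arg(route)
  ka <- switch(route,
    IM = params$ka_im,
    PO = params$ka_po,
    IM_PA = {
      if (is.null(params$ka_ima))
        stop("no acetate depot in these parameters", call. = FALSE)
      composite_ka(c(1, params$fra), c(params$ka_im, params$ka_ima))
    })
  vss <- params$vp + params$vt
  if (literal) return(params$cl / vss - 1 / ka)
  vss / params$cl + 1 / ka
}

#' Steady-state volume and per-kilogram normalizations
#'
#' @param params A [pk_params].
#' @param body_weight_kg Body weight used for normalization (the study
#'   mean was 56.8 kg).
#' @return Named vector: `vss` (L), `cl_per_kg` (L/h/kg), `vss_per_kg`
#'   (L/kg).
#' @export
vss_normalized <- function(params, body_weight_kg = 56.8) {
  if (body_weight_kg <= 0) stop("weight must be positive", call. = FALSE)
  vss <- params$vp + params$vt
  c(vss = vss, cl_per_kg = params$cl / body_weight_kg,
    vss_per_kg = vss / body_weight_kg)
}

#' Orthogonal (total) least-squares slope
#'
#' Slope of the first principal axis of the centred scatter — the
#' orthogonal least-squares line through the centroid — plus the squared
#' Pearson correlation. Used to compare per-subject clearances of the two
#' drugs; unlike ordinary regression it treats x and y symmetrically
#' (swapping them inverts the slope).
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
orthogonal_slope <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0 && sxx == syy)
    stop("degenerate scatter: orthogonal slope undefined", call. = FALSE)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  if (sxy == 0) slope <- if (syy > sxx) Inf else 0
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = stats::cor(x, y)^2)
}

#' Secondary descriptor table for one treatment
#'
#' Population-typical Cmax/tmax (1 h grid to 96 h), AUC to 96 h and to
#' infinity, terminal half-life from 95-96 h, MRT, Vss and per-kg values.
#'
#' @param params A [pk_params].
#' @param treatment Treatment code `"A"`-`"E"` (see [treatment_doses]).
#' @param body_weight_kg Normalization weight.
#' @param grid_step Simulation grid for Cmax/tmax, h.
#' @return One-row data.frame.
#' @export
secondary_descriptors <- function(params, treatment,
                                  body_weight_kg = 56.8, grid_step = 1) {
  doses <- treatment_doses(treatment)
  route <- switch(treatment, A = , B = "IM", C = "IM_PA", D = , E = "PO")
  cm <- cmax_tmax(params, doses, grid_step = grid_step)
  pr <- pk_profile(params, doses, seq(0, 96, by = 1))
  vn <- vss_normalized(params, body_weight_kg)
  data.frame(treatment = treatment,
             label = attr(doses, "label"),
             cmax = unname(cm["cmax"]), tmax = unname(cm["tmax"]),
             auc_0_96 = auc(pr), auc_inf = auc_inf(params, doses),
             t_half_95_96 = suppressWarnings(thalf_95_96(params, doses)),
             mrt = mrt(params, route),
             vss = unname(vn["vss"]),
             cl_per_kg = unname(vn["cl_per_kg"]),
             vss_per_kg = unname(vn["vss_per_kg"]))
}
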