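# Structural and population parameter containers.

# canonical parameter order used throughout (and by the compiled code)
.P9 <- c("cl", "vp", "cld", "vt", "ka_im", "ka_po", "ka_ima", "fr", "fra")
.DEPOTS <- c(IM_PHOSPHATE = 0L, ORAL = 1L, IM_ACETATE = 2L)

#' Structural pharmacokinetic parameters
#'
#' Fixed-effect parameters of the two-compartment disposition model with
#' route/formulation-specific first-order absorption. All clearances and
#' volumes are apparent (scaled by the unidentified IM bioavailability
#' `F_IM`). Betamethasone instances carry a third depot (IM acetate) with
#' its own absorption rate `ka_ima` and relative bioavailability `fra`;
#' dexamethasone instances omit both.
#'
#' @param cl Apparent clearance CL/F (L/h).
#' @param vp Apparent central volume Vp/F (L).
#' @param cld Apparent distributional clearance CLD/F (L/h).
#' @param vt Apparent peripheral volume VT/F (L).
#' @param ka_im First-order absorption rate after IM phosphate dosing (1/h).
#' @param ka_po First-order absorption rate after oral dosing (1/h).
#' @param fr Relative oral bioavailability F_PO/F_IM.
#' @param ka_ima Absorption/hydrolysis rate of the IM acetate depot (1/h),
#'   or `NULL` for a drug without an acetate formulation.
#' @param fra Relative acetate bioavailability F_IMa/F_IM, or `NULL`.
#' @return An object of class `pk_params` (a named list).
#' @examples
#' p <- pk_params(cl = 9.29, vp = 51.3, cld = 0.538, vt = 5.06,
#'                ka_im = 0.46, ka_po = 0.936, fr = 1.04)
#' disposition_constants(p)
#' @export
pk_params <- function(cl, vp, cld, vt, ka_im, ka_po, fr,
                      ka_ima = NULL, fra = NULL) {
  x <- list(cl = cl, vp = vp, cld = cld, vt = vt,
            ka_im = ka_im, ka_po = ka_po, fr = fr)
  if (!is.null(ka_ima) || !is.null(fra)) {
    if (is.null(ka_ima) || is.null(fra))
      stop("`ka_ima` and `fra` must be supplied together", call. = FALSE)
    x$ka_ima <- ka_ima
    x$fra <- fra
  }
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals <= 0) || cld < 0)
    stop("all structural parameters must be finite and strictly positive",
         call. = FALSE)
  structure(x, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Structural PK parameters (apparent, /F):\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

# full length-9 vector for the compiled code; unused depot slots get
# harmless positive placeholders (they are never dosed)
.p9_vector <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  c(params$cl, params$vp, params$cld, params$vt,
    params$ka_im, params$ka_po,
    if (is.null(params$ka_ima)) 1 else params$ka_ima,
    params$fr,
    if (is.null(params$fra)) 1 else params$fra)
}

.params_from_p9 <- function(p9, has_acetate) {
  if (has_acetate)
    pk_params(cl = p9[1], vp = p9[2], cld = p9[3], vt = p9[4],
              ka_im = p9[5], ka_po = p9[6], fr = p9[8],
              ka_ima = p9[7], fra = p9[9])
  else
    pk_params(cl = p9[1], vp = p9[2], cld = p9[3], vt = p9[4],
              ka_im = p9[5], ka_po = p9[6], fr = p9[8])
}

#' Disposition micro-constants and exponents
#'
#' Reparameterizes clearances/volumes into the micro-rate constants
#' `k10 = CL/Vp`, `k12 = CLD/Vp`, `k21 = CLD/VT` and the bi-exponential
#' disposition exponents `alpha > beta`, the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21`.
#'
#' @param params A [pk_params] object.
#' @return Named list with `k10`, `k12`, `k21`, `alpha`, `beta` (1/h).
#' @examples
#' d <- disposition_constants(dex_typical())
#' log(2) / d$beta  # terminal disposition half-life, h
#' @export
disposition_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  k10 <- params$cl / params$vp
  k12 <- params$cld / params$vp
  k21 <- params$cld / params$vt
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Absorbed-fraction-weighted composite absorption rate
#'
#' Harmonic mean of depot absorption rate constants weighted by the
#' absorbed fractions: `sum(w) / sum(w / ka)`. For the one-to-one
#' phosphate/acetate IM suspension the phosphate depot carries weight 1
#' (all bioavailabilities are expressed relative to IM phosphate) and the
#' acetate depot weight `fra`. The mean absorption time is
#' `MAT = 1 / composite_ka(...)`.
#'
#' @param weights Non-negative absorbed-fraction weights, not all zero.
#' @param kas Positive absorption rate constants, same length (1/h).
#' @return Composite absorption rate constant (1/h).
#' @examples
#' b <- bet_typical()
#' 1 / composite_ka(c(1, b$fra), c(b$ka_im, b$ka_ima))  # MAT, h
#' @export
composite_ka <- function(weights, kas) {
  if (length(weights) != length(kas))
    stop("`weights` and `kas` must have the same length", call. = FALSE)
  if (any(weights < 0) || any(kas <= 0))
    stop("weights must be >= 0 and rate constants > 0", call. = FALSE)
  if (sum(weights) == 0)
    stop("total weight is zero", call. = FALSE)
  sum(weights) / sum(weights / kas)
}

#' Published typical parameter values
#'
#' Typical (population) structural parameter values for dexamethasone and
#' betamethasone after IM/PO dosing in healthy nonpregnant women, and the
#' corresponding population objects carrying inter-individual variability
#' and residual error. `dex_population()` places log-normal random effects
#' on CL/F, ka_im and ka_po (the central-volume variability was estimated
#' at zero and is fixed there); `bet_population()` on CL/F, Vp/F, ka_im,
#' ka_ima, ka_po, fr and fra with a CL-Vp covariance.
#'
#' @return `dex_typical()`/`bet_typical()`: a [pk_params] object;
#'   `dex_population()`/`bet_population()`: a [pop_params] object.
#' @export
dex_typical <- function() {
  pk_params(cl = 9.29, vp = 51.3, cld = 0.538, vt = 5.06,
            ka_im = 0.460, ka_po = 0.936, fr = 1.04)
}

#' @rdname dex_typical
#' @export
bet_typical <- function() {
  pk_params(cl = 5.95, vp = 67.5, cld = 0.173, vt = 4.94,
            ka_im = 0.971, ka_po = 1.21, fr = 0.935,
            ka_ima = 0.00638, fra = 0.819)
}

#' Population parameters
#'
#' Couples typical structural values with the random-effects model: each
#' parameter named in `iiv` receives a multiplicative log-normal random
#' effect `P_i = theta_P * exp(eta_i)`, `eta ~ N(0, omega)`; observed
#' log-concentrations carry additive residual error with variance `sigma2`.
#'
#' @param theta A [pk_params] object of typical values.
#' @param omega Variance-covariance matrix of the log-scale random effects
#'   (dimension = `length(iiv)`), or a vector of variances for a diagonal
#'   omega.
#' @param sigma2 Residual variance on the natural-log concentration scale.
#' @param iiv Character vector naming the structural parameters that carry
#'   a random effect (subset of `names(theta)`).
#' @return Object of class `pop_params`.
#' @export
pop_params <- function(theta, omega, sigma2, iiv) {
  stopifnot(inherits(theta, "pk_params"))
  if (!all(iiv %in% names(theta)))
    stop("`iiv` names parameters absent from `theta`", call. = FALSE)
  if (is.vector(omega) && !is.matrix(omega)) omega <- diag(omega, length(omega))
  omega <- as.matrix(omega)
  if (nrow(omega) != length(iiv) || ncol(omega) != length(iiv))
    stop("omega dimension must match length(iiv)", call. = FALSE)
  if (max(abs(omega - t(omega))) > 1e-10)
    stop("omega must be symmetric", call. = FALSE)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("omega must be positive semi-definite", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 < 0)
    stop("sigma2 must be non-negative", call. = FALSE)
  dimnames(omega) <- list(iiv, iiv)
  structure(list(theta = theta, omega = omega, sigma2 = sigma2, iiv = iiv),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters\n\nTypical values:\n")
  print(round(unlist(x$theta), 4))
  cat("\nIIV variance-covariance (log scale):\n")
  print(round(x$omega, 4))
  cat(sprintf("\nResidual variance (log scale): %.4g  (CV%% %.1f)\n",
              x$sigma2, cv_percent(x$sigma2)))
  invisible(x)
}

#' @rdname dex_typical
#' @export
dex_population <- function() {
  pop_params(dex_typical(),
             omega = c(cl = 0.0265, ka_im = 0.0633, ka_po = 0.395),
             sigma2 = 0.0455,
             iiv = c("cl", "ka_im", "ka_po"))
}

#' @rdname dex_typical
#' @export
bet_population <- function() {
  iiv <- c("cl", "vp", "ka_im", "ka_ima", "ka_po", "fr", "fra")
  om <- diag(c(0.0210, 0.0188, 0.0441, 0.147, 0.241, 0.0182, 0.00773))
  om[1, 2] <- om[2, 1] <- 0.0155
  pop_params(bet_typical(), om, sigma2 = 0.0211, iiv = iiv)
}

#' Individual parameters from typical values and random effects
#'
#' Applies the log-normal IIV model: every parameter with a random effect
#' is multiplied by `exp(eta)`; the rest are unchanged.
#'
#' @param pop A [pop_params] object (or a [pk_params] theta together with
#'   `iiv`).
#' @param eta Named or positional vector of random effects, one per entry
#'   of `pop$iiv`.
#' @return A [pk_params] object of individual parameters.
#' @export
individual_params <- function(pop, eta) {
  stopifnot(inherits(pop, "pop_params"))
  if (length(eta) != length(pop$iiv))
    stop("eta dimension does not match the IIV map", call. = FALSE)
  th <- pop$theta
  for (k in seq_along(pop$iiv)) {
    nm <- pop$iiv[k]
    th[[nm]] <- th[[nm]] * exp(eta[[k]])
  }
  class(th) <- "pk_params"
  th
}

#' Log-normal variance as a coefficient of variation
#'
#' Converts a log-scale variance `omega2` to the coefficient of variation
#' of the implied log-normal distribution, `100 * sqrt(exp(omega2) - 1)`,
#' the convention used to report inter-individual variability.
#'
#' @param omega2 Log-scale variance(s), >= 0.
#' @return CV in percent.
#' @examples
#' cv_percent(0.0265) # 16.4
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("variance must be non-negative", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-square probability of a drop in objective function value
#' (-2 log-likelihood) between nested models.
#'
#' @param delta_ofv Non-negative OFV difference.
#' @param df Degrees of freedom (number of added parameters).
#' @return p-value.
#' @examples
#' lrt_pvalue(5.5, 1) # 0.019
#' @export
lrt_pvalue <- function(delta_ofv, df) {
  if (any(delta_ofv < 0)) stop("delta_ofv must be >= 0", call. = FALSE)
  stats::pchisq(delta_ofv, df = df, lower.tail = FALSE)
}
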