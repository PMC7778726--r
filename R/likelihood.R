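# Observation likelihood (M3), Laplace marginal likelihood, and the
# population objective function.

#' Log-likelihood contribution of one observation (M3 for BLQ)
#'
#' Quantified records contribute a normal density on the log scale:
#' `dnorm(log(dv), log(pred_cp), sqrt(sigma2), log = TRUE)`. Records below
#' the limit of quantification contribute the censored-normal probability
#' `log(Phi((log(lloq) - log(pred_cp)) / sqrt(sigma2)))` (the Beal M3
#' correction). Predictions are floored at 1e-12 ng/mL before logging so
#' pre-dose records are handled without -Inf.
#'
#' @param pred_cp Model-predicted concentration(s), ng/mL.
#' @param dv Observed concentration(s); ignored (may be `NA`) where
#'   `blq` is `TRUE`.
#' @param blq Logical flag(s): is the record below the LLOQ?
#' @param lloq Lower limit of quantification (ng/mL).
#' @param sigma2 Residual variance on the log scale.
#' @return Log-likelihood contribution(s).
#' @examples
#' obs_loglik(0.1, blq = TRUE, lloq = 0.1, sigma2 = 0.04)  # log(0.5)
#' @export
obs_loglik <- function(pred_cp, dv = NA_real_, blq = FALSE,
                       lloq = 0.1, sigma2) {
  if (missing(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be a positive residual variance", call. = FALSE)
  n <- max(length(pred_cp), length(dv), length(blq))
  pred_cp <- rep_len(pred_cp, n)
  dv <- rep_len(dv, n)
  blq <- rep_len(as.logical(blq), n)
  if (any(!blq & (!is.finite(dv) | dv <= 0)))
    stop("quantified records need a positive observed concentration",
         call. = FALSE)
  sd <- sqrt(sigma2)
  lc <- log(pmax(pred_cp, 1e-12))
  out <- numeric(n)
  out[blq] <- stats::pnorm((log(lloq) - lc[blq]) / sd, log.p = TRUE)
  out[!blq] <- stats::dnorm(log(dv[!blq]), lc[!blq], sd, log = TRUE)
  out
}

# ---------------------------------------------------------------------------
# internal model bookkeeping

# pmap: for each of the 9 canonical parameters, 0-based index of its random
# effect in pop$iiv, or -1
.pmap <- function(pop) {
  m <- match(.P9, pop$iiv)
  ifelse(is.na(m), -1L, m - 1L)
}

# 0-based indices of the etas that can influence this subject's predictions
.active_etas <- function(pop, depots_present) {
  relevant <- vapply(pop$iiv, function(nm) {
    switch(nm,
      ka_im = 0L %in% depots_present,
      ka_po = ,
      fr    = 1L %in% depots_present,
      ka_ima = ,
      fra   = 2L %in% depots_present,
      TRUE)
  }, logical(1))
  act <- which(relevant)
  # marginalizing over inactive etas separately is exact only if they are
  # uncorrelated with the active ones; otherwise keep the full set
  if (length(act) < length(pop$iiv)) {
    inact <- setdiff(seq_along(pop$iiv), act)
    if (any(pop$omega[act, inact, drop = FALSE] != 0))
      act <- seq_along(pop$iiv)
  }
  as.integer(act - 1L)
}

.omega_sub <- function(omega, act0) {
  idx <- act0 + 1L
  om <- omega[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(ch)) stop("omega is not positive definite on the active block",
                        call. = FALSE)
  list(oinv = chol2inv(ch), ldet = 2 * sum(log(diag(ch))))
}

# C++-ready per-subject structure from analysis-dataset rows
.subject_struct <- function(rows) {
  isdose <- rows$EVID == 1
  obs <- rows[!isdose, , drop = FALSE]
  dose <- rows[isdose, , drop = FALSE]
  if (nrow(obs) == 0) stop("subject has no observations", call. = FALSE)
  blq <- as.integer(obs$BLQ == 1)
  logdv <- ifelse(blq == 1, 0, log(obs$DV))
  lloq <- unique(obs$LLOQ[is.finite(obs$LLOQ)])
  if (length(lloq) != 1) lloq <- lloq[1]
  list(obs_t = obs$TIME, obs_logdv = as.numeric(logdv), obs_blq = blq,
       dose_t = dose$TIME, dose_amt = dose$AMT,
       dose_depot = unname(.DEPOTS[dose$CMT]),
       lloq = as.numeric(lloq),
       id = rows$ID[1])
}

.subject_list <- function(data) {
  stopifnot(is.data.frame(data))
  lapply(split(data, factor(data$ID, levels = unique(data$ID))),
         .subject_struct)
}

# shared setup for likelihood evaluation over a prepared subject list
.lik_ctx <- function(pop) {
  pm <- .pmap(pop)
  cache <- new.env(parent = emptyenv())
  omega_for <- function(act0) {
    key <- paste0("k", paste(act0, collapse = ","))
    if (is.null(cache[[key]])) cache[[key]] <- .omega_sub(pop$omega, act0)
    cache[[key]]
  }
  list(pmap = pm, theta9 = .p9_vector(pop$theta),
       sigma = sqrt(pop$sigma2), omega_for = omega_for)
}

#' Laplace marginal log-likelihood of one subject
#'
#' Finds the mode of the joint log-likelihood of the subject's data and
#' random effects by damped Newton ascent (central finite-difference
#' gradients/Hessians, gradient tolerance 1e-8) starting from `eta = 0`,
#' and applies the Laplace approximation
#' `loglik = joint(mode) + p/2 log(2*pi) - 1/2 log det H` where `H` is the
#' curvature of the negative joint log-likelihood at the mode. Random
#' effects whose parameter cannot influence the subject's predictions
#' (e.g. an oral absorption rate for a subject dosed only IM) are
#' marginalized exactly and excluded from the optimization when they are
#' uncorrelated with the active effects.
#'
#' @param subject One subject's rows of an analysis dataset (see
#'   [read_pk_dataset]) or a prepared subject structure.
#' @param pop A [pop_params] object.
#' @param eta_start Optional warm start for the mode search (full eta
#'   dimension).
#' @return List with `loglik`, empirical-Bayes `eta` (full dimension,
#'   named), `converged`, `iterations`, `grad_norm`.
#' @export
laplace_subject_loglik <- function(subject, pop, eta_start = NULL) {
  stopifnot(inherits(pop, "pop_params"))
  if (is.data.frame(subject)) subject <- .subject_struct(subject)
  ctx <- .lik_ctx(pop)
  act <- .active_etas(pop, unique(subject$dose_depot))
  om <- ctx$omega_for(act)
  if (is.null(eta_start)) eta_start <- numeric(length(pop$iiv))
  res <- cpp_laplace_subject(eta_start[act + 1L], act, ctx$pmap, ctx$theta9,
                             subject, om$oinv, om$ldet, ctx$sigma)
  eta_full <- stats::setNames(numeric(length(pop$iiv)), pop$iiv)
  eta_full[act + 1L] <- res$eta
  list(loglik = res$loglik, eta = eta_full, converged = res$converged,
       iterations = res$iterations, grad_norm = res$grad_norm)
}

#' Population objective function value
#'
#' Minus twice the sum of per-subject Laplace marginal log-likelihoods.
#' This is the quantity minimized by [pk_fit] and compared between nested
#' models with [lrt_pvalue]; it is additive over subjects.
#'
#' @param data Analysis dataset (one drug; see [read_pk_dataset]).
#' @param pop A [pop_params] object.
#' @param warm Optional environment holding an `eta` matrix (n_eta x
#'   n_subjects) of warm starts; updated in place with the new modes.
#' @return OFV (scalar). Attribute `n_nonconverged` counts subjects whose
#'   inner mode search did not meet tolerance.
#' @export
total_ofv <- function(data, pop, warm = NULL) {
  subs <- if (is.list(data) && !is.data.frame(data)) data else .subject_list(data)
  ctx <- .lik_ctx(pop)
  neta <- length(pop$iiv)
  if (!is.null(warm) && is.null(warm$eta))
    warm$eta <- matrix(0, neta, length(subs))
  ll <- 0
  bad <- 0L
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    act <- .active_etas(pop, unique(s$dose_depot))
    om <- ctx$omega_for(act)
    e0 <- if (is.null(warm)) numeric(length(act)) else warm$eta[act + 1L, i]
    res <- cpp_laplace_subject(e0, act, ctx$pmap, ctx$theta9, s,
                               om$oinv, om$ldet, ctx$sigma)
    if (!res$converged) bad <- bad + 1L
    if (!is.null(warm)) {
      warm$eta[, i] <- 0
      warm$eta[act + 1L, i] <- res$eta
    }
    ll <- ll + res$loglik
  }
  structure(-2 * ll, n_nonconverged = bad)
}
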