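# Population fitting: Laplace marginal likelihood minimized over
# log-transformed typical values, a log-Cholesky omega, and log sigma2.

#' Fitting control
#'
#' @param iter_max,eval_max Outer optimizer (PORT/`nlminb`) limits.
#' @param rel_tol Outer relative convergence tolerance.
#' @param inner_grad_tol Gradient tolerance of the inner (eta) mode search.
#' @param se Compute standard errors from the numerically differentiated
#'   OFV Hessian after fitting.
#' @param polish After the line-search optimizer stops, run up to
#'   `polish_iter` damped Newton steps on the numerically differentiated
#'   OFV until its gradient max-norm falls below `polish_tol`; PORT often
#'   reports false convergence on this objective a little short of the
#'   stationary point.
#' @param polish_iter,polish_tol Polish phase limits.
#' @return List of control settings.
#' @export
pk_control <- function(iter_max = 400, eval_max = 2000, rel_tol = 1e-8,
                       inner_grad_tol = 1e-8, se = TRUE,
                       polish = TRUE, polish_iter = 4, polish_tol = 0.1) {
  list(iter_max = iter_max, eval_max = eval_max, rel_tol = rel_tol,
       inner_grad_tol = inner_grad_tol, se = se, polish = polish,
       polish_iter = polish_iter, polish_tol = polish_tol)
}

# --- model structure ------------------------------------------------------

# which structural parameters exist / carry IIV for each drug (the final
# published models); users can override `iiv` in pk_fit()
.default_iiv <- function(drug) {
  if (drug == "DEX") c("cl", "ka_im", "ka_po")
  else c("cl", "vp", "ka_im", "ka_ima", "ka_po", "fr", "fra")
}

.theta_names <- function(drug) {
  if (drug == "DEX") c("cl", "vp", "cld", "vt", "ka_im", "ka_po", "fr")
  else .P9
}

# --- packing: unconstrained vector <-> pop_params -------------------------

# omega parameterization: log-sd for each independent eta; the optional
# correlated cl-vp block is a 2x2 log-Cholesky (log L11, L21, log L22)
.pack <- function(pop, drug, cov_cl_vp) {
  tn <- .theta_names(drug)
  th <- log(unlist(pop$theta)[tn])
  names(th) <- paste0("log_", tn)
  om <- pop$omega
  iiv <- pop$iiv
  vpar <- c()
  if (cov_cl_vp) {
    L <- t(chol(om[c("cl", "vp"), c("cl", "vp")]))
    vpar <- c(vpar, lchol_cl = log(L[1, 1]), chol_clvp = L[2, 1],
              lchol_vp = log(L[2, 2]))
    rest <- setdiff(iiv, c("cl", "vp"))
  } else rest <- iiv
  for (nm in rest) {
    v <- c(log(sqrt(om[nm, nm])))
    names(v) <- paste0("lsd_", nm)
    vpar <- c(vpar, v)
  }
  c(th, vpar, lsig = log(sqrt(pop$sigma2)))
}

.unpack <- function(x, drug, iiv, cov_cl_vp) {
  tn <- .theta_names(drug)
  th <- as.list(stats::setNames(unname(exp(x[seq_along(tn)])), tn))
  theta <- if (drug == "DEX")
    pk_params(th$cl, th$vp, th$cld, th$vt, th$ka_im, th$ka_po, th$fr)
  else
    pk_params(th$cl, th$vp, th$cld, th$vt, th$ka_im, th$ka_po, th$fr,
              ka_ima = th$ka_ima, fra = th$fra)
  i <- length(tn)
  om <- matrix(0, length(iiv), length(iiv), dimnames = list(iiv, iiv))
  if (cov_cl_vp) {
    L <- matrix(0, 2, 2)
    L[1, 1] <- exp(x[i + 1]); L[2, 1] <- x[i + 2]; L[2, 2] <- exp(x[i + 3])
    blk <- L %*% t(L)
    om[c("cl", "vp"), c("cl", "vp")] <- blk
    i <- i + 3
    rest <- setdiff(iiv, c("cl", "vp"))
  } else rest <- iiv
  for (nm in rest) {
    i <- i + 1
    om[nm, nm] <- exp(2 * x[i])
  }
  sigma2 <- unname(exp(2 * x[i + 1]))
  pop_params(theta, om, sigma2, iiv)
}

# --- starting values ------------------------------------------------------

# crude pooled-curve heuristics: CL from dose/AUC of the IM-solution arm,
# terminal slope from its last quantified points, absorption rates from
# time-to-peak; good enough to put the optimizer in the right basin
.nca_start <- function(data, drug) {
  obs <- data[data$EVID == 0 & data$BLQ == 0, ]
  # time since the most recent dose, so subjects kept on a common clock
  # (carryover sequences) align with re-zeroed ones
  tad <- numeric(nrow(obs))
  for (id in unique(obs$ID)) {
    dt <- data$TIME[data$ID == id & data$EVID == 1]
    i <- obs$ID == id
    tad[i] <- vapply(obs$TIME[i], function(t) {
      prior <- dt[dt <= t]
      if (length(prior)) t - max(prior) else t
    }, numeric(1))
  }
  obs$TAD <- tad
  mean_curve <- function(trts) {
    o <- obs[obs$TRT %in% trts & obs$TAD <= 96, ]
    if (nrow(o) == 0) return(NULL)
    ag <- stats::aggregate(DV ~ TAD, data = o, FUN = function(z)
      exp(mean(log(z))))
    names(ag)[1] <- "TIME"
    ag[order(ag$TIME), ]
  }
  trap <- function(t, c) sum(diff(t) * (utils::head(c, -1) + c[-1]) / 2)
  im <- mean_curve(if (drug == "DEX") "A" else "B")
  po <- mean_curve(if (drug == "DEX") "D" else "E")
  ref <- if (!is.null(im)) im else po
  n <- nrow(ref)
  tail_idx <- max(1, n - 3):n
  lam <- -stats::coef(stats::lm(log(DV) ~ TIME, data = ref[tail_idx, ]))[2]
  lam <- max(min(lam, 1), 1e-3)
  auc <- trap(ref$TIME, ref$DV) + ref$DV[n] / lam
  cl0 <- 6 * 1000 / auc
  vz <- cl0 / lam
  ka_from <- function(curve, fallback) {
    if (is.null(curve)) return(fallback)
    max(3 / curve$TIME[which.max(curve$DV)], 2.5 * lam)
  }
  st <- list(cl = cl0, vp = 0.6 * vz, cld = 0.05 * cl0, vt = 0.06 * vz,
             ka_im = ka_from(im, 0.7), ka_po = ka_from(po, 1),
             fr = if (!is.null(im) && !is.null(po))
               max(0.3, min(3, trap(po$TIME, po$DV) / trap(im$TIME, im$DV)))
             else 1)
  if (drug == "BET") {
    st$ka_ima <- 0.01  # slow-depot magnitude; refined by the optimizer
    st$fra <- 0.8
  }
  do.call(pk_params, st)
}

# --- the fit --------------------------------------------------------------

#' Fit the population pharmacokinetic model
#'
#' Maximum (Laplace-approximate marginal) likelihood estimation of the
#' two-compartment depot model for one drug: typical values on the log
#' scale, log-normal IIV with omega in a log-Cholesky parameterization,
#' log-scale residual variance, and Beal M3 likelihood for BLQ records.
#' Minimization uses `stats::nlminb`; per-subject empirical-Bayes modes
#' are warm-started across objective evaluations.
#'
#' @param data Analysis dataset for one drug (e.g. from [drug_dataset] or
#'   [read_pk_dataset]).
#' @param drug `"DEX"` or `"BET"`; decides which depots/thetas exist and
#'   the default IIV structure (DEX: CL, ka_im, ka_po, central-volume IIV
#'   fixed at 0; BET: all seven with a CL-Vp covariance).
#' @param start Optional [pk_params] (or [pop_params]) starting point;
#'   defaults to pooled-curve NCA-style heuristics.
#' @param iiv Character vector of parameters carrying IIV; default per
#'   drug.
#' @param cov_cl_vp Estimate the CL-Vp covariance (default: BET only).
#' @param fix Named list of quantities to fix rather than estimate:
#'   entries of `omega2` (named log-variances), and/or `sigma2`.
#' @param control See [pk_control].
#' @return Object of class `pk_fit`.
#' @examples
#' \donttest{
#' study <- generate_study(design = study_design(n_per_sequence = 1),
#'                         seed = 7)
#' fit <- pk_fit(drug_dataset(study, "DEX"), "DEX",
#'               control = pk_control(se = FALSE))
#' coef(fit)
#' }
#' @export
pk_fit <- function(data, drug = c("DEX", "BET"), start = NULL,
                   iiv = NULL, cov_cl_vp = NULL, fix = NULL,
                   control = pk_control()) {
  drug <- match.arg(drug)
  if (is.null(iiv)) iiv <- .default_iiv(drug)
  if (is.null(cov_cl_vp)) cov_cl_vp <- drug == "BET" &&
      all(c("cl", "vp") %in% iiv)
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("`data` must be a non-empty analysis dataset", call. = FALSE)
  if ("DRUG" %in% names(data) && length(unique(data$DRUG)) > 1)
    stop("fit one drug at a time (use drug_dataset())", call. = FALSE)

  if (is.null(start)) start <- .nca_start(data, drug)
  if (inherits(start, "pk_params")) {
    om0 <- diag(rep(0.04, length(iiv)))
    dimnames(om0) <- list(iiv, iiv)
    start <- pop_params(start, om0, sigma2 = 0.05, iiv = iiv)
  }
  stopifnot(inherits(start, "pop_params"))
  if (cov_cl_vp && start$omega["cl", "vp"] == 0) {
    # a PD seed for the log-Cholesky block
    start$omega["cl", "vp"] <- start$omega["vp", "cl"] <-
      0.1 * sqrt(start$omega["cl", "cl"] * start$omega["vp", "vp"])
  }

  x0 <- .pack(start, drug, cov_cl_vp)
  free <- rep(TRUE, length(x0))
  names(free) <- names(x0)
  if (!is.null(fix$sigma2)) {
    x0["lsig"] <- log(sqrt(fix$sigma2))
    free["lsig"] <- FALSE
  }
  if (!is.null(fix$omega2)) {
    for (nm in names(fix$omega2)) {
      key <- paste0("lsd_", nm)
      if (!key %in% names(x0))
        stop("cannot fix omega2 entry `", nm, "`", call. = FALSE)
      x0[key] <- log(sqrt(fix$omega2[[nm]]))
      free[key] <- FALSE
    }
  }

  subs <- .subject_list(data)
  warm <- new.env(parent = emptyenv())
  n_eval <- 0L
  xfull <- x0
  objective <- function(xf) {
    xfull[free] <<- xf
    pop <- try(.unpack(xfull, drug, iiv, cov_cl_vp), silent = TRUE)
    if (inherits(pop, "try-error")) return(1e10)
    v <- try(total_ofv(subs, pop, warm = warm), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    n_eval <<- n_eval + 1L
    as.numeric(v)
  }
  opt <- stats::nlminb(x0[free], objective,
                       control = list(iter.max = control$iter_max,
                                      eval.max = control$eval_max,
                                      rel.tol = control$rel_tol))
  par <- opt$par
  fval <- opt$objective
  grad_norm <- NA_real_
  if (isTRUE(control$polish)) {
    pol <- .newton_polish(objective, par, fval,
                          max_iter = control$polish_iter,
                          tol = control$polish_tol)
    par <- pol$par
    fval <- pol$value
    grad_norm <- pol$grad_norm
  }
  xfull[free] <- par
  pop <- .unpack(xfull, drug, iiv, cov_cl_vp)
  ofv <- total_ofv(subs, pop, warm = warm)  # refresh EB modes at optimum

  fit <- structure(list(
    pop = pop, drug = drug, ofv = as.numeric(ofv),
    n_nonconverged = attr(ofv, "n_nonconverged"),
    convergence = opt$convergence, message = opt$message,
    grad_norm = grad_norm,
    n_eval = n_eval, par = xfull, free = free,
    iiv = iiv, cov_cl_vp = cov_cl_vp,
    eta = {
      e <- warm$eta
      dimnames(e) <- list(iiv, names(subs))
      t(e)
    },
    start = start, data = data, control = control,
    se_table = NULL, vcov = NULL), class = "pk_fit")
  if (isTRUE(control$se)) fit <- add_standard_errors(fit)
  fit
}

# damped Newton refinement on a numerically differentiated objective;
# eigenvalue-floored Hessian with backtracking keeps each step a descent
.newton_polish <- function(f, x, fx = f(x), max_iter = 4, tol = 0.1) {
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_along(x), function(i) {
      h <- 1e-4 * max(abs(x[i]), 1)
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, numeric(1))
    gnorm <- max(abs(g))
    if (gnorm < tol) break
    H <- .num_hessian(f, x)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-2)
    step <- drop(ev$vectors %*% (crossprod(ev$vectors, g) / lam))
    tstep <- 1
    moved <- FALSE
    for (bt in 1:10) {
      fc <- f(x - tstep * step)
      if (is.finite(fc) && fc < fx) {
        x <- x - tstep * step
        fx <- fc
        moved <- TRUE
        break
      }
      tstep <- tstep / 2
    }
    if (!moved) break
  }
  list(par = x, value = fx, grad_norm = gnorm)
}

# --- standard errors ------------------------------------------------------

# central-difference Hessian of a scalar function
.num_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hs <- h * pmax(abs(x), 1)
  f0 <- f(x)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + hs[i]
    xm <- x; xm[i] <- x[i] - hs[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hs[i]^2
    for (j in seq_len(i - 1)) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hs[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
      xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hs[c(i, j)]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}

# natural-scale parameter vector (thetas, omega entries, sigma2) from the
# transformed vector; used for the delta method
.natural_vec <- function(xfull, drug, iiv, cov_cl_vp) {
  pop <- .unpack(xfull, drug, iiv, cov_cl_vp)
  tn <- .theta_names(drug)
  th <- unlist(pop$theta)[tn]
  om <- diag(pop$omega)
  names(om) <- paste0("omega2_", iiv)
  out <- c(th, om)
  if (cov_cl_vp) out <- c(out, cov_cl_vp = pop$omega["cl", "vp"])
  c(out, sigma2 = pop$sigma2)
}

#' Standard errors from the OFV curvature
#'
#' Numerically differentiates the objective function at the optimum,
#' inverts half the Hessian (the observed information for -2 log L), and
#' delta-method maps to the natural scale. `%RSE = 100 * SE / estimate`.
#' A non-positive-definite information matrix is flagged, not silently
#' accepted.
#'
#' @param fit A [pk_fit] object.
#' @return The fit with `se_table` (natural-scale estimates, SE, %RSE) and
#'   `vcov` filled in; `se_ok` reports whether the information matrix was
#'   positive definite.
#' @export
add_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  subs <- .subject_list(fit$data)
  warm <- new.env(parent = emptyenv())
  total_ofv(subs, fit$pop, warm = warm)
  xfull <- fit$par
  free <- fit$free
  f <- function(xf) {
    xfull[free] <- xf
    pop <- .unpack(xfull, fit$drug, fit$iiv, fit$cov_cl_vp)
    as.numeric(total_ofv(subs, pop, warm = warm))
  }
  H <- .num_hessian(f, fit$par[free])
  info <- H / 2
  ch <- tryCatch(chol(info), error = function(e) NULL)
  fit$se_ok <- !is.null(ch)
  if (is.null(ch)) {
    fit$se_table <- NULL
    warning("OFV Hessian not positive definite; no standard errors",
            call. = FALSE)
    return(fit)
  }
  vx <- chol2inv(ch)
  # jacobian of natural-scale quantities wrt the free transformed params
  g0 <- .natural_vec(xfull, fit$drug, fit$iiv, fit$cov_cl_vp)
  J <- matrix(0, length(g0), sum(free))
  xf0 <- fit$par[free]
  for (k in seq_len(sum(free))) {
    h <- 1e-5 * max(abs(xf0[k]), 1)
    xp <- xf0; xp[k] <- xp[k] + h
    xm <- xf0; xm[k] <- xm[k] - h
    xtmp <- xfull; xtmp[free] <- xp
    gp <- .natural_vec(xtmp, fit$drug, fit$iiv, fit$cov_cl_vp)
    xtmp[free] <- xm
    gm <- .natural_vec(xtmp, fit$drug, fit$iiv, fit$cov_cl_vp)
    J[, k] <- (gp - gm) / (2 * h)
  }
  Vn <- J %*% vx %*% t(J)
  se <- sqrt(pmax(diag(Vn), 0))
  fit$vcov <- structure(Vn, dimnames = list(names(g0), names(g0)))
  fit$se_table <- data.frame(
    parameter = names(g0), estimate = unname(g0), se = se,
    rse_pct = 100 * se / abs(unname(g0)), row.names = NULL)
  fit
}

# --- methods --------------------------------------------------------------

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d subjects, OFV %.3f\n",
              x$drug, nrow(x$eta), x$ofv))
  cat(sprintf("outer convergence code %d (%s); %d objective evaluations\n",
              x$convergence, x$message, x$n_eval))
  print(summary(x), ...)
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' Mirrors the conventional reporting layout: typical value with %RSE,
#' IIV variance with %RSE and as CV%, then the residual variance.
#'
#' @param object A [pk_fit].
#' @param ... Unused.
#' @return data.frame of class `summary.pk_fit`.
#' @export
summary.pk_fit <- function(object, ...) {
  pop <- object$pop
  tn <- .theta_names(object$drug)
  get_se <- function(nm) {
    if (is.null(object$se_table)) return(NA_real_)
    i <- match(nm, object$se_table$parameter)
    if (is.na(i)) NA_real_ else object$se_table$rse_pct[i]
  }
  rows <- lapply(tn, function(nm) {
    om2 <- if (nm %in% object$iiv) pop$omega[nm, nm] else NA_real_
    data.frame(parameter = nm,
               estimate = unlist(pop$theta)[[nm]],
               rse_pct = get_se(nm),
               omega2 = om2,
               omega2_rse_pct = if (nm %in% object$iiv)
                 get_se(paste0("omega2_", nm)) else NA_real_,
               cv_pct = if (!is.na(om2)) cv_percent(om2) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (object$cov_cl_vp)
    out <- rbind(out, data.frame(parameter = "cov_cl_vp",
                                 estimate = pop$omega["cl", "vp"],
                                 rse_pct = get_se("cov_cl_vp"),
                                 omega2 = NA, omega2_rse_pct = NA,
                                 cv_pct = NA))
  out <- rbind(out, data.frame(parameter = "sigma2",
                               estimate = pop$sigma2,
                               rse_pct = get_se("sigma2"),
                               omega2 = NA, omega2_rse_pct = NA,
                               cv_pct = NA))
  rownames(out) <- NULL
  class(out) <- c("summary.pk_fit", "data.frame")
  out
}

#' @export
print.summary.pk_fit <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  for (j in 2:6) y[[j]] <- signif(y[[j]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) unlist(object$pop$theta)

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = sum(object$free), class = "logLik")
}

#' @export
vcov.pk_fit <- function(object, ...) object$vcov

#' Model predictions
#'
#' @param object A [pk_fit].
#' @param newdata Optional analysis dataset; defaults to the fitted data.
#' @param type `"individual"` uses each subject's empirical-Bayes etas;
#'   `"population"` sets all etas to zero.
#' @param ... Unused.
#' @return Vector of predicted concentrations (ng/mL) for the observation
#'   rows of the dataset, in row order.
#' @export
predict.pk_fit <- function(object, newdata = NULL,
                           type = c("individual", "population"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  subs <- .subject_list(data)
  out <- lapply(names(subs), function(id) {
    s <- subs[[id]]
    eta <- if (type == "individual" && id %in% rownames(object$eta))
      object$eta[id, ] else rep(0, length(object$iiv))
    ip <- individual_params(object$pop, eta)
    cpp_conc(s$obs_t, s$dose_t, s$dose_amt, s$dose_depot, .p9_vector(ip))
  })
  unlist(out, use.names = FALSE)
}

#' @export
residuals.pk_fit <- function(object, type = c("individual", "population"),
                             ...) {
  type <- match.arg(type)
  pred <- predict(object, type = type)
  obs <- object$data[object$data$EVID == 0, ]
  r <- log(obs$DV) - log(pmax(pred, 1e-12))
  r[obs$BLQ == 1] <- NA_real_
  r
}

#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  design <- attr(object$data, "design")
  if (is.null(design)) design <- study_design()
  lapply(seq_len(nsim), function(i)
    simulate_population(object$pop, object$data,
                        seed = if (is.null(seed)) NULL else seed + i - 1))
}

#' @export
plot.pk_fit <- function(x, ...) {
  obs <- x$data[x$data$EVID == 0 & x$data$BLQ == 0, ]
  pred <- predict(x, type = "individual")
  pred <- pred[x$data$BLQ[x$data$EVID == 0] == 0]
  graphics::plot(pred, obs$DV, log = "xy",
                 xlab = "Individual prediction (ng/mL)",
                 ylab = "Observed (ng/mL)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
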