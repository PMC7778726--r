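# Dose events, treatments, and closed-form concentration profiles.

#' Dose events
#'
#' Builds a dose-event table. Times are hours since the subject's first
#' dose; amounts are mg of free-alcohol drug equivalent; `depot` selects
#' the absorption pathway (`"IM_PHOSPHATE"`, `"ORAL"` or `"IM_ACETATE"`).
#' The relative bioavailability of the depot (1, `fr` or `fra`) is applied
#' inside the concentration model, not here.
#'
#' @param time Dose times (h), >= 0.
#' @param amount Dose amounts (mg), >= 0.
#' @param depot Depot label(s), recycled.
#' @return data.frame of class `pk_doses` with columns time, amount, depot.
#' @export
dose_events <- function(time, amount, depot = "IM_PHOSPHATE") {
  depot <- rep_len(as.character(depot), length(time))
  if (!all(depot %in% names(.DEPOTS)))
    stop("unknown depot; use IM_PHOSPHATE, ORAL or IM_ACETATE", call. = FALSE)
  if (any(time < 0) || any(amount < 0))
    stop("dose times and amounts must be non-negative", call. = FALSE)
  d <- data.frame(time = as.numeric(time), amount = as.numeric(amount),
                  depot = depot, stringsAsFactors = FALSE)
  d <- d[order(d$time), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("pk_doses", "data.frame")
  d
}

#' Study treatments A-E
#'
#' The five single-dose treatments of the crossover study, all 6 mg total:
#' A = DEX phosphate IM solution, B = BET phosphate IM solution,
#' C = BET phosphate (3 mg) + acetate (3 mg) IM suspension ("BET-PA"),
#' D = DEX phosphate oral tablets, E = BET phosphate oral tablets.
#'
#' @param code Treatment letter, one of `"A"`-`"E"`.
#' @param time Administration time (h since the subject's first dose).
#' @return A `pk_doses` table for the administration; attributes `drug`
#'   (`"DEX"`/`"BET"`) and `label`.
#' @export
treatment_doses <- function(code, time = 0) {
  code <- match.arg(code, c("A", "B", "C", "D", "E"))
  d <- switch(code,
    A = dose_events(time, 6, "IM_PHOSPHATE"),
    B = dose_events(time, 6, "IM_PHOSPHATE"),
    C = dose_events(c(time, time), c(3, 3), c("IM_PHOSPHATE", "IM_ACETATE")),
    D = dose_events(time, 6, "ORAL"),
    E = dose_events(time, 6, "ORAL"))
  attr(d, "drug") <- if (code %in% c("A", "D")) "DEX" else "BET"
  attr(d, "label") <- switch(code,
    A = "DEX-P IM", B = "BET-P IM", C = "BET-PA IM",
    D = "DEX-P PO", E = "BET-P PO")
  d
}

.dose_arrays <- function(doses) {
  if (is.null(doses) || nrow(doses) == 0)
    return(list(t = numeric(0), amt = numeric(0), depot = integer(0)))
  list(t = doses$time, amt = doses$amount,
       depot = unname(.DEPOTS[doses$depot]))
}

#' Concentration-time profile
#'
#' Evaluates the closed-form solution of the two-compartment model with
#' first-order depot inputs (a tri-exponential per dose, superposed over
#' the dose history). Concentrations are in ng/mL (doses mg, volumes L).
#'
#' @param params A [pk_params] object.
#' @param doses A `pk_doses` table ([dose_events]/[treatment_doses]).
#' @param times Ascending observation times (h since first dose).
#' @param full If `TRUE`, also return the peripheral concentration and the
#'   remaining depot amounts (mg).
#' @return data.frame of class `pk_profile` with columns `time` and `cp`
#'   (and `ct`, `a_im`, `a_po`, `a_ima` when `full = TRUE`).
#' @examples
#' pr <- pk_profile(dex_typical(), treatment_doses("A"), seq(0, 96, 0.5))
#' max(pr$cp)
#' @export
pk_profile <- function(params, doses, times, full = FALSE) {
  stopifnot(inherits(params, "pk_params"))
  if (is.unsorted(times)) stop("`times` must be ascending", call. = FALSE)
  da <- .dose_arrays(doses)
  p9 <- .p9_vector(params)
  if (full) {
    st <- cpp_profile(times, da$t, da$amt, da$depot, p9)
    out <- data.frame(time = times, cp = st$cp, ct = st$ct,
                      a_im = st$depot_mg[, 1], a_po = st$depot_mg[, 2],
                      a_ima = st$depot_mg[, 3])
  } else {
    out <- data.frame(time = times,
                      cp = cpp_conc(times, da$t, da$amt, da$depot, p9))
  }
  class(out) <- c("pk_profile", "data.frame")
  attr(out, "params") <- params
  attr(out, "doses") <- doses
  out
}

#' @export
plot.pk_profile <- function(x, log = "", lloq = NULL, ...) {
  y <- x$cp
  if (grepl("y", log)) y <- pmax(y, 1e-3)
  graphics::plot(x$time, y, type = "l", log = log,
                 xlab = "Time (h)", ylab = "Concentration (ng/mL)", ...)
  if (!is.null(lloq)) graphics::abline(h = lloq, lty = 3)
  invisible(x)
}

# concentrations at arbitrary times for a raw p9 vector (internal fast path)
.conc_p9 <- function(p9, doses, times) {
  da <- .dose_arrays(doses)
  cpp_conc(times, da$t, da$amt, da$depot, p9)
}
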