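# Synthetic crossover-study generator: the trial's structure (8 sequences x
# 6 subjects, treatments A-E, 17 samples per period, 10-day washout) so the
# whole pipeline is exercisable without clinical data.

.SEQUENCES <- list(
  AB = c("A", "B"), BA = c("B", "A"),
  CD = c("C", "D"), DC = c("D", "C"),
  ED = c("E", "D"), DE = c("D", "E"),
  CE = c("C", "E"), EC = c("E", "C"))

.SAMPLING_TIMES <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 12, 18, 24, 30, 36,
                     48, 60, 72, 96)

#' Crossover study design
#'
#' The default design reproduces the trial structure: 8 two-period
#' sequences (AB, BA, CD, DC, ED, DE, CE, EC) of 6 subjects each, 17
#' samples per period at 0-96 h post dose, a second period starting 336 h
#' (4 sampling days + 10-day washout) after the first dose, LLOQ
#' 0.1 ng/mL, and body weights in 47.0-68.7 kg.
#'
#' @param n_per_sequence Subjects per sequence (default 6).
#' @param sampling_times Per-period sampling times, h post dose.
#' @param period_offset Start of period 2, h after the first dose.
#' @param lloq Lower limit of quantification, ng/mL.
#' @param weight_range Body-weight bounds (kg); weights are drawn
#'   uniformly (only the range is known) and act as labels, not
#'   covariates.
#' @return Object of class `pk_design`.
#' @examples
#' d <- study_design()
#' d$n_subjects # 48
#' @export
study_design <- function(n_per_sequence = 6,
                         sampling_times = .SAMPLING_TIMES,
                         period_offset = 336,
                         lloq = 0.1,
                         weight_range = c(47.0, 68.7)) {
  if (n_per_sequence < 1) stop("need at least 1 subject per sequence",
                               call. = FALSE)
  if (period_offset <= max(sampling_times))
    stop("period 2 must start after period 1 sampling ends", call. = FALSE)
  structure(list(
    sequences = .SEQUENCES,
    n_per_sequence = as.integer(n_per_sequence),
    n_subjects = as.integer(n_per_sequence * length(.SEQUENCES)),
    sampling_times = sampling_times,
    period_offset = period_offset,
    lloq = lloq,
    weight_range = weight_range), class = "pk_design")
}

#' @export
print.pk_design <- function(x, ...) {
  cat(sprintf("Crossover design: %d sequences x %d = %d subjects\n",
              length(x$sequences), x$n_per_sequence, x$n_subjects))
  cat(sprintf("%d samples per period; period 2 at %g h; LLOQ %g ng/mL\n",
              length(x$sampling_times), x$period_offset, x$lloq))
  invisible(x)
}

#' Generate a synthetic crossover study
#'
#' Simulates the full event-level dataset under the design: per subject a
#' body weight, one random-effect vector per drug received, dosing per the
#' sequence's treatments (period 2 at the inter-period offset, all times on
#' a common clock since the subject's first dose), log-normal residual
#' error on each observation, and LLOQ censoring. Observations in each
#' period assay that period's drug, so sequences CE/EC (both periods
#' betamethasone) carry the slow-acetate residue of period 1 into the
#' period-2 records.
#'
#' @param pop_dex,pop_bet [pop_params] objects used for DEX / BET subjects
#'   (defaults: the published population models).
#' @param design A [pk_design].
#' @param seed Integer seed; the dataset is reproducible from it.
#' @return A `pk_study` data.frame in the analysis-dataset schema (see
#'   [read_pk_dataset]) with the pre-censoring concentration kept in the
#'   oracle-only column `.latent`.
#' @export
generate_study <- function(pop_dex = dex_population(),
                           pop_bet = bet_population(),
                           design = study_design(),
                           seed = 1L) {
  stopifnot(inherits(design, "pk_design"))
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", design$n_subjects)
  id <- 0L
  for (sq in names(design$sequences)) {
    for (k in seq_len(design$n_per_sequence)) {
      id <- id + 1L
      wt <- stats::runif(1, design$weight_range[1], design$weight_range[2])
      etas <- list()
      subj_rows <- list()
      for (period in 1:2) {
        trt <- design$sequences[[sq]][period]
        drug <- if (trt %in% c("A", "D")) "DEX" else "BET"
        pop <- if (drug == "DEX") pop_dex else pop_bet
        if (is.null(etas[[drug]]))
          etas[[drug]] <- as.numeric(
            MASS::mvrnorm(1, mu = rep(0, length(pop$iiv)), Sigma = pop$omega))
        t0 <- design$period_offset * (period - 1)
        doses <- treatment_doses(trt, time = t0)
        obs_t <- t0 + design$sampling_times
        # all same-drug doses up to now (carryover for CE/EC)
        drug_doses <- do.call(rbind, lapply(which(
          design$sequences[[sq]][1:period] %in%
            if (drug == "DEX") c("A", "D") else c("B", "C", "E")),
          function(p) treatment_doses(design$sequences[[sq]][p],
                                      time = design$period_offset * (p - 1))))
        ip <- individual_params(pop, etas[[drug]])
        conc <- pk_profile(ip, drug_doses, obs_t)$cp
        eps <- stats::rnorm(length(obs_t), 0, sqrt(pop$sigma2))
        latent <- conc * exp(eps)
        subj_rows[[length(subj_rows) + 1L]] <- data.frame(
          ID = id,
          TIME = c(doses$time, obs_t),
          EVID = c(rep(1L, nrow(doses)), rep(0L, length(obs_t))),
          AMT = c(doses$amount, rep(NA_real_, length(obs_t))),
          CMT = c(doses$depot, rep(NA_character_, length(obs_t))),
          DV = c(rep(NA_real_, nrow(doses)), latent),
          MDV = c(rep(1L, nrow(doses)), rep(0L, length(obs_t))),
          BLQ = 0L,
          LLOQ = design$lloq,
          DRUG = drug, TRT = trt, SEQ = sq, PERIOD = period, WT = wt,
          .latent = c(rep(NA_real_, nrow(doses)), latent),
          stringsAsFactors = FALSE)
      }
      rows[[id]] <- do.call(rbind, subj_rows)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  out <- censor_lloq(out, design$lloq)
  class(out) <- c("pk_study", "data.frame")
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}

#' Censor observations below the limit of quantification
#'
#' Marks observation rows with concentration below `lloq` as BLQ and
#' withholds the numeric value. Idempotent. The pre-censoring value is
#' preserved in the `.latent` column (synthetic data only, for test
#' oracles); [write_pk_dataset] drops it.
#'
#' @param data Analysis dataset.
#' @param lloq LLOQ, ng/mL.
#' @return The dataset with `BLQ`, `DV` and `LLOQ` updated.
#' @export
censor_lloq <- function(data, lloq = 0.1) {
  obs <- data$EVID == 0
  val <- if (".latent" %in% names(data)) data$.latent else data$DV
  below <- obs & !is.na(val) & val < lloq
  already <- obs & data$BLQ == 1
  data$BLQ[below] <- 1L
  data$DV[below | already] <- NA_real_
  data$LLOQ[obs] <- lloq
  data
}

#' Extract one drug's analysis dataset
#'
#' Returns the rows used to fit one drug, with the trial's time
#' convention: subjects who received the drug in a single period
#' contribute that period re-zeroed at its dose time; sequences CE/EC
#' (betamethasone in both periods) keep both periods on the common clock
#' since the first dose, so the acetate carryover is part of the record.
#'
#' @param study A `pk_study` dataset.
#' @param drug `"DEX"` or `"BET"`.
#' @return A `pk_study` data.frame for the one drug.
#' @export
drug_dataset <- function(study, drug = c("DEX", "BET")) {
  drug <- match.arg(drug)
  keep <- study[study$DRUG == drug, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  pieces <- lapply(split(keep, keep$ID), function(s) {
    if (length(unique(s$PERIOD)) == 1) {
      t0 <- min(s$TIME[s$EVID == 1])
      s$TIME <- s$TIME - t0
    }
    s
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  class(out) <- c("pk_study", "data.frame")
  attr(out, "design") <- attr(study, "design")
  out
}
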