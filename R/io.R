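# Dataset I/O (NONMEM-convention CSV) and the command-line entry point.

.DATASET_COLS <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV", "BLQ",
                   "LLOQ", "DRUG", "TRT", "SEQ", "PERIOD", "WT")

.validate_dataset <- function(d) {
  errs <- character(0)
  add <- function(rows, msg) {
    if (length(rows))
      errs <<- c(errs, sprintf("row %d: %s", rows, msg))
  }
  missing_cols <- setdiff(.DATASET_COLS, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  dose <- d$EVID == 1
  add(which(dose & (is.na(d$AMT) | d$AMT <= 0)),
      "dose row needs AMT > 0")
  add(which(dose & !is.na(d$DV)), "dose row must not carry DV")
  add(which(dose & !(d$CMT %in% names(.DEPOTS))),
      "dose row needs a valid depot in CMT")
  obs <- d$EVID == 0
  add(which(obs & d$BLQ == 1 & !is.na(d$DV)),
      "BLQ row must not carry a numeric DV")
  add(which(obs & d$BLQ == 0 & (is.na(d$DV) | d$DV <= 0)),
      "quantified row needs DV > 0")
  add(which(obs & (is.na(d$LLOQ) | d$LLOQ <= 0)),
      "observation row needs LLOQ > 0")
  add(which(d$TIME < 0), "TIME must be >= 0")
  for (id in unique(d$ID)) {
    tt <- d$TIME[d$ID == id]
    if (is.unsorted(tt))
      errs <- c(errs, sprintf("subject %s: TIME not non-decreasing", id))
  }
  errs
}

#' Read and write analysis datasets
#'
#' One row per dose or observation event, NONMEM-convention columns:
#' `ID`, `TIME` (h since the subject's first dose), `EVID` (1 dose / 0
#' observation), `AMT` (mg, dose rows), `CMT` (depot label, dose rows),
#' `DV` (ng/mL, quantified observations), `MDV`, `BLQ` (0/1), `LLOQ`
#' (ng/mL), `DRUG`, `TRT`, `SEQ`, `PERIOD`, `WT` (kg). CSV with a header
#' row, `.` as the missing marker, `#` comment lines ignored. Reading
#' validates the schema and reports offending line numbers; writing drops
#' the oracle-only `.latent` column.
#'
#' @param path File path.
#' @return `read_pk_dataset()`: a `pk_study` data.frame.
#' @export
read_pk_dataset <- function(path) {
  d <- utils::read.csv(path, na.strings = ".", comment.char = "#",
                       stringsAsFactors = FALSE)
  errs <- .validate_dataset(d)
  if (length(errs))
    stop("invalid dataset `", path, "`:\n  ",
         paste(utils::head(errs, 10), collapse = "\n  "), call. = FALSE)
  class(d) <- c("pk_study", "data.frame")
  d
}

#' @rdname read_pk_dataset
#' @param data Analysis dataset.
#' @param header Optional character vector written as leading `#` comment
#'   lines (provenance/config).
#' @export
write_pk_dataset <- function(data, path, header = NULL) {
  d <- as.data.frame(data)[, .DATASET_COLS]
  errs <- .validate_dataset(d)
  if (length(errs))
    stop("refusing to write an invalid dataset:\n  ",
         paste(utils::head(errs, 10), collapse = "\n  "), call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.csv(.df_na_dot(d), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.df_na_dot <- function(d) {
  for (j in seq_along(d)) {
    v <- d[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    d[[j]] <- v
  }
  d
}

# --- command-line interface ----------------------------------------------

.cli_usage <- paste(
  "usage: dexbetpk-cli <command> [options]",
  "",
  "commands:",
  "  simulate-study --out FILE [--seed N] [--n-per-sequence N]",
  "  fit            --data FILE --drug DEX|BET --out FILE [--no-se]",
  "  vpc            --data FILE --drug DEX|BET --out FILE",
  "                 [--n-replicates N] [--seed N]",
  "  regimen-sim    --out PREFIX [--n-subjects N] [--seed N]",
  "  secondary      --drug DEX|BET --out FILE [--weight KG]",
  sep = "\n")

.cli_opts <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (key %in% c("no-se")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i == length(args)) stop("missing value for --", key, call. = FALSE)
      out[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  out
}

.cli_header <- function(cmd, opts) {
  c(sprintf("dexbetpk %s", as.character(utils::packageVersion("dexbetpk"))),
    sprintf("command: %s", cmd),
    sprintf("config: %s", paste(names(opts), unlist(lapply(opts, as.character)),
                                sep = "=", collapse = " ")),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see
#' `inst/scripts/dexbetpk-cli.R` for shell use. Subcommands:
#' `simulate-study` (synthetic crossover dataset), `fit` (parameter table
#' CSV), `vpc` (percentile/band table), `regimen-sim` (WHO regimen band
#' profiles and metrics), `secondary` (descriptor table from published
#' typical values). Every output carries its configuration in `#` header
#' lines.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("no command given", call. = FALSE)
    cmd <- args[1]
    opts <- .cli_opts(args[-1])
    hdr <- .cli_header(cmd, opts)
    write_tab <- function(tab, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste0("# ", hdr), con)
      utils::write.csv(tab, con, row.names = FALSE)
    }
    switch(cmd,
      "simulate-study" = {
        seed <- as.integer(opts$seed %||% 1)
        nps <- as.integer(opts[["n-per-sequence"]] %||% 6)
        study <- generate_study(design = study_design(n_per_sequence = nps),
                                seed = seed)
        write_pk_dataset(study, opts$out, header = hdr)
        message("wrote ", opts$out, " (", nrow(study), " rows, seed ",
                seed, ")")
      },
      "fit" = {
        data <- read_pk_dataset(opts$data)
        drug <- match.arg(opts$drug, c("DEX", "BET"))
        data <- drug_dataset(data, drug)
        ctrl <- pk_control(se = is.null(opts[["no-se"]]))
        fit <- pk_fit(data, drug, control = ctrl)
        write_tab(summary(fit), opts$out)
        message(sprintf("fit %s: OFV %.3f, convergence %d; wrote %s",
                        drug, fit$ofv, fit$convergence, opts$out))
      },
      "vpc" = {
        data <- read_pk_dataset(opts$data)
        drug <- match.arg(opts$drug, c("DEX", "BET"))
        data <- drug_dataset(data, drug)
        pop <- if (drug == "DEX") dex_population() else bet_population()
        v <- vpc(data, pop,
                 n_replicates = as.integer(opts[["n-replicates"]] %||% 500),
                 seed = as.integer(opts$seed %||% 1))
        write_tab(as.data.frame(v), opts$out)
        message(sprintf("VPC coverage %.3f; wrote %s", vpc_coverage(v),
                        opts$out))
      },
      "regimen-sim" = {
        seed <- as.integer(opts$seed %||% 1)
        n <- as.integer(opts[["n-subjects"]] %||% 200)
        regs <- who_regimens()
        for (nm in names(regs)) {
          pop <- if (regs[[nm]]$drug == "DEX") dex_population()
                 else bet_population()
          rs <- regimen_metrics(pop, regs[[nm]], n_subjects = n, seed = seed)
          write_tab(rs$profile, paste0(opts$out, "_", nm, "_profile.csv"))
          write_tab(rs$summary, paste0(opts$out, "_", nm, "_metrics.csv"))
        }
        message("wrote band profiles and metrics for ",
                length(regs), " regimens under prefix ", opts$out)
      },
      "secondary" = {
        drug <- match.arg(opts$drug, c("DEX", "BET"))
        params <- if (drug == "DEX") dex_typical() else bet_typical()
        trts <- if (drug == "DEX") c("A", "D") else c("B", "C", "E")
        wt <- as.numeric(opts$weight %||% 56.8)
        tab <- do.call(rbind, lapply(trts, function(tr)
          secondary_descriptors(params, tr, body_weight_kg = wt)))
        write_tab(tab, opts$out)
        message("wrote ", opts$out)
      },
      stop("unknown command: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(.cli_usage)
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
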