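#' Study datasets
#'
#' A `dex_data` object is a list of subject records, each holding the
#' covariates (`bw` kg, `age` months, `pma` weeks, `sex`, `prism`), the dose
#' events, the timed concentration observations with their occasion flag
#' (1 = during infusion, 2 = after cessation), any planned pre-dose samples
#' (concentration exactly zero, kept as design rows but never entering the
#' likelihood), and the infusion cessation time. `dex_data()` parses the
#' event-record table documented in [read_dataset()]; `as.data.frame()`
#' inverts it.
#'
#' @param table event-record data frame with columns `ID`, `TIME`, `AMT`,
#'   `RATE`, `DUR`, `DV`, `OCC`, `BW`, `AGE`, `PMA`, `SEX`, `PRISM`
#' @return a `dex_data` object
#' @export
dex_data <- function(table) {
  req <- c("ID", "TIME", "AMT", "RATE", "DUR", "DV", "OCC",
           "BW", "AGE", "PMA", "SEX", "PRISM")
  miss <- setdiff(req, names(table))
  if (length(miss))
    .dex_stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(table$TIME)))
    .dex_stop("TIME must be present on every row")
  neg <- which(!is.na(table$DV) & table$DV < 0)
  if (length(neg))
    .dex_stop("negative DV on row(s) ", paste(head(neg, 5), collapse = ", "))
  ids <- unique(table$ID)
  subs <- lapply(ids, function(id) {
    rows <- table[table$ID == id, , drop = FALSE]
    if (is.unsorted(rows$TIME))
      .dex_stop("TIME not non-decreasing within ID ", id)
    dose_rows <- !is.na(rows$AMT)
    if (!any(dose_rows)) .dex_stop("ID ", id, " has no dose rows")
    doses <- dose_events(start = rows$TIME[dose_rows],
                         rate = .na0(rows$RATE[dose_rows]),
                         duration = .na0(rows$DUR[dose_rows]),
                         amount = rows$AMT[dose_rows])
    obs_rows <- !dose_rows & !is.na(rows$DV) & rows$DV > 0
    pre_rows <- !dose_rows & !is.na(rows$DV) & rows$DV == 0
    if (any(!dose_rows & is.na(rows$DV)))
      .dex_stop("row with neither AMT nor DV for ID ", id)
    if (any(is.na(rows$OCC[obs_rows])))
      .dex_stop("observation rows of ID ", id, " must carry OCC")
    .subject(id = id, bw = rows$BW[1], age = rows$AGE[1], pma = rows$PMA[1],
             sex = as.character(rows$SEX[1]), prism = rows$PRISM[1],
             doses = doses,
             obs = data.frame(time = rows$TIME[obs_rows],
                              conc = rows$DV[obs_rows],
                              occasion = as.integer(rows$OCC[obs_rows])),
             predose = rows$TIME[pre_rows])
  })
  new_dex_data(subs)
}

.na0 <- function(x) ifelse(is.na(x), 0, x)

.subject <- function(id, bw, age, pma, sex, prism, doses, obs,
                     predose = numeric(0)) {
  if (bw <= 0 || pma <= 0) .dex_stop("BW and PMA must be positive")
  list(id = id, bw = as.numeric(bw), age = as.numeric(age),
       pma = as.numeric(pma), sex = sex, prism = as.numeric(prism),
       doses = doses, obs = obs, predose = predose,
       cessation = .dose_grid(doses)$cessation)
}

new_dex_data <- function(subjects) structure(subjects, class = "dex_data")

#' @rdname dex_data
#' @param x a `dex_data` object
#' @param ... unused
#' @export
as.data.frame.dex_data <- function(x, ...) {
  rows <- lapply(x, function(s) {
    d <- data.frame(TIME = s$doses$start, AMT = s$doses$amount,
                    RATE = ifelse(s$doses$rate > 0, s$doses$rate, NA),
                    DUR = ifelse(s$doses$duration > 0, s$doses$duration, NA),
                    DV = NA_real_, OCC = NA_integer_, .ord = 0)
    o <- data.frame(TIME = s$obs$time, AMT = NA_real_, RATE = NA_real_,
                    DUR = NA_real_, DV = s$obs$conc,
                    OCC = s$obs$occasion, .ord = 1)
    p <- if (length(s$predose))
      data.frame(TIME = s$predose, AMT = NA_real_, RATE = NA_real_,
                 DUR = NA_real_, DV = 0, OCC = 1L, .ord = 1)
    else NULL
    tab <- rbind(d, o, p)
    tab <- tab[order(tab$TIME, tab$.ord), setdiff(names(tab), ".ord")]
    cbind(ID = s$id, tab, BW = s$bw, AGE = s$age, PMA = s$pma,
          SEX = s$sex, PRISM = s$prism)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dex_data <- function(x, ...) {
  nobs <- sum(vapply(x, function(s) nrow(s$obs), 0L))
  cat(sprintf("dexmedetomidine PK dataset: %d subjects, %d observations\n",
              length(x), nobs))
  bw <- vapply(x, `[[`, 0, "bw"); age <- vapply(x, `[[`, 0, "age")
  cat(sprintf("  weight %.1f-%.1f kg, age %.1f-%.1f months\n",
              min(bw), max(bw), min(age), max(age)))
  invisible(x)
}

.units_header <- paste("# units: TIME h, AMT ug, RATE ug/h, DUR h,",
                       "DV ng/mL, BW kg, AGE months, PMA weeks")

#' Read and write event-record datasets
#'
#' The on-disk format is a NONMEM-flavoured but self-describing CSV: one row
#' per dose event or observation, a `# units:` comment line, an explicit
#' `DUR` column rather than rate codes, and dose/observation rows
#' disambiguated by `AMT` present vs `DV` present. `DV` is blank on dose
#' rows, positive on observation rows, and exactly 0 on planned pre-dose
#' design rows. Times are hours from the first dose. Numbers are written
#' with enough digits to round-trip doubles exactly.
#'
#' @param path CSV file path
#' @param data a `dex_data` object
#' @return `read_dataset()` returns a `dex_data` object; `write_dataset()`
#'   returns `path` invisibly
#' @export
read_dataset <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# units:"))
    warning("no '# units:' header line; assuming h/ug/ng-per-mL convention")
  else if (first != .units_header)
    .dex_stop("unexpected units header: ", first)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  dex_data(tab)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  tab <- as.data.frame(data)
  num <- vapply(tab, is.numeric, TRUE)
  for (j in which(num)) tab[[j]] <- .fmt_num(tab[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.units_header, con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# shortest decimal string that parses back to the identical double
.fmt_num <- function(x) {
  s <- as.character(x)
  ok <- is.na(x) | (!is.na(suppressWarnings(as.numeric(s))) &
                      suppressWarnings(as.numeric(s)) == x)
  s[!ok] <- sprintf("%.17g", x[!ok])
  s
}

#' Write a run manifest
#'
#' Serialises everything needed to re-execute a fit exactly: sampler
#' configuration and seed, prior hyperparameters, convergence summary,
#' DIC, data dimensions and package version.
#'
#' @param fit a [dex_fit()] result
#' @param path JSON file path
#' @return `path`, invisibly
#' @export
write_manifest <- function(fit, path) {
  m <- list(
    package = "dexpk",
    version = as.character(utils::packageVersion("dexpk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    control = unclass(fit$control),
    priors = {p <- unclass(fit$priors); p$Omega0 <- diag(p$Omega0); p},
    n_subjects = length(fit$data),
    n_obs = sum(vapply(fit$data, function(s) nrow(s$obs), 0L)),
    rhat_max = max(fit$rhat$rhat),
    converged = fit$converged,
    dic = fit$dic
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
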