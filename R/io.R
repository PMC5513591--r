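#' Read a tracer enrichment CSV into enrichment series
#'
#' Expected columns: `dam_id`, `group`, `compartment` (`dam_plasma` /
#' `litter_urine`), `time_h`, `conc`, and optionally `units` (`gpg`,
#' default, or `ppm`, divided by 1e6 on ingestion). Validation errors name
#' the offending rows: unknown compartment labels, non-increasing times
#' within a series, negative concentrations.
#'
#' @param path CSV file path.
#' @return a named list of [enrichment_series()], keyed
#'   `"<dam_id>.<compartment>"`.
#' @export
read_tracer_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dam_id", "group", "compartment", "time_h", "conc")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- !d$compartment %in% c("dam_plasma", "litter_urine")
  if (any(bad))
    stop(sprintf("unknown compartment label in row(s): %s",
                 paste(which(bad), collapse = ", ")))
  units <- if (is.null(d$units)) rep("gpg", nrow(d)) else d$units
  bad_u <- !units %in% c("gpg", "ppm")
  if (any(bad_u))
    stop(sprintf("unknown units in row(s): %s", paste(which(bad_u), collapse = ", ")))
  d$conc_gpg <- ifelse(units == "ppm", ppm_to_gpg(d$conc), d$conc)

  keys <- split(seq_len(nrow(d)), list(d$dam_id, d$compartment), drop = TRUE)
  out <- lapply(keys, function(idx) {
    rows <- d[idx, ]
    if (any(diff(rows$time_h) <= 0)) {
      off <- idx[which(diff(rows$time_h) <= 0)[1] + 1]
      stop(sprintf("time not strictly increasing for %s/%s at file row %d",
                   rows$dam_id[1], rows$compartment[1], off))
    }
    enrichment_series(rows$time_h, rows$conc_gpg,
                      compartment = rows$compartment[1],
                      subject_id = rows$dam_id[1],
                      group = rows$group[1])
  })
  out
}

#' Read a dose-record CSV
#'
#' Expected columns: `dam_id`, `group`, `d2o_mass_g`, `dam_body_mass_g`,
#' and optionally `purity` (default 0.999), `litter_mass_g`, `litter_size`.
#'
#' @param path CSV file path.
#' @return a data frame, one row per dam.
#' @export
read_dose_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dam_id", "group", "d2o_mass_g", "dam_body_mass_g")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$dam_id))
    stop("duplicate dam_id in dose table")
  if (is.null(d$purity)) d$purity <- 0.999
  d
}

#' Read a weight-suckle-weight session CSV
#'
#' Expected columns: `litter_id`, `group`, `pnd`, `pre_weight_g`,
#' `post_weight_g`, `duration_h`, `litter_size`. Negative weight gains are
#' legitimate (weighing noise) and pass validation.
#'
#' @param path CSV file path.
#' @param per_pup if `TRUE`, rows are per-pup records and are summed into
#'   whole-litter sessions via [aggregate_pup_records()].
#' @return a session data frame.
#' @export
read_wsw_csv <- function(path, per_pup = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("litter_id", "group", "pnd", "pre_weight_g", "post_weight_g",
            "duration_h", "litter_size")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(d$duration_h <= 0)) stop("duration_h must be > 0")
  if (per_pup) d <- aggregate_pup_records(d)
  d
}

#' Write a study bundle to a directory of CSV files
#'
#' Writes `tracer.csv`, `doses.csv`, `wsw.csv`, `truth.csv` (if present)
#' and `config.json` in the same dialects the readers consume, at full
#' double precision so write-then-read round-trips are lossless to rounding.
#'
#' @param study a [generate_study()] result, or any list with compatible
#'   `tracer` / `doses` / `wsw` elements.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) format(x, digits = 17, trim = TRUE))
    write.csv(d, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  tr <- study$tracer
  tr$conc <- tr$conc_gpg
  tr$conc_gpg <- NULL
  tr$units <- "gpg"
  wr(tr, "tracer.csv")
  wr(study$doses, "doses.csv")
  if (!is.null(study$wsw)) wr(study$wsw, "wsw.csv")
  if (!is.null(study$truth)) wr(study$truth, "truth.csv")
  if (!is.null(study$config)) {
    cfg <- study$config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' Reloads the CSV tables, restores the canonical `conc_gpg` column, checks
#' that every tracer and WSW subject resolves to a dose record with a
#' consistent group label, and reattaches the config snapshot if present.
#'
#' @param dir bundle directory.
#' @return a list with `tracer`, `doses`, `wsw`, `truth`, `config` (the
#'   last three `NULL` when absent).
#' @export
read_study_bundle <- function(dir) {
  tracer_raw <- read.csv(file.path(dir, "tracer.csv"), stringsAsFactors = FALSE)
  units <- if (is.null(tracer_raw$units)) "gpg" else tracer_raw$units
  tracer_raw$conc_gpg <- ifelse(units == "ppm", ppm_to_gpg(tracer_raw$conc),
                                tracer_raw$conc)
  tracer_raw$conc <- tracer_raw$units <- NULL
  doses <- read_dose_csv(file.path(dir, "doses.csv"))
  wswp <- file.path(dir, "wsw.csv")
  wsw <- if (file.exists(wswp)) read_wsw_csv(wswp) else NULL
  trp <- file.path(dir, "truth.csv")
  truth <- if (file.exists(trp)) read.csv(trp, stringsAsFactors = FALSE) else NULL
  cfp <- file.path(dir, "config.json")
  config <- if (file.exists(cfp)) jsonlite::read_json(cfp, simplifyVector = TRUE)
            else NULL

  orphan <- setdiff(unique(tracer_raw$dam_id), doses$dam_id)
  if (length(orphan) > 0)
    stop(sprintf("tracer subject(s) without dose record: %s",
                 paste(orphan, collapse = ", ")))
  gmap <- setNames(doses$group, doses$dam_id)
  bad_g <- tracer_raw$group != gmap[tracer_raw$dam_id]
  if (any(bad_g))
    stop("group labels inconsistent between tracer and dose tables")
  list(tracer = tracer_raw, doses = doses, wsw = wsw, truth = truth,
       config = config)
}
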