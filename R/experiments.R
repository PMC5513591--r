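series_from_table <- function(tracer, id, compartment) {
  rows <- tracer[tracer$dam_id == id & tracer$compartment == compartment, ]
  if (nrow(rows) == 0) return(NULL)
  enrichment_series(rows$time_h, rows$conc_gpg, compartment = compartment,
                    subject_id = id, group = rows$group[1])
}

#' Run the tracer experiment: per-dam fits and group comparison
#'
#' The full deuterated-water analysis. For every dam in the bundle: estimate
#' total body water from the plasma intercept, fit the two-compartment
#' turnover model to the plasma and urine series ([d2o_fit()]), and record
#' rates, their SDs and CVs, body water and milk flow. Dams whose fit fails
#' or does not converge are reported and excluded from group summaries with
#' a warning. Group endpoints (body-water mass and %, transfer constant,
#' milk flow) are summarised as median, quartiles and [min; max]; with two
#' or more groups, the first two are compared endpoint-wise by the exact
#' Mann-Whitney test. With a single group the comparison is skipped with a
#' notice.
#'
#' @param study a list with `tracer` and `doses` data frames (a
#'   [generate_study()] result or [read_study_bundle()] output).
#' @param control a [d2o_control()].
#' @return an object of class `d2o_exp1_report`: `per_dam` table,
#'   `group_summary` table, `tests` (exact Mann-Whitney on TBW mass and
#'   milk flow, or `NULL`), `fits` (the underlying `d2o_fit` objects),
#'   `excluded` ids.
#' @export
run_experiment1 <- function(study, control = d2o_control()) {
  tracer <- study$tracer
  doses <- study$doses
  if (is.null(tracer) || is.null(doses))
    stop("study must contain tracer and dose tables")

  rows <- list()
  fits <- list()
  excluded <- character()
  for (i in seq_len(nrow(doses))) {
    id <- doses$dam_id[i]
    dam <- series_from_table(tracer, id, "dam_plasma")
    lit <- series_from_table(tracer, id, "litter_urine")
    if (is.null(dam) || is.null(lit)) {
      warning(sprintf("dam %s missing a tracer series; skipped", id))
      excluded <- c(excluded, id)
      next
    }
    dose <- d2o_dose(doses$d2o_mass_g[i], doses$dam_body_mass_g[i],
                     doses$purity[i])
    fit <- tryCatch(
      d2o_fit(dam, lit, dose, litter_mass = doses$litter_mass_g[i],
              control = control),
      error = function(e) {
        warning(sprintf("fit failed for dam %s: %s", id, conditionMessage(e)))
        NULL
      })
    if (is.null(fit) || !fit$converged) {
      excluded <- c(excluded, id)
      if (!is.null(fit)) fits[[id]] <- fit
      next
    }
    fits[[id]] <- fit
    cf <- coef(fit)
    rows[[id]] <- data.frame(
      dam_id = id, group = doses$group[i],
      k_out_dam = cf[["k_out_dam"]],
      k_dam_to_litter = cf[["k_dam_to_litter"]],
      k_out_litter = cf[["k_out_litter"]],
      sd_k_dam_to_litter = fit$param_sd[["k_dam_to_litter"]],
      cv_k_dam_to_litter = fit$param_cv[["k_dam_to_litter"]],
      tbw_mass_g = fit$pools$tbw_dam,
      tbw_pct = 100 * fit$tbw_estimate$fraction,
      milk_flow_gph = fit$milk_flow,
      milk_flow_sd = fit$milk_flow_sd,
      n_obs = fit$n_obs,
      converged = fit$converged)
  }
  per_dam <- do.call(rbind, rows)
  rownames(per_dam) <- NULL
  if (is.null(per_dam) || nrow(per_dam) == 0)
    stop("no dam produced a converged fit")

  endpoints <- c(tbw_mass_g = "tbw_mass_g", tbw_pct = "tbw_pct",
                 k_dam_to_litter = "k_dam_to_litter",
                 milk_flow_gph = "milk_flow_gph")
  groups <- unique(per_dam$group)
  gs <- list()
  for (g in groups) {
    sub <- per_dam[per_dam$group == g, ]
    for (ep in names(endpoints)) {
      s <- median_quartiles(sub[[endpoints[[ep]]]])
      gs[[length(gs) + 1L]] <- data.frame(
        group = g, endpoint = ep, n = nrow(sub),
        median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]],
        min = s[["min"]], max = s[["max"]])
    }
  }
  group_summary <- do.call(rbind, gs)

  tests <- NULL
  if (length(groups) >= 2) {
    g1 <- per_dam[per_dam$group == groups[1], ]
    g2 <- per_dam[per_dam$group == groups[2], ]
    tests <- list(
      tbw_mass = mw_exact_test(g1$tbw_mass_g, g2$tbw_mass_g),
      milk_flow = mw_exact_test(g1$milk_flow_gph, g2$milk_flow_gph))
  } else {
    message("single group: Mann-Whitney comparison skipped")
  }

  structure(list(per_dam = per_dam, group_summary = group_summary,
                 tests = tests, fits = fits, excluded = excluded,
                 control = control),
            class = "d2o_exp1_report")
}

#' @export
print.d2o_exp1_report <- function(x, digits = 4, ...) {
  cat("Deuterated-water turnover experiment\n\n")
  cat(sprintf("Converged dams: %d (%d excluded)\n\n",
              nrow(x$per_dam), length(x$excluded)))
  mf <- x$group_summary[x$group_summary$endpoint == "milk_flow_gph", ]
  for (i in seq_len(nrow(mf)))
    cat(sprintf("  %s (n=%d): milk flow median %.2f g/h [%.2f; %.2f]\n",
                mf$group[i], mf$n[i], mf$median[i], mf$min[i], mf$max[i]))
  if (!is.null(x$tests)) {
    cat(sprintf("\nExact Mann-Whitney: milk flow p = %.4g; TBW mass p = %.4g\n",
                x$tests$milk_flow$p.value, x$tests$tbw_mass$p.value))
  }
  invisible(x)
}

#' Run the weight-suckle-weight experiment
#'
#' Per group and postnatal day: the number of litters, mean and SD of dam
#' milk production ([wsw_dam_production()]). Days observed in both groups
#' with at least two litters each are compared by [welch_t_test()]; days
#' where a group was not measured appear with `NA` (printed as "nd"), and
#' days with a single litter get a mean but no test.
#'
#' @param wsw a session data frame (columns as in [read_wsw_csv()]).
#' @return an object of class `d2o_exp2_report`: `table` (group, pnd, n,
#'   mean_gph, sd_gph), `tests` (pnd, statistic, df, p_value).
#' @export
run_experiment2 <- function(wsw) {
  if (is.null(wsw) || nrow(wsw) == 0) stop("no WSW sessions supplied")
  wsw$production <- as.numeric(
    wsw_dam_production(wsw$pre_weight_g, wsw$post_weight_g, wsw$duration_h,
                       wsw$litter_size))
  groups <- unique(wsw$group)
  days <- sort(unique(wsw$pnd))
  tab <- expand.grid(group = groups, pnd = days, stringsAsFactors = FALSE)
  tab$n <- tab$mean_gph <- tab$sd_gph <- NA_real_
  for (i in seq_len(nrow(tab))) {
    v <- wsw$production[wsw$group == tab$group[i] & wsw$pnd == tab$pnd[i]]
    tab$n[i] <- length(v)
    if (length(v) > 0) tab$mean_gph[i] <- mean(v)
    if (length(v) > 1) tab$sd_gph[i] <- sd(v)
  }
  tests <- NULL
  if (length(groups) >= 2) {
    tl <- list()
    for (day in days) {
      v1 <- wsw$production[wsw$group == groups[1] & wsw$pnd == day]
      v2 <- wsw$production[wsw$group == groups[2] & wsw$pnd == day]
      if (length(v1) >= 2 && length(v2) >= 2) {
        ht <- welch_t_test(v1, v2)
        tl[[length(tl) + 1L]] <- data.frame(
          pnd = day, statistic = unname(ht$statistic),
          df = unname(ht$parameter), p_value = ht$p.value)
      } else {
        tl[[length(tl) + 1L]] <- data.frame(
          pnd = day, statistic = NA_real_, df = NA_real_, p_value = NA_real_)
      }
    }
    tests <- do.call(rbind, tl)
  }
  structure(list(table = tab[order(tab$pnd, tab$group), ], tests = tests),
            class = "d2o_exp2_report")
}

#' @export
print.d2o_exp2_report <- function(x, ...) {
  cat("Weight-suckle-weight experiment (mean +/- SD, g/h)\n\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    val <- if (is.na(r$mean_gph)) "nd"
           else sprintf("%.2f +/- %s", r$mean_gph,
                        if (is.na(r$sd_gph)) "--" else sprintf("%.2f", r$sd_gph))
    cat(sprintf("  PND %d  %-4s n=%-2d %s\n", r$pnd, r$group, r$n, val))
  }
  if (!is.null(x$tests)) {
    cat("\nWelch t tests per day:\n")
    for (i in seq_len(nrow(x$tests))) {
      r <- x$tests[i, ]
      cat(sprintf("  PND %d: %s\n", r$pnd,
                  if (is.na(r$p_value)) "not tested (a group has < 2 litters)"
                  else sprintf("t = %.3f, df = %.1f, p = %.4g",
                               r$statistic, r$df, r$p_value)))
    }
  }
  invisible(x)
}

#' Compare tracer-derived and weight-suckle-weight milk flows
#'
#' For each group present in both reports, the tracer experiment's median
#' milk flow (a single value for the whole sampling window) is compared
#' against the WSW mean on the requested days as a percent difference
#' `100 * (tracer - wsw) / wsw`; a positive value is a tracer-over-WSW
#' overestimation. The overall figure is the mean across the group-day
#' cells.
#'
#' @param exp1 a [run_experiment1()] report (or any data frame with
#'   `group`, `endpoint`, `median` columns matching its `group_summary`).
#' @param exp2 a [run_experiment2()] report.
#' @param pnd postnatal days to compare on.
#' @return an object of class `d2o_method_comparison`: `by_cell` data frame
#'   and `mean_percent_diff`.
#' @export
compare_methods <- function(exp1, exp2, pnd = 13) {
  gsum <- if (inherits(exp1, "d2o_exp1_report")) exp1$group_summary else exp1
  mf <- gsum[gsum$endpoint == "milk_flow_gph", ]
  tab <- exp2$table
  cells <- list()
  for (g in intersect(mf$group, unique(tab$group))) {
    for (day in pnd) {
      w <- tab$mean_gph[tab$group == g & tab$pnd == day]
      if (length(w) == 0 || is.na(w) || w == 0) next
      d2o <- mf$median[mf$group == g]
      cells[[length(cells) + 1L]] <- data.frame(
        group = g, pnd = day, d2o_gph = d2o, wsw_gph = w,
        percent_diff = percent_change(w, d2o))
    }
  }
  if (length(cells) == 0) stop("no comparable group x day cells")
  by_cell <- do.call(rbind, cells)
  structure(list(by_cell = by_cell,
                 mean_percent_diff = mean(by_cell$percent_diff)),
            class = "d2o_method_comparison")
}

#' @export
print.d2o_method_comparison <- function(x, ...) {
  cat("Tracer vs weight-suckle-weight milk flow\n")
  print(x$by_cell, row.names = FALSE, digits = 4)
  cat(sprintf("mean percent difference (tracer over WSW): %.1f%%\n",
              x$mean_percent_diff))
  invisible(x)
}

#' Write a tracer-experiment report to CSV and JSON
#'
#' `per_dam.csv` carries one row per converged dam (rates, SDs, CVs, body
#' water, milk flow); `summary.csv` the group summaries; `report.json` the
#' summaries, test p-values and the control snapshot needed to regenerate
#' the run.
#'
#' @param report a [run_experiment1()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_experiment1_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_dam, file.path(dir, "per_dam.csv"), row.names = FALSE)
  write.csv(report$group_summary, file.path(dir, "summary.csv"),
            row.names = FALSE)
  ctrl <- report$control
  class(ctrl) <- NULL
  jsonlite::write_json(
    list(group_summary = report$group_summary,
         tests = if (is.null(report$tests)) NULL else
           list(tbw_mass_p = report$tests$tbw_mass$p.value,
                milk_flow_p = report$tests$milk_flow$p.value),
         excluded = report$excluded,
         control = ctrl),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
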