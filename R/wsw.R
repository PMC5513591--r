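#' Dam milk production from a weight-suckle-weight session
#'
#' The classical comparator: the litter is weighed after a separation from
#' the dam (`pre_weight`), returned to suckle for `duration_h` hours, and
#' weighed again (`post_weight`). Mean per-pup intake is the mean weight
#' difference divided by suckling time; multiplying back by litter size
#' gives dam production, so algebraically dam production is simply
#' `(post_weight - pre_weight) / duration_h` regardless of litter size.
#' Negative differences (weighing noise, metabolic losses) are retained,
#' never clipped — clipping would bias the session mean upward.
#'
#' All arguments are vectorised over sessions.
#'
#' @param pre_weight whole-litter weight before suckling (g).
#' @param post_weight whole-litter weight after suckling (g).
#' @param duration_h suckling duration (h), > 0.
#' @param litter_size number of pups, >= 1 (only affects the per-pup
#'   intermediate returned as attribute `per_pup`).
#' @return dam milk production in g/h, with attribute `per_pup` (g/h per pup).
#' @examples
#' wsw_dam_production(300, 302, 1, 8)  # 2 g/h, 0.25 g/h per pup
#' @export
wsw_dam_production <- function(pre_weight, post_weight, duration_h, litter_size = 8) {
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("duration_h must be > 0")
  if (any(litter_size < 1)) stop("litter_size must be >= 1")
  if (any(pre_weight <= 0) || any(post_weight <= 0))
    stop("weights must be > 0")
  prod <- (post_weight - pre_weight) / duration_h
  structure(prod, per_pup = prod / litter_size)
}

#' Relative mass gain of a pup or litter
#'
#' Growth normalised to birth weight: `(weight - birth_weight) /
#' birth_weight`, dimensionless. Zero at birth weight, 1 when weight has
#' doubled.
#'
#' @param weight weight(s) at the day(s) of interest (g).
#' @param birth_weight weight at birth (g), > 0.
#' @return numeric vector of relative mass gains.
#' @export
relative_mass_gain <- function(weight, birth_weight) {
  if (any(!is.finite(birth_weight)) || any(birth_weight <= 0))
    stop("birth_weight must be > 0")
  (weight - birth_weight) / birth_weight
}

#' Relative mass gain at a given postnatal day from a growth record
#'
#' @param record data frame with columns `pnd` and `weight_g` (daily
#'   weights).
#' @param birth_weight birth weight (g).
#' @param pnd postnatal day to evaluate; must be present in the record.
#' @return the relative mass gain at that day.
#' @export
growth_rmg <- function(record, birth_weight, pnd) {
  i <- match(pnd, record$pnd)
  if (is.na(i)) stop(sprintf("postnatal day %s not present in record", pnd))
  relative_mass_gain(record$weight_g[i], birth_weight)
}

#' Sum per-pup weight-suckle-weight records into litter sessions
#'
#' When individual pups were weighed, rows sharing `litter_id` and `pnd` are
#' combined into one whole-litter session: weights are summed, litter size
#' is the row count (or the sum of an existing `litter_size` column), and
#' the common duration is kept. Whole-litter weighing is the canonical
#' input; this is the ingest step for per-pup files.
#'
#' @param records data frame with columns `litter_id`, `group`, `pnd`,
#'   `pre_weight_g`, `post_weight_g`, `duration_h` and optionally
#'   `litter_size`.
#' @return one row per litter x day with summed weights.
#' @export
aggregate_pup_records <- function(records) {
  if (!all(c("litter_id", "pnd", "pre_weight_g", "post_weight_g",
             "duration_h") %in% names(records)))
    stop("records must have litter_id, pnd, pre_weight_g, post_weight_g, duration_h")
  if (is.null(records$litter_size)) records$litter_size <- 1L
  key <- interaction(records$litter_id, records$pnd, drop = TRUE)
  dur <- tapply(records$duration_h, key, unique, simplify = FALSE)
  if (any(lengths(dur) > 1))
    stop("sessions within a litter x day must share one duration")
  out <- data.frame(
    litter_id = tapply(as.character(records$litter_id), key, `[`, 1),
    group = if (is.null(records$group)) NA_character_
            else as.vector(tapply(as.character(records$group), key, `[`, 1)),
    pnd = as.vector(tapply(records$pnd, key, `[`, 1)),
    pre_weight_g = as.vector(tapply(records$pre_weight_g, key, sum)),
    post_weight_g = as.vector(tapply(records$post_weight_g, key, sum)),
    duration_h = as.vector(vapply(dur, `[[`, numeric(1), 1)),
    litter_size = as.vector(tapply(records$litter_size, key, sum)),
    row.names = NULL)
  out[order(out$litter_id, out$pnd), , drop = FALSE]
}
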