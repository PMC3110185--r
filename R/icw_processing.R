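# In-Cell Western processing: background correction from no-stain wells,
# cytotoxicity-corrected differentiation index, vehicle-relative scaling,
# replicate CV and an (optional) automated outlier rule.

#' Background-correct well intensities
#'
#' Subtracts, per plate and per channel, the mean intensity of that plate's
#' no-stain wells from every well. Corrected intensities that fall below zero
#' are clamped to 0; non-control wells driven negative are flagged `outlier`.
#' Idempotent once the no-stain wells sit exactly at the estimated background.
#'
#' @param wells Well `data.frame` as produced by [generate_plate()] or
#'   [read_wells()].
#' @return The well table with corrected `channel700`/`channel800`.
#' @export
background_correct <- function(wells) {
  if (is.null(wells$qc_flag)) wells$qc_flag <- "ok"
  for (pid in unique(wells$plate_id)) {
    on_plate <- wells$plate_id == pid
    ns <- on_plate & wells$chemical == "NOSTAIN"
    if (!any(ns)) {
      stop("plate ", pid, " has no NOSTAIN background wells", call. = FALSE)
    }
    for (ch in c("channel700", "channel800")) {
      bg <- mean(wells[[ch]][ns])
      v <- wells[[ch]][on_plate] - bg
      neg <- v < 0
      flag <- neg & wells$chemical[on_plate] != "NOSTAIN"
      wells$qc_flag[on_plate][flag] <- "outlier"
      v[neg] <- 0
      wells[[ch]][on_plate] <- v
    }
  }
  wells
}

#' Cytotoxicity-corrected differentiation index
#'
#' The MYH6/MYH7 (channel-800) signal normalised to relative cell number by
#' dividing by the cell-stain (channel-700) intensity of the same well.
#' Wells with zero channel-700 have no defined index: they are flagged
#' `missing` and carry `NA`, excluding them downstream.
#'
#' @param wells Background-corrected well `data.frame`.
#' @return The well table with a `diff_index` column.
#' @export
differentiation_index <- function(wells) {
  if (is.null(wells$qc_flag)) wells$qc_flag <- "ok"
  idx <- ifelse(wells$channel700 > 0,
                wells$channel800 / wells$channel700, NA_real_)
  undef <- wells$channel700 <= 0 & wells$chemical != "NOSTAIN"
  wells$qc_flag[undef] <- "missing"
  wells$diff_index <- idx
  wells
}

#' Vehicle-relative responses
#'
#' Scales each well's cell-number signal and differentiation index to the
#' mean of its own plate's vehicle wells, yielding unitless responses with
#' vehicle = 1. Duplicate wells are retained as individual observations (the
#' activity rule operates on values, not means). Vehicle wells themselves are
#' emitted (at `conc_uM = 0`) and serve as the 0-concentration controls for
#' banding.
#'
#' @param wells Background-corrected well table with `diff_index`
#'   (see [differentiation_index()]).
#' @return Long `data.frame`: `plate_id`, `chemical`, `conc_uM`,
#'   `endpoint_axis` (`cell_number` or `differentiation`), `replicate_id`,
#'   `value`, `qc_flag`.
#' @export
relative_to_vehicle <- function(wells) {
  if (is.null(wells$diff_index)) wells <- differentiation_index(wells)
  out <- list()
  for (pid in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == pid & wells$chemical != "NOSTAIN", ,
                drop = FALSE]
    veh <- pw[pw$chemical == "VEHICLE" & pw$qc_flag == "ok", , drop = FALSE]
    if (nrow(veh) < 2) {
      stop("plate ", pid, " has fewer than 2 usable vehicle wells",
           call. = FALSE)
    }
    v700 <- mean(veh$channel700)
    vdiff <- mean(veh$diff_index, na.rm = TRUE)
    if (!is.finite(v700) || v700 == 0 || !is.finite(vdiff) || vdiff == 0) {
      stop("plate ", pid, " has a zero vehicle mean", call. = FALSE)
    }
    rep_id <- paste(pid, pw$row, pw$col, sep = "_")
    both <- rbind(
      data.frame(plate_id = pid, chemical = pw$chemical,
                 conc_uM = pw$conc_uM, endpoint_axis = "cell_number",
                 replicate_id = rep_id, value = pw$channel700 / v700,
                 qc_flag = pw$qc_flag),
      data.frame(plate_id = pid, chemical = pw$chemical,
                 conc_uM = pw$conc_uM, endpoint_axis = "differentiation",
                 replicate_id = rep_id, value = pw$diff_index / vdiff,
                 qc_flag = ifelse(is.na(pw$diff_index), "missing",
                                  pw$qc_flag))
    )
    out[[length(out) + 1L]] <- both
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Process raw plates to vehicle-relative responses
#'
#' Convenience chain: [background_correct()], [differentiation_index()],
#' [relative_to_vehicle()], optionally [qc_flag_outliers()].
#'
#' @param wells Raw well table.
#' @param outlier_k MAD multiplier for the automated outlier rule; `NULL`
#'   (default) disables it, mirroring the original manual inspection.
#' @return Long response `data.frame` (see [relative_to_vehicle()]).
#' @export
process_plates <- function(wells, outlier_k = NULL) {
  resp <- relative_to_vehicle(differentiation_index(background_correct(wells)))
  if (!is.null(outlier_k)) resp <- qc_flag_outliers(resp, k = outlier_k)
  resp
}

#' Replicate coefficient of variation
#'
#' `100 * sd(x) / mean(x)` (sample SD). Undefined (NA) when the mean is 0 or
#' fewer than 2 values are given.
#'
#' @param values Numeric vector of replicate responses.
#' @return CV in percent, or `NA`.
#' @export
replicate_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Automated replicate-outlier flagging
#'
#' Reproducible surrogate for manual plate inspection: within each chemical x
#' concentration x axis group, a value deviating from the group median by
#' more than `k` times the raw median absolute deviation is flagged `outlier`
#' and excluded from fitting. Disabled by default in [process_plates()].
#'
#' @param responses Long response table from [relative_to_vehicle()].
#' @param k MAD multiplier (default 5).
#' @return The response table with updated `qc_flag`.
#' @export
qc_flag_outliers <- function(responses, k = 5) {
  grp <- interaction(responses$chemical, responses$conc_uM,
                     responses$endpoint_axis, drop = TRUE)
  for (g in levels(grp)) {
    sel <- grp == g & responses$qc_flag == "ok"
    v <- responses$value[sel]
    if (length(v) < 2) next
    med <- stats::median(v)
    madv <- stats::median(abs(v - med))
    out <- abs(v - med) > k * madv
    if (any(out)) {
      responses$qc_flag[which(sel)[out]] <- "outlier"
    }
  }
  responses
}
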