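# Concentration-response analysis: control variability band, activity
# classification, trend-specific four-parameter Hill fitting, AC50
# assignment with the 1 M inactive default, and the AC_F inversion.
#
# Conventions follow the screening analysis this package re-implements:
# responses are vehicle-relative (control = 1); a treatment is tested
# against the band mean +/- 2 SD of the 0-concentration controls; downward
# trends are fit with the control anchored at top = 1 and bottom in [0, 1];
# upward trends are shifted by -1 so the control is 0 and a 100% increase
# is 1; the AC50 is the concentration at which the fitted curve reaches a
# 50% change from the control.

INACTIVE_AC50_M <- 1.0

#' Control variability band
#'
#' Mean of the 0-concentration (vehicle) control values plus/minus two
#' sample standard deviations.
#'
#' @param controls Numeric vector of >= 2 vehicle-relative control values.
#' @return An object of class `control_band` with fields `mean`, `sd`,
#'   `low`, `high`.
#' @export
control_band <- function(controls) {
  controls <- controls[is.finite(controls)]
  if (length(controls) < 2) {
    stop("control_band needs at least 2 control values", call. = FALSE)
  }
  m <- mean(controls)
  s <- stats::sd(controls)
  structure(list(mean = m, sd = s, low = m - 2 * s, high = m + 2 * s),
            class = "control_band")
}

#' Classify concentration-response shape against the control band
#'
#' A treatment with every value inside the band (inclusive at the edges) has
#' no effect; excursions only above the band are an upward trend, only below
#' a downward trend, and excursions on both sides are nonmonotone
#' ("u-shaped" or inverse u-shaped) and yield no AC50.
#'
#' @param values Treated-well vehicle-relative responses (all
#'   concentrations pooled).
#' @param band A [control_band()].
#' @return One of `"none"`, `"up"`, `"down"`, `"ushape"`.
#' @export
classify_activity <- function(values, band) {
  values <- values[is.finite(values)]
  above <- any(values > band$high)
  below <- any(values < band$low)
  if (above && below) "ushape"
  else if (above) "up"
  else if (below) "down"
  else "none"
}

# Predicted response on the fitting scale.
# down: bottom + (1 - bottom) / (1 + (c/K)^h)   (top anchored at 1)
# up (shifted by -1): top * c^h / (c^h + K^h)   (bottom anchored at 0)
hill_predict <- function(conc, shape, bottom, top, ac50, slope) {
  frac <- hill_fraction(conc, ac50, slope)
  if (shape == "down") bottom + (1 - bottom) * (1 - frac) else top * frac
}

#' Trend-specific four-parameter Hill fit
#'
#' Nonlinear least squares on the scale the trend dictates. Downward trends
#' are fit with the 0-concentration control fixed at top = 1 (100%) and the
#' bottom bounded in \[0, 1\] (complete loss of signal = 0). Upward trends
#' are fit on values shifted by -1 (control = 0; a 100% increase = 1) with
#' the bottom fixed at 0 and the top free (>= 0). The slope is bounded in
#' \[0.1, 20\] and the midpoint within 1000-fold of the tested range.
#' Optimisation is a deterministic multi-start (slope inits 0.5, 1, 4)
#' L-BFGS-B taking the lowest residual sum of squares; failures return
#' `converged = FALSE`, never an error.
#'
#' @param conc Concentrations in uM (> 0).
#' @param values Vehicle-relative responses (unshifted; the upward shift is
#'   applied internally).
#' @param shape `"up"` or `"down"`.
#' @return An object of class `hill_fit`: `shape`, `top`, `bottom`,
#'   `ac50_param` (uM), `hillslope`, `rss`, `converged`, `n`.
#' @export
fit_hill <- function(conc, values, shape = c("down", "up")) {
  shape <- match.arg(shape)
  ok <- is.finite(conc) & is.finite(values) & conc > 0
  conc <- conc[ok]
  y <- values[ok]
  fail <- structure(list(shape = shape, top = NA_real_, bottom = NA_real_,
                         ac50_param = NA_real_, hillslope = NA_real_,
                         rss = NA_real_, converged = FALSE, n = length(y)),
                    class = "hill_fit")
  if (length(y) < 4) return(fail)
  if (shape == "up") y <- y - 1
  lk_lo <- log10(min(conc)) - 3
  lk_hi <- log10(max(conc)) + 3
  obj <- function(par) {
    pred <- hill_predict(conc, shape, bottom = par[1], top = par[1],
                         ac50 = 10^par[2], slope = par[3])
    sum((pred - y)^2)
  }
  # par = (bottom|top, log10 ac50, slope)
  amp_bounds <- if (shape == "down") c(0, 1) else c(0, 10)
  # The amplitude enters the model linearly for fixed (ac50, slope):
  # down: y = 1 - frac + b*frac; up: y' = top*frac. A deterministic coarse
  # grid over (log10 ac50, slope) with the analytic amplitude gives robust
  # starts; the 4-point design has ridge-shaped least-squares surfaces that
  # strand a single-start quasi-Newton search.
  amp_hat <- function(frac) {
    num <- if (shape == "down") sum(frac * (y - 1 + frac)) else sum(frac * y)
    a <- if (sum(frac^2) > 0) num / sum(frac^2) else 0
    min(max(a, amp_bounds[1]), amp_bounds[2])
  }
  starts <- list()
  for (lk in seq(log10(min(conc)) - 2, log10(max(conc)) + 2, length.out = 21)) {
    for (h0 in c(0.25, 0.5, 1, 2, 4, 8, 16)) {
      frac <- hill_fraction(conc, 10^lk, h0)
      par <- c(amp_hat(frac), lk, h0)
      starts[[length(starts) + 1L]] <- list(par = par, rss = obj(par))
    }
  }
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "rss"))]
  best <- NULL
  for (s in starts[seq_len(min(5, length(starts)))]) {
    res <- tryCatch(
      stats::optim(s$par, obj, method = "L-BFGS-B",
                   lower = c(amp_bounds[1], lk_lo, 0.1),
                   upper = c(amp_bounds[2], lk_hi, 20),
                   control = list(factr = 10, maxit = 1000)),
      error = function(e) NULL
    )
    if (is.null(res) || !all(is.finite(res$par))) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) return(fail)
  p <- best$par
  structure(list(
    shape = shape,
    top = if (shape == "down") 1 else p[1],
    bottom = if (shape == "down") p[1] else 0,
    ac50_param = 10^p[2],
    hillslope = p[3],
    rss = best$value,
    converged = TRUE,
    n = length(y)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s trend): ac50 = %.4g uM, slope = %.3g, ", x$shape,
              x$ac50_param, x$hillslope),
      sprintf("top = %.3g, bottom = %.3g, rss = %.3g, converged = %s\n",
              x$top, x$bottom, x$rss, x$converged), sep = "")
  invisible(x)
}

#' AC50 assignment from a fitted curve
#'
#' The AC50 is the concentration at which the fitted curve produces a 50%
#' change from the 0-concentration control (response 0.5 on the downward
#' scale; 0.5 on the shifted upward scale, i.e. a relative response of 1.5).
#' If the fitted curve never attains a 50% change, the combination is
#' inactive and carries the default AC50 of 1 M. Crossings above the top
#' tested concentration are retained and flagged `extrapolated`; a crossing
#' at or beyond 1 M itself collapses to the inactive default.
#'
#' @param fit A [fit_hill()] result.
#' @param max_conc_uM Highest tested concentration (uM), used for the
#'   extrapolation flag.
#' @return A list: `active`, `ac50_uM`, `ac50_M`, `extrapolated`.
#' @export
ac50_from_fit <- function(fit, max_conc_uM) {
  inactive <- list(active = FALSE, ac50_uM = NA_real_,
                   ac50_M = INACTIVE_AC50_M, extrapolated = FALSE)
  if (!fit$converged) return(inactive)
  if (fit$shape == "down") {
    # bottom + (1-b) K^h/(K^h+c^h) = 0.5  =>  c = K * (0.5/(0.5-b))^(1/h)
    if (fit$bottom >= 0.5) return(inactive)
    c50 <- fit$ac50_param * (0.5 / (0.5 - fit$bottom))^(1 / fit$hillslope)
  } else {
    # top c^h/(c^h+K^h) = 0.5  =>  c = K * (0.5/(top-0.5))^(1/h)
    if (fit$top <= 0.5) return(inactive)
    c50 <- fit$ac50_param * (0.5 / (fit$top - 0.5))^(1 / fit$hillslope)
  }
  if (!is.finite(c50) || c50 <= 0) return(inactive)
  ac50_M <- c50 * 1e-6
  if (ac50_M >= INACTIVE_AC50_M) return(inactive)
  list(active = TRUE, ac50_uM = c50, ac50_M = ac50_M,
       extrapolated = c50 > max_conc_uM)
}

#' AC_F: concentration producing an F-percent change
#'
#' Inversion of the Hill curve around its midpoint: the concentration at
#' which the fitted response changes by F percent relative to the
#' 0-concentration control,
#' `AC_F = AC50 * (F / (100 - F))^(1 / |Hillslope|)`.
#' `ac_f(ac50, slope, 50)` is the AC50 itself; AC_F is monotone increasing
#' in F.
#'
#' @param ac50 AC50 (any concentration unit; the result is in the same unit).
#' @param hillslope Hill slope of the fitted curve (nonzero).
#' @param F Percent change in (0, 100), exclusive.
#' @return The AC_F concentration.
#' @export
ac_f <- function(ac50, hillslope, F) {
  if (any(!is.finite(F)) || any(F <= 0) || any(F >= 100)) {
    stop("F must lie strictly between 0 and 100", call. = FALSE)
  }
  if (any(ac50 <= 0)) stop("ac50 must be > 0", call. = FALSE)
  if (any(hillslope == 0)) stop("hillslope must be nonzero", call. = FALSE)
  ac50 * (F / (100 - F))^(1 / abs(hillslope))
}

axis_endpoints <- function(axis, shape) {
  if (axis == "cell_number") {
    if (shape == "down") "cell_loss" else "cell_gain"
  } else {
    if (shape == "down") "diff_decrease" else "diff_increase"
  }
}

call_one_axis <- function(chemical, axis, points, controls, max_conc_uM) {
  eps <- c("cell_loss", "cell_gain")
  if (axis == "differentiation") eps <- c("diff_decrease", "diff_increase")
  blank <- data.frame(
    chemical = chemical,
    endpoint = eps,
    active = FALSE, shape = "none",
    ac50_uM = NA_real_, ac50_M = INACTIVE_AC50_M,
    hillslope = NA_real_, top = NA_real_, bottom = NA_real_,
    extrapolated = FALSE, rss = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(points) == 0 || length(controls) < 2) {
    blank$shape <- "missing"
    return(blank)
  }
  band <- control_band(controls)
  shape <- classify_activity(points$value, band)
  if (shape == "none") return(blank)
  if (shape == "ushape") {
    blank$shape <- "ushape"
    return(blank)
  }
  fit <- fit_hill(points$conc_uM, points$value, shape)
  call <- ac50_from_fit(fit, max_conc_uM)
  hit <- axis_endpoints(axis, shape)
  out <- blank
  i <- out$endpoint == hit
  out$shape[i] <- shape
  out$active[i] <- call$active
  out$ac50_uM[i] <- call$ac50_uM
  out$ac50_M[i] <- call$ac50_M
  out$extrapolated[i] <- call$extrapolated
  out$hillslope[i] <- fit$hillslope
  out$top[i] <- fit$top
  out$bottom[i] <- fit$bottom
  out$rss[i] <- fit$rss
  out
}

#' Call activity for a whole screen
#'
#' For every chemical and both endpoint axes: build the 0-concentration
#' control band from the vehicle wells of the chemical's plate(s), classify
#' the trend, fit the trend-specific Hill curve and assign the AC50. Each
#' chemical yields one row per endpoint (`cell_loss`, `cell_gain`,
#' `diff_decrease`, `diff_increase`); inactive combinations carry the 1 M
#' default. Nonmonotone axes are reported with `shape = "ushape"` and no
#' AC50.
#'
#' @param responses Long response table from [process_plates()].
#' @return A `data.frame` of activity calls: `chemical`, `endpoint`,
#'   `active`, `shape`, `ac50_uM`, `ac50_M`, `hillslope`, `top`, `bottom`,
#'   `extrapolated`, `rss`.
#' @export
call_screen <- function(responses) {
  ok <- responses[responses$qc_flag == "ok" & is.finite(responses$value), ,
                  drop = FALSE]
  chems <- sort(unique(ok$chemical[ok$chemical != "VEHICLE"]))
  max_conc <- max(ok$conc_uM)
  out <- list()
  for (chem in chems) {
    rows <- ok[ok$chemical == chem, , drop = FALSE]
    plates <- unique(rows$plate_id)
    veh <- ok[ok$chemical == "VEHICLE" & ok$plate_id %in% plates, ,
              drop = FALSE]
    for (axis in AXES) {
      pts <- rows[rows$endpoint_axis == axis & rows$conc_uM > 0, ,
                  drop = FALSE]
      ctrl <- veh$value[veh$endpoint_axis == axis]
      out[[length(out) + 1L]] <-
        call_one_axis(chem, axis, pts, ctrl, max_conc)
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Write/read activity-call tables
#'
#' @param calls Activity-call `data.frame` from [call_screen()].
#' @param path File path.
#' @return `read_calls` returns the call `data.frame`.
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
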