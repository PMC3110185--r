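# Synthetic plate/screen generator with known Hill-response ground truth.
#
# The simulated world mirrors the screen design the analysis assumes: 96-well
# plates, eight chemicals per plate (one per row) at four concentrations in
# duplicate wells, dedicated vehicle columns and antibody-free (no-stain)
# background wells, two infrared channels (700 = cell stain, 800 = MYH6/MYH7),
# multiplicative log-normal intensity noise plus additive background.

ENDPOINTS <- c("cell_loss", "cell_gain", "diff_decrease", "diff_increase")
AXES <- c("cell_number", "differentiation")

#' Plate layout specification
#'
#' Describes a 96-well screening plate: one chemical per row, each tested
#' concentration plated in duplicate wells within the row, plus dedicated
#' vehicle (0-concentration DMSO) columns and no-stain background wells.
#'
#' @param n_rows,n_cols Plate dimensions (default 8 x 12, a 96-well plate).
#' @param chemicals_per_plate Number of chemicals per plate (default 8,
#'   one per row).
#' @param concentrations Tested concentrations in micromolar, strictly
#'   increasing. Default `c(0.0125, 0.125, 1.25, 12.5)`, a 3-decade series
#'   capped at 12.5 uM by vehicle (DMSO) tolerance.
#' @param replicate_wells Wells per chemical x concentration within a row
#'   (default 2).
#' @param vehicle_cols Column indices carrying vehicle control wells.
#' @param nostain_cols Column indices reserved for antibody/stain-free
#'   background wells.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(n_rows = 8, n_cols = 12,
                         chemicals_per_plate = 8,
                         concentrations = c(0.0125, 0.125, 1.25, 12.5),
                         replicate_wells = 2,
                         vehicle_cols = 9:11,
                         nostain_cols = 12) {
  if (length(concentrations) < 1 || any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (length(vehicle_cols) < 1) {
    stop("at least one vehicle column is required", call. = FALSE)
  }
  if (length(intersect(vehicle_cols, nostain_cols)) > 0) {
    stop("vehicle and no-stain wells must be disjoint", call. = FALSE)
  }
  if (chemicals_per_plate > n_rows) {
    stop("more chemicals per plate than rows", call. = FALSE)
  }
  treated_cols <- setdiff(seq_len(n_cols), c(vehicle_cols, nostain_cols))
  need <- length(concentrations) * replicate_wells
  if (length(treated_cols) < need) {
    stop(sprintf(
      "layout needs %d treated columns for %d concentrations x %d replicates, has %d",
      need, length(concentrations), replicate_wells, length(treated_cols)
    ), call. = FALSE)
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      chemicals_per_plate = chemicals_per_plate,
      concentrations = concentrations,
      replicate_wells = replicate_wells,
      vehicle_cols = as.integer(vehicle_cols),
      nostain_cols = as.integer(nostain_cols),
      treated_cols = as.integer(treated_cols[seq_len(need)])
    ),
    class = "plate_layout"
  )
}

#' Intensity noise model
#'
#' Raw channel intensities are perturbed by multiplicative log-normal noise
#' (unit mean, coefficient of variation `cv_intensity`) and an additive
#' Gaussian background common to both channels. Defaults reproduce the
#' sub-22% replicate CV regime reported for the assay: 5% intensity CV and a
#' background of 5% of the default vehicle intensity.
#'
#' @param cv_intensity Coefficient of variation of the per-channel
#'   multiplicative noise (>= 0).
#' @param background_mean,background_sd Mean and SD of the additive
#'   background intensity (arbitrary units).
#' @param seed Integer seed; identical seeds give identical plates.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_intensity = 0.05, background_mean = 500,
                        background_sd = 100, seed = 1L) {
  if (cv_intensity < 0) stop("cv_intensity must be >= 0", call. = FALSE)
  if (background_sd < 0) stop("background_sd must be >= 0", call. = FALSE)
  structure(
    list(cv_intensity = cv_intensity, background_mean = background_mean,
         background_sd = background_sd, seed = as.integer(seed)),
    class = "noise_model"
  )
}

axis_of_endpoint <- function(endpoint) {
  ifelse(endpoint %in% c("cell_loss", "cell_gain", "ushape_cell"),
         "cell_number",
         ifelse(endpoint %in% c("diff_decrease", "diff_increase",
                                "ushape", "ushape_diff"),
                "differentiation", NA_character_))
}

#' Ground-truth chemical
#'
#' A chemical's true effects, one per endpoint axis at most. Endpoints
#' `cell_loss`/`cell_gain` act on the cell-number axis, `diff_decrease`/
#' `diff_increase` on the differentiation axis; `ushape` (nonmonotone,
#' differentiation axis) and `ushape_cell` give the nonmonotone class a
#' generative definition; `none` marks an inactive chemical.
#'
#' @param name Chemical identifier.
#' @param effects `data.frame` with columns `endpoint`, `true_ac50`
#'   (Hill midpoint, uM), `hill_slope` (> 0) and `max_effect` (fractional
#'   change of the vehicle signal at saturation; in `[0, 1]` for losses,
#'   >= 0 for gains). Omit or pass endpoint `"none"` for inactive chemicals.
#' @return An object of class `truth_chemical`.
#' @export
truth_chemical <- function(name, effects = NULL) {
  if (is.null(effects) || nrow(effects) == 0) {
    effects <- data.frame(endpoint = "none", true_ac50 = NA_real_,
                          hill_slope = NA_real_, max_effect = NA_real_)
  }
  effects <- as.data.frame(effects)
  real <- effects[effects$endpoint != "none", , drop = FALSE]
  if (nrow(real) > 0) {
    bad <- !(real$endpoint %in% c(ENDPOINTS, "ushape", "ushape_cell"))
    if (any(bad)) {
      stop("unknown endpoint: ", paste(real$endpoint[bad], collapse = ", "),
           call. = FALSE)
    }
    if (any(real$true_ac50 <= 0)) stop("true_ac50 must be > 0", call. = FALSE)
    if (any(real$hill_slope <= 0)) stop("hill_slope must be > 0", call. = FALSE)
    loss <- real$endpoint %in% c("cell_loss", "diff_decrease")
    if (any(real$max_effect[loss] < 0 | real$max_effect[loss] > 1)) {
      stop("max_effect for losses must lie in [0, 1]", call. = FALSE)
    }
    if (any(real$max_effect < 0)) stop("max_effect must be >= 0", call. = FALSE)
    ax <- axis_of_endpoint(real$endpoint)
    if (anyDuplicated(ax)) {
      stop("at most one effect per endpoint axis", call. = FALSE)
    }
  }
  structure(list(name = as.character(name), effects = effects),
            class = "truth_chemical")
}

# Saturable Hill occupancy c^h / (c^h + ac50^h); 0 at c = 0.
hill_fraction <- function(conc, ac50, slope) {
  ifelse(conc <= 0, 0, 1 / (1 + (ac50 / conc)^slope))
}

# True vehicle-relative response of one axis at the given concentrations.
# Losses: 1 - max_effect * hill; gains: 1 + max_effect * hill; u-shape: a
# gain term at low concentration plus a stronger, right-shifted loss term.
axis_true_response <- function(chem, axis, conc) {
  eff <- chem$effects
  eff <- eff[eff$endpoint != "none" & axis_of_endpoint(eff$endpoint) == axis, ,
             drop = FALSE]
  if (nrow(eff) == 0) return(rep(1, length(conc)))
  e <- eff[1, ]
  h <- hill_fraction(conc, e$true_ac50, e$hill_slope)
  resp <- switch(
    sub("_cell$|_diff$", "", e$endpoint),
    cell_loss = ,
    diff_decrease = 1 - e$max_effect * h,
    cell_gain = ,
    diff_increase = 1 + e$max_effect * h,
    ushape = 1 + e$max_effect * h -
      2 * e$max_effect * hill_fraction(conc, 20 * e$true_ac50,
                                       2 * e$hill_slope)
  )
  pmax(resp, 0)
}

# Analytic concentration at which the true curve reaches a 50% change from
# vehicle; NA when the saturating effect never reaches 50% or the shape is
# nonmonotone. This is what the AC50 estimator targets when max_effect != 1.
true_c50 <- function(endpoint, true_ac50, hill_slope, max_effect) {
  if (is.na(true_ac50) || !endpoint %in% ENDPOINTS) return(NA_real_)
  if (max_effect <= 0.5) return(NA_real_)
  true_ac50 * (0.5 / (max_effect - 0.5))^(1 / hill_slope)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate one screening plate
#'
#' Generates two-channel well intensities for up to `chemicals_per_plate`
#' chemicals. The expected channel-700 signal of a treated well is the
#' vehicle intensity times the chemical's cell-number Hill response; the
#' expected channel-800 signal is channel-700 times the differentiation Hill
#' response times the baseline 800/700 ratio. No-stain wells carry background
#' only. With `cv_intensity = 0` and `background_sd = 0` the generation is an
#' exact evaluation of the Hill responses.
#'
#' @param spec A [plate_layout()].
#' @param chems List of [truth_chemical()] objects, at most one per row.
#' @param noise A [noise_model()].
#' @param plate_id Plate identifier.
#' @param vehicle_intensity Expected channel-700 intensity of vehicle wells
#'   (arbitrary units).
#' @param baseline_ratio Channel-800 / channel-700 ratio of vehicle wells.
#' @return A `data.frame` of wells with columns `plate_id`, `row`, `col`,
#'   `chemical`, `conc_uM`, `channel700`, `channel800`, `is_vehicle`,
#'   `is_nostain`.
#' @export
generate_plate <- function(spec = plate_layout(), chems,
                           noise = noise_model(), plate_id = "P1",
                           vehicle_intensity = 10000, baseline_ratio = 0.4) {
  if (inherits(chems, "truth_chemical")) chems <- list(chems)
  if (length(chems) > spec$chemicals_per_plate) {
    stop("more chemicals than plate rows available", call. = FALSE)
  }
  with_seed(noise$seed, {
    rows <- list()
    mk <- function(row, col, chemical, conc, mu700, mu800) {
      data.frame(plate_id = plate_id, row = row, col = col,
                 chemical = chemical, conc_uM = conc,
                 mu700 = mu700, mu800 = mu800,
                 is_vehicle = chemical == "VEHICLE",
                 is_nostain = chemical == "NOSTAIN")
    }
    conc_by_col <- rep(spec$concentrations, each = spec$replicate_wells)
    for (r in seq_len(spec$n_rows)) {
      chem <- if (r <= length(chems)) chems[[r]] else NULL
      for (j in seq_along(spec$treated_cols)) {
        cc <- conc_by_col[j]
        if (is.null(chem)) next
        cell <- axis_true_response(chem, "cell_number", cc)
        diff <- axis_true_response(chem, "differentiation", cc)
        mu700 <- vehicle_intensity * cell
        mu800 <- mu700 * diff * baseline_ratio
        rows[[length(rows) + 1L]] <-
          mk(r, spec$treated_cols[j], chem$name, cc, mu700, mu800)
      }
      for (col in spec$vehicle_cols) {
        rows[[length(rows) + 1L]] <-
          mk(r, col, "VEHICLE", 0, vehicle_intensity,
             vehicle_intensity * baseline_ratio)
      }
      for (col in spec$nostain_cols) {
        rows[[length(rows) + 1L]] <- mk(r, col, "NOSTAIN", 0, 0, 0)
      }
    }
    wells <- do.call(rbind, rows)
    n <- nrow(wells)
    sdlog <- sqrt(log(1 + noise$cv_intensity^2))
    lnfac <- function(n) {
      if (sdlog == 0) rep(1, n) else exp(rnorm(n, -sdlog^2 / 2, sdlog))
    }
    bg <- function(n) {
      if (noise$background_sd == 0) rep(noise$background_mean, n)
      else rnorm(n, noise$background_mean, noise$background_sd)
    }
    wells$channel700 <- wells$mu700 * lnfac(n) + bg(n)
    wells$channel800 <- wells$mu800 * lnfac(n) + bg(n)
    wells$mu700 <- NULL
    wells$mu800 <- NULL
    wells$qc_flag <- "ok"
    rownames(wells) <- NULL
    wells
  })
}

#' Default ground-truth sampler settings
#'
#' Parameter ranges from which screen-level ground truth is drawn. Defaults
#' state the screen the analysis emulates: 18% of the library active (56/309
#' in the motivating screen), potencies log-uniform over the printed AC50
#' span 0.02-18 uM, and an activity-pattern mix matching the observed
#' preponderance of decreased cell number / decreased differentiation, with
#' a small nonmonotone class (5/309 observed).
#'
#' @param p_active Probability a chemical has any effect.
#' @param pattern_weights Named weights over activity patterns among active
#'   chemicals.
#' @param ac50_range Log-uniform range of Hill midpoints (uM).
#' @param slope_range Uniform range of Hill slopes.
#' @param loss_effect_range,gain_effect_range Uniform ranges of `max_effect`
#'   for losses and gains.
#' @return A list of sampler settings.
#' @export
truth_sampler <- function(p_active = 0.18,
                          pattern_weights = c(cell_loss = 0.20,
                                              diff_decrease = 0.25,
                                              both_loss = 0.25,
                                              cell_gain = 0.14,
                                              diff_increase = 0.07,
                                              ushape = 0.09),
                          ac50_range = c(0.02, 18),
                          slope_range = c(0.8, 4),
                          loss_effect_range = c(0.6, 1),
                          gain_effect_range = c(0.7, 1.5)) {
  for (rng in list(ac50_range, slope_range, loss_effect_range,
                   gain_effect_range)) {
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[2] < rng[1]) {
      stop("parameter ranges must be finite length-2 increasing vectors",
           call. = FALSE)
    }
  }
  if (length(pattern_weights) == 0 || sum(pattern_weights) <= 0) {
    stop("pattern_weights must be nonempty with positive sum", call. = FALSE)
  }
  list(p_active = p_active, pattern_weights = pattern_weights,
       ac50_range = ac50_range, slope_range = slope_range,
       loss_effect_range = loss_effect_range,
       gain_effect_range = gain_effect_range)
}

sample_effect <- function(endpoint, sampler) {
  loss <- endpoint %in% c("cell_loss", "diff_decrease")
  er <- if (loss) sampler$loss_effect_range else sampler$gain_effect_range
  data.frame(
    endpoint = endpoint,
    true_ac50 = exp(runif(1, log(sampler$ac50_range[1]),
                          log(sampler$ac50_range[2]))),
    hill_slope = runif(1, sampler$slope_range[1], sampler$slope_range[2]),
    max_effect = runif(1, er[1], er[2])
  )
}

sample_truth_chemicals <- function(n, sampler) {
  patterns <- names(sampler$pattern_weights)
  prob <- sampler$pattern_weights / sum(sampler$pattern_weights)
  lapply(seq_len(n), function(i) {
    name <- sprintf("CHEM%03d", i)
    if (runif(1) >= sampler$p_active) return(truth_chemical(name))
    pat <- sample(patterns, 1, prob = prob)
    eff <- switch(
      pat,
      both_loss = rbind(sample_effect("cell_loss", sampler),
                        sample_effect("diff_decrease", sampler)),
      sample_effect(pat, sampler)
    )
    truth_chemical(name, eff)
  })
}

#' Simulate a multi-plate screen with ground truth
#'
#' Draws `n_chemicals` ground-truth chemicals, lays them out on
#' `ceiling(slots / chemicals_per_plate)` plates and simulates every plate.
#' The first `n_qc_triplicates` chemicals are plated on three row slots each
#' (plating replicates for internal quality control, mirroring the screen's
#' triplicated chemicals).
#'
#' @param n_chemicals Number of distinct chemicals (>= 1).
#' @param sampler Settings from [truth_sampler()].
#' @param spec A [plate_layout()].
#' @param noise A [noise_model()]; its seed drives truth sampling and every
#'   plate (per-plate seeds are derived deterministically).
#' @param n_qc_triplicates Number of chemicals plated in triplicate.
#' @param ... Passed to [generate_plate()].
#' @return A list with `wells` (all plates, row-bound), `truth` (long
#'   `data.frame`: `chemical`, `endpoint`, `true_ac50_uM`, `hill_slope`,
#'   `max_effect`, `true_c50_uM`; one `"none"` row per inactive chemical) and
#'   `chemicals` (the `truth_chemical` list).
#' @export
generate_screen <- function(n_chemicals, sampler = truth_sampler(),
                            spec = plate_layout(), noise = noise_model(),
                            n_qc_triplicates = 0, ...) {
  if (n_chemicals < 1) stop("n_chemicals must be >= 1", call. = FALSE)
  if (n_qc_triplicates > n_chemicals) {
    stop("n_qc_triplicates cannot exceed n_chemicals", call. = FALSE)
  }
  chems <- with_seed(noise$seed, sample_truth_chemicals(n_chemicals, sampler))
  slots <- seq_len(n_chemicals)
  if (n_qc_triplicates > 0) {
    slots <- c(slots, rep(seq_len(n_qc_triplicates), each = 2))
  }
  n_plates <- ceiling(length(slots) / spec$chemicals_per_plate)
  plates <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    idx <- slots[seq((p - 1) * spec$chemicals_per_plate + 1,
                     min(p * spec$chemicals_per_plate, length(slots)))]
    pn <- noise
    pn$seed <- (noise$seed * 1009L + p) %% .Machine$integer.max
    plates[[p]] <- generate_plate(spec, chems[idx], pn,
                                  plate_id = sprintf("P%02d", p), ...)
  }
  truth <- do.call(rbind, lapply(chems, function(ch) {
    eff <- ch$effects
    data.frame(chemical = ch$name, endpoint = eff$endpoint,
               true_ac50_uM = eff$true_ac50, hill_slope = eff$hill_slope,
               max_effect = eff$max_effect,
               true_c50_uM = mapply(true_c50, eff$endpoint, eff$true_ac50,
                                    eff$hill_slope, eff$max_effect))
  }))
  rownames(truth) <- NULL
  list(wells = do.call(rbind, plates), truth = truth, chemicals = chems)
}

#' Write/read simulator artifacts
#'
#' Plain-CSV serialization of the well table and truth table, and YAML for
#' layout/noise configuration.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `read_wells` returns the well `data.frame`.
#' @export
write_wells <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wells
#' @export
read_wells <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "row", "col", "chemical", "conc_uM",
              "channel700", "channel800")
  miss <- setdiff(needed, names(wells))
  if (length(miss) > 0) {
    stop("well table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(wells$qc_flag)) wells$qc_flag <- "ok"
  wells
}
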