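# Screen-level reporting: Table-1-style summaries of activity calls, the
# packaged published-screen AC50 fixture, Ward/Euclidean clustering for
# heatmap ordering, and the end-to-end pipeline driver.

#' Load the packaged published-screen AC50 table
#'
#' AC50 values (uM) for the 56 chemicals with calculated AC50s in a
#' published 309-chemical mouse ES-cell differentiation/cytotoxicity screen,
#' transcribed verbatim with endpoint labels resolved from the screen's
#' results narrative (`cell_loss` = increased cytotoxicity, `cell_gain` =
#' increased cell number, `diff_decrease`/`diff_increase` literal).
#'
#' @return `data.frame`: `chemical`, `endpoint`, `ac50_uM`.
#' @export
published_ac50 <- function() {
  path <- system.file("extdata", "published_screen_ac50.csv",
                      package = "escreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize a screen's activity calls
#'
#' All quantities are recomputed from the call table: per-endpoint active
#' counts and AC50 extrema (with chemical names), the number and fraction of
#' chemicals with at least one AC50, potency-range counts and the number of
#' nonmonotone (u-shaped) chemicals.
#'
#' @param calls Activity-call table from [call_screen()], or a fixture-style
#'   table (`chemical`, `endpoint`, `ac50_uM`) in which every row is an
#'   active call.
#' @param library_size Total chemicals screened, used for the active
#'   fraction; defaults to the number of distinct chemicals in `calls`.
#' @return An object of class `screen_summary`.
#' @export
summarize_actives <- function(calls, library_size = NULL) {
  bad <- setdiff(unique(calls$endpoint), c(ENDPOINTS, "none"))
  if (length(bad) > 0) {
    stop("unknown endpoint label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(calls$active)) {
    calls$active <- is.finite(calls$ac50_uM)
  }
  act <- calls[calls$active & is.finite(calls$ac50_uM), , drop = FALSE]
  per_endpoint <- lapply(stats::setNames(ENDPOINTS, ENDPOINTS), function(ep) {
    a <- act[act$endpoint == ep, , drop = FALSE]
    if (nrow(a) == 0) {
      return(list(n_active = 0L, min_ac50_uM = NA_real_,
                  min_chemical = NA_character_, max_ac50_uM = NA_real_,
                  max_chemical = NA_character_))
    }
    list(n_active = nrow(a),
         min_ac50_uM = min(a$ac50_uM),
         min_chemical = a$chemical[which.min(a$ac50_uM)],
         max_ac50_uM = max(a$ac50_uM),
         max_chemical = a$chemical[which.max(a$ac50_uM)])
  })
  n_chem_active <- length(unique(act$chemical))
  if (is.null(library_size)) library_size <- length(unique(calls$chemical))
  n_ushape <- if (is.null(calls$shape)) 0L else {
    length(unique(calls$chemical[calls$shape == "ushape"]))
  }
  structure(list(
    per_endpoint = per_endpoint,
    n_ac50 = nrow(act),
    n_chemicals_active = n_chem_active,
    library_size = library_size,
    fraction_active = n_chem_active / library_size,
    n_submicromolar = sum(act$ac50_uM < 1),
    n_over_10uM = sum(act$ac50_uM >= 10),
    n_ushape_chemicals = n_ushape
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screen summary: %d/%d chemicals with >= 1 AC50 (%.1f%%); %d AC50 values\n",
              x$n_chemicals_active, x$library_size,
              100 * x$fraction_active, x$n_ac50))
  for (ep in names(x$per_endpoint)) {
    pe <- x$per_endpoint[[ep]]
    if (pe$n_active == 0) {
      cat(sprintf("  %-13s  0 active\n", ep))
    } else {
      cat(sprintf("  %-13s %2d active; most potent %s (%.3g uM), least potent %s (%.3g uM)\n",
                  ep, pe$n_active, pe$min_chemical, pe$min_ac50_uM,
                  pe$max_chemical, pe$max_ac50_uM))
    }
  }
  cat(sprintf("  sub-micromolar AC50s: %d; AC50s >= 10 uM: %d; u-shaped chemicals: %d\n",
              x$n_submicromolar, x$n_over_10uM, x$n_ushape_chemicals))
  invisible(x)
}

#' Two-dimensional hierarchical clustering for heatmap ordering
#'
#' Agglomerative clustering with Euclidean distance and Ward's
#' minimum-variance linkage (`stats::hclust(method = "ward.D2")` on
#' unsquared Euclidean distances), applied to rows and, optionally, columns
#' independently. A constant matrix is valid and yields zero-height merges.
#'
#' @param mat Numeric matrix of relative activities (>= 2 rows).
#' @param cluster_cols Also cluster columns (needs >= 2 columns).
#' @return An object of class `cluster_result`: `row_order`, `col_order`,
#'   `row_tree`, `col_tree` (hclust objects), `metric`, `linkage`.
#' @export
hcluster <- function(mat, cluster_cols = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("clustering needs >= 2 rows", call. = FALSE)
  rt <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  ct <- NULL
  col_order <- seq_len(ncol(mat))
  if (cluster_cols && ncol(mat) >= 2) {
    ct <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                        method = "ward.D2")
    col_order <- ct$order
  }
  structure(list(row_order = rt$order, col_order = col_order,
                 row_tree = rt, col_tree = ct,
                 metric = "euclidean", linkage = "ward.D2"),
            class = "cluster_result")
}

default_config <- function() {
  list(
    seed = 1L,
    n_chemicals = 24L,
    p_active = 0.5,          # demo screens are enriched for actives so the
    n_qc_triplicates = 3L,   # association/model stages have signal to find
    cv_intensity = 0.05,
    alpha = 0.1,
    k_folds = 3L,
    n_assays = 12L,
    n_informative = 3L,
    model_output = "diff_decrease"
  )
}

#' Synthetic external assay columns
#'
#' Companion columns for the association and model stages of a synthetic
#' run: `n_informative` columns whose activity tracks the ground truth of
#' `target` (active chemicals are detected with probability `p_detect` at a
#' potency jittered around truth), the rest independent noise columns, plus
#' one synthetic in-vivo LEL column tracking any ES activity.
#'
#' @param truth Truth table from [generate_screen()].
#' @param n_assays Total number of in-vitro columns.
#' @param n_informative Number of truth-tracking columns.
#' @param target Endpoint whose truth the informative columns track.
#' @param p_detect Detection probability of an informative column.
#' @param seed Integer seed.
#' @return An `assay_matrix` of external columns.
#' @export
synthetic_assay_columns <- function(truth, n_assays = 12, n_informative = 3,
                                    target = "diff_decrease", p_detect = 0.85,
                                    seed = 1L) {
  chems <- unique(truth$chemical)
  on_target <- chems %in% truth$chemical[truth$endpoint == target]
  any_active <- chems %in% truth$chemical[truth$endpoint != "none"]
  target_ac50_M <- truth$true_ac50_uM[match(chems, truth$chemical)] * 1e-6
  with_seed(seed, {
    cols <- list()
    kinds <- character(0)
    for (i in seq_len(n_assays)) {
      informative <- i <= n_informative
      v <- rep(INACTIVE_AC50_M, length(chems))
      if (informative) {
        hit <- on_target & stats::runif(length(chems)) < p_detect
        v[hit] <- pmin(0.9, target_ac50_M[hit] *
                         exp(stats::rnorm(sum(hit), 0, 0.3)))
        bg <- !on_target & stats::runif(length(chems)) < 0.05
        v[bg] <- 10^stats::runif(sum(bg), -8, -5)
      } else {
        bg <- stats::runif(length(chems)) < 0.25
        v[bg] <- 10^stats::runif(sum(bg), -8, -5)
      }
      cols[[sprintf("ASSAY%02d", i)]] <- v
      kinds <- c(kinds, "in_vitro_ac50")
    }
    lel <- rep(LEL_INACTIVE, length(chems))
    hit <- any_active & stats::runif(length(chems)) < 0.7
    lel[hit] <- 10^stats::runif(sum(hit), 0, 2)
    cols[["LEL_dev"]] <- lel
    kinds <- c(kinds, "in_vivo_lel")
    m <- do.call(cbind, cols)
    rownames(m) <- chems
    assay_matrix(m, kinds)
  })
}

#' Run the full synthetic pipeline
#'
#' simulate -> process -> call -> associate -> model -> report. Writes all
#' artifacts (CSV/JSON) plus a run log into `out_dir`. Identical config and
#' seed give identical artifacts (the log's timestamp line aside).
#'
#' @param config A configuration list or path to a YAML file; missing fields
#'   fall back to the demo defaults (24 chemicals, seed 1).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("escreen_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("escreen %s | R %s | started %s",
       as.character(utils::packageVersion("escreen")),
       paste(R.version$major, R.version$minor, sep = "."),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("config: %s", jsonlite::toJSON(cfg, auto_unbox = TRUE))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    screen <- generate_screen(
      cfg$n_chemicals,
      sampler = truth_sampler(p_active = cfg$p_active),
      noise = noise_model(cv_intensity = cfg$cv_intensity, seed = cfg$seed),
      n_qc_triplicates = cfg$n_qc_triplicates
    )
    write_wells(screen$wells, file.path(out_dir, "plates.csv"))
    utils::write.csv(screen$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    screen
  })
  logf("simulate: %d chemicals on %d plates", cfg$n_chemicals,
       length(unique(sim$wells$plate_id)))

  responses <- stage("process", {
    r <- process_plates(sim$wells)
    utils::write.csv(r, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
    r
  })
  logf("process: %d response records", nrow(responses))

  calls <- stage("fit", {
    cl <- call_screen(responses)
    write_calls(cl, file.path(out_dir, "calls.csv"))
    cl
  })
  logf("fit: %d active calls of %d", sum(calls$active), nrow(calls))

  extra <- stage("assay_columns", {
    synthetic_assay_columns(sim$truth, cfg$n_assays, cfg$n_informative,
                            target = cfg$model_output,
                            seed = cfg$seed + 1L)
  })
  mat <- stage("matrix", {
    m <- build_matrix(calls, extra)
    write_assay_matrix(m, file.path(out_dir, "matrix.csv"))
    m
  })

  assoc <- stage("associate", {
    a <- association_screen(mat, inputs = ENDPOINTS,
                            outputs = setdiff(colnames(mat$values), ENDPOINTS),
                            alpha = cfg$alpha)
    utils::write.csv(a, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    a
  })
  logf("associate: %d tests, %d significant at alpha = %g", nrow(assoc),
       sum(assoc$significant), cfg$alpha)

  model <- stage("model", {
    output <- dichotomize(mat)[, cfg$model_output]
    cand <- colnames(mat$values)[mat$kind == "in_vitro_ac50"]
    cand <- setdiff(cand, ENDPOINTS)
    if (min(sum(output == 1), sum(output == 0)) < cfg$k_folds) {
      logf("model: skipped (class smaller than %d folds)", cfg$k_folds)
      NULL
    } else {
      sc <- scale_scores(assay_matrix(mat$values[, cand, drop = FALSE],
                                      mat$kind[cand]))
      fit <- fit_linmod(sc, output, k_folds = cfg$k_folds, seed = cfg$seed)
      write_linmod(fit, file.path(out_dir, "model.json"))
      pr <- predict(fit, sc)
      pr$truth <- output
      utils::write.csv(pr, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      roc <- roc_curve(pr$score, output)
      utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                       row.names = FALSE)
      fit
    }
  })
  if (!is.null(model)) {
    logf("model: Nmax = %d, Cutoff = %.4g, CV AUC = %.3f", model$Nmax,
         model$Cutoff, model$cv_metrics$mean_auc)
  }

  summary <- stage("report", {
    s <- summarize_actives(calls)
    jsonlite::write_json(unclass(s), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    s
  })
  clust <- stage("cluster", {
    sc <- scale_scores(assay_matrix(mat$values[, ENDPOINTS, drop = FALSE]))
    if (nrow(sc) >= 2) hcluster(sc) else NULL
  })
  logf("done")

  invisible(list(out_dir = out_dir, config = cfg, screen = sim,
                 responses = responses, calls = calls, matrix = mat,
                 associations = assoc, model = model, summary = summary,
                 clustering = clust))
}
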