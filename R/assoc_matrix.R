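# Chemical x assay data matrix: AC50 columns (molar, inactive = 1 M),
# in-vivo LEL columns (mg/kg/day with an explicit inactive sentinel),
# pathway perturbation scores, log-potency scaling, and the two univariate
# association tests (Fisher exact on dichotomized activity; Welch t on
# log-potency scores).

LEL_INACTIVE <- 1e6  # mg/kg/day sentinel for "no effective dose observed"

#' Construct a chemical x assay matrix
#'
#' @param values Numeric matrix, chemicals as rownames, assay/endpoint
#'   columns as colnames. AC50-kind columns are in molar with 1.0 = inactive;
#'   LEL columns in mg/kg/day with `1e6` = inactive.
#' @param kind Character vector (recycled) giving each column's kind:
#'   `"in_vitro_ac50"`, `"in_vivo_lel"` or `"pathway_ps"`.
#' @return An object of class `assay_matrix`.
#' @export
assay_matrix <- function(values, kind = "in_vitro_ac50") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have chemical rownames and column ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column ids", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate chemical ids", call. = FALSE)
  }
  kind <- rep_len(kind, ncol(values))
  if (!all(kind %in% c("in_vitro_ac50", "in_vivo_lel", "pathway_ps"))) {
    stop("unknown column kind", call. = FALSE)
  }
  ac50 <- kind != "in_vivo_lel"
  if (any(values[, ac50] <= 0 | values[, ac50] > 1, na.rm = TRUE)) {
    stop("AC50 values must lie in (0, 1] molar", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("matrix cells must be complete; inactivity is the default value, not absence",
         call. = FALSE)
  }
  names(kind) <- colnames(values)
  structure(list(values = values, kind = kind), class = "assay_matrix")
}

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("assay_matrix: %d chemicals x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Build the data matrix from activity calls
#'
#' Four ES-cell columns (`cell_loss`, `cell_gain`, `diff_decrease`,
#' `diff_increase`) holding molar AC50s with the 1 M inactive default, plus
#' any appended external columns.
#'
#' @param calls Activity-call table from [call_screen()] (or the packaged
#'   published-screen fixture via [published_ac50()]).
#' @param extra An optional `assay_matrix` of external columns over the same
#'   chemicals to append.
#' @return An `assay_matrix`.
#' @export
build_matrix <- function(calls, extra = NULL) {
  if (!all(c("chemical", "endpoint") %in% names(calls))) {
    stop("calls need chemical and endpoint columns", call. = FALSE)
  }
  bad <- setdiff(unique(calls$endpoint), c(ENDPOINTS, "none"))
  if (length(bad) > 0) {
    stop("unknown endpoint label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(calls$ac50_M)) calls$ac50_M <- calls$ac50_uM * 1e-6
  chems <- sort(unique(calls$chemical))
  m <- matrix(INACTIVE_AC50_M, nrow = length(chems), ncol = 4,
              dimnames = list(chems, ENDPOINTS))
  hit <- calls[calls$endpoint %in% ENDPOINTS & is.finite(calls$ac50_M) &
                 calls$ac50_M < INACTIVE_AC50_M, , drop = FALSE]
  if (nrow(hit) > 0) {
    m[cbind(hit$chemical, hit$endpoint)] <- hit$ac50_M
  }
  out <- assay_matrix(m, "in_vitro_ac50")
  if (!is.null(extra)) {
    ev <- extra$values[match(chems, rownames(extra$values)), , drop = FALSE]
    if (anyNA(ev)) stop("extra columns must cover all chemicals", call. = FALSE)
    rownames(ev) <- chems
    if (length(intersect(colnames(ev), colnames(m))) > 0) {
      stop("duplicate column ids", call. = FALSE)
    }
    out <- assay_matrix(cbind(m, ev), c(rep("in_vitro_ac50", 4), extra$kind))
  }
  out
}

inactive_value <- function(kind) {
  ifelse(kind == "in_vivo_lel", LEL_INACTIVE, INACTIVE_AC50_M)
}

#' Dichotomize a data matrix
#'
#' 1 if activity was seen at any concentration/dose (value below the
#' column's inactive default), else 0. Idempotent on its own output when that
#' output is re-wrapped with the same defaults.
#'
#' @param m An `assay_matrix`, or a numeric matrix of AC50s in molar.
#' @return Binary integer matrix.
#' @export
dichotomize <- function(m) {
  if (inherits(m, "assay_matrix")) {
    sent <- matrix(inactive_value(m$kind), nrow = nrow(m$values),
                   ncol = ncol(m$values), byrow = TRUE)
    v <- m$values
  } else {
    v <- as.matrix(m)
    if (all(v %in% c(0, 1))) return(v * 1L)  # already dichotomized
    sent <- matrix(INACTIVE_AC50_M, nrow(v), ncol(v))
  }
  out <- (v < sent) * 1L
  dimnames(out) <- dimnames(v)
  out
}

#' Log-potency scores
#'
#' The scaling applied to AC50 columns before the t-test and the additive
#' model: `score = -log10(AC50 in molar)`. The 1 M inactive default maps to
#' exactly 0; more potent chemicals score higher (1 uM -> 6). Defined for
#' AC50-kind columns only; LEL columns are excluded.
#'
#' @param m An `assay_matrix` or a numeric matrix/vector of molar AC50s.
#' @return Numeric matrix (or vector) of scores.
#' @export
scale_scores <- function(m) {
  if (inherits(m, "assay_matrix")) {
    keep <- m$kind != "in_vivo_lel"
    v <- m$values[, keep, drop = FALSE]
  } else {
    v <- m
  }
  if (any(v <= 0)) stop("AC50 values must be positive", call. = FALSE)
  -log10(v)
}

#' Fisher exact association between two dichotomized columns
#'
#' Builds the 2x2 contingency table (TP = input and output both positive,
#' FP = input positive only, FN = output positive only, TN = neither) and
#' tests association with a two-sided Fisher exact test. A degenerate margin
#' (all-0 or all-1 column) carries no information: p = 1, flagged.
#'
#' @param input,output Equal-length binary (0/1) vectors.
#' @param input_col,output_col Column labels carried into the result.
#' @return One-row `data.frame`: `input`, `output`, `method`, `statistic`
#'   (odds ratio estimate), `p_value`, `TP`, `FP`, `FN`, `TN`, `direction`,
#'   `degenerate`.
#' @export
fisher_association <- function(input, output, input_col = "input",
                               output_col = "output") {
  stopifnot(length(input) == length(output))
  tp <- sum(input == 1 & output == 1)
  fp <- sum(input == 1 & output == 0)
  fn <- sum(input == 0 & output == 1)
  tn <- sum(input == 0 & output == 0)
  degenerate <- (tp + fp) %in% c(0, length(input)) ||
    (tp + fn) %in% c(0, length(input))
  if (degenerate) {
    p <- 1
    or <- NA_real_
  } else {
    ft <- stats::fisher.test(matrix(c(tp, fn, fp, tn), 2), alternative = "two.sided")
    p <- ft$p.value
    or <- unname(ft$estimate)
  }
  data.frame(input = input_col, output = output_col, method = "fisher",
             statistic = or, p_value = p, TP = tp, FP = fp, FN = fn, TN = tn,
             direction = sign(tp * tn - fp * fn), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' t-test association between a score column and a dichotomized output
#'
#' Welch two-sample t comparing the log-potency score distribution of
#' output-positive vs output-negative chemicals. Direction is positive when
#' output-positives score higher. Groups of size < 2 or zero pooled variance
#' are flagged degenerate/not testable (p = NA).
#'
#' @param scores Numeric score vector (see [scale_scores()]).
#' @param output Binary vector of the same length.
#' @param input_col,output_col Column labels carried into the result.
#' @return One-row `data.frame` matching [fisher_association()]'s layout
#'   (contingency counts are the group sizes in `TP`/`FN`; `FP`/`TN` are NA).
#' @export
ttest_association <- function(scores, output, input_col = "input",
                              output_col = "output") {
  stopifnot(length(scores) == length(output))
  pos <- scores[output == 1]
  neg <- scores[output == 0]
  res <- data.frame(input = input_col, output = output_col, method = "ttest",
                    statistic = NA_real_, p_value = NA_real_,
                    TP = length(pos), FP = NA_integer_, FN = length(neg),
                    TN = NA_integer_,
                    direction = sign(mean(pos) - mean(neg)),
                    stringsAsFactors = FALSE)
  if (length(pos) < 2 || length(neg) < 2) {
    res$degenerate <- TRUE
    res$direction <- NA_real_
    return(res)
  }
  tt <- tryCatch(stats::t.test(pos, neg), error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$statistic)) {
    # zero variance in both groups: identical groups are a null result,
    # separated groups an unbounded t -- both are flagged, not errors
    if (stats::sd(pos) == 0 && stats::sd(neg) == 0 &&
        mean(pos) == mean(neg)) {
      res$statistic <- 0
      res$p_value <- 1
      res$degenerate <- FALSE
    } else {
      res$degenerate <- TRUE
    }
    return(res)
  }
  res$statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  res$degenerate <- FALSE
  res
}

#' Pathway perturbation scores
#'
#' A chemical-pathway perturbation score (PS) is the minimum AC50 over the
#' assay columns mapped to the pathway; a chemical inactive on every mapped
#' assay scores the 1 M default. PS columns append to the data matrix as
#' kind `pathway_ps`.
#'
#' @param m An `assay_matrix`.
#' @param map Named list: pathway id -> character vector of column ids.
#'   Every mapped column must exist; empty pathways are rejected.
#' @param append If `TRUE` (default) return `m` with PS columns appended,
#'   else an `assay_matrix` of the PS columns alone.
#' @return An `assay_matrix`.
#' @export
pathway_score <- function(m, map, append = TRUE) {
  if (length(map) == 0 || is.null(names(map))) {
    stop("pathway map must be a named list", call. = FALSE)
  }
  ps <- sapply(names(map), function(pw) {
    cols <- map[[pw]]
    if (length(cols) == 0) {
      stop("pathway ", pw, " maps to no columns", call. = FALSE)
    }
    miss <- setdiff(cols, colnames(m$values))
    if (length(miss) > 0) {
      stop("pathway ", pw, " maps to unknown columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(m$kind[cols] == "in_vivo_lel")) {
      stop("pathway ", pw, " maps to non-AC50 columns", call. = FALSE)
    }
    apply(m$values[, cols, drop = FALSE], 1, min)
  })
  ps <- matrix(ps, nrow = nrow(m$values),
               dimnames = list(rownames(m$values), paste0("PS_", names(map))))
  if (!append) return(assay_matrix(ps, "pathway_ps"))
  assay_matrix(cbind(m$values, ps),
               c(m$kind, rep("pathway_ps", ncol(ps))))
}

#' Read a pathway map from JSON
#'
#' @param path JSON file: `{"pathway id": ["column id", ...], ...}`.
#' @return Named list of character vectors.
#' @export
read_pathway_map <- function(path) {
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(map, as.character)
}

#' Univariate association screen
#'
#' Runs both association tests (Fisher exact on dichotomized activity;
#' Welch t on log-potency scores, AC50-kind inputs only) for every input x
#' output column pair, flags significance at `p <= alpha` and sorts by
#' ascending p with a lexicographic (input, output, method) tie-break.
#' Pairs where input and output are the same column are skipped.
#'
#' @param m An `assay_matrix`.
#' @param inputs,outputs Column ids to use as predictors / predicted.
#' @param alpha Significance level on the raw p-values (default 0.1, the
#'   screen's reporting threshold).
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`; the motivating analysis reports raw p-values).
#' @return `data.frame` of association results with a `significant` flag.
#' @export
association_screen <- function(m, inputs, outputs, alpha = 0.1,
                               adjust = "none") {
  miss <- setdiff(c(inputs, outputs), colnames(m$values))
  if (length(miss) > 0) {
    stop("unknown columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(outputs) == 0 || length(inputs) == 0) {
    return(data.frame())
  }
  bin <- dichotomize(m)
  rows <- list()
  for (ic in inputs) {
    for (oc in outputs) {
      if (ic == oc) {
        message("association_screen: skipping self-pair ", ic)
        next
      }
      rows[[length(rows) + 1L]] <-
        fisher_association(bin[, ic], bin[, oc], ic, oc)
      if (m$kind[ic] != "in_vivo_lel") {
        rows[[length(rows) + 1L]] <-
          ttest_association(-log10(m$values[, ic]), bin[, oc], ic, oc)
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= alpha
  res <- res[order(res$p_value, res$input, res$output, res$method), ]
  rownames(res) <- NULL
  res
}

#' Write/read an assay matrix as CSV
#'
#' First column `chemical`, remaining columns by id; a `#kind:` header
#' comment row preserves column kinds.
#'
#' @param m An `assay_matrix`.
#' @param path File path.
#' @return `read_assay_matrix` returns the `assay_matrix`.
#' @export
write_assay_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind:", paste(m$kind, collapse = ",")), con)
  df <- data.frame(chemical = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assay_matrix
#' @export
read_assay_matrix <- function(path) {
  first <- readLines(path, n = 1)
  kind <- "in_vitro_ac50"
  skip <- 0
  if (startsWith(first, "#kind:")) {
    kind <- strsplit(sub("^#kind:", "", first), ",")[[1]]
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$chemical
  assay_matrix(v, kind)
}
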