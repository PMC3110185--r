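# Independent oracles used to check the package's own implementations.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities not exceeding the
# observed table's, with R's 1 + 1e-7 tie tolerance). Pure choose() arithmetic.
fisher_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  r1 <- tp + fp # input-positive margin
  c1 <- tp + fn # output-positive margin
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  px <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  p_obs <- px[xs == tp]
  sum(px[px <= p_obs * (1 + 1e-7)])
}

# AUC as the positive-negative pairwise concordance fraction, ties 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Brute-force Ward agglomeration: repeatedly merge the pair of clusters with
# the minimal increase in within-cluster sum of squares. Returns the merge
# sequence as canonical member-set strings.
ward_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- character(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]
        b <- clusters[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (is.null(best) || cost < best$cost) best <- list(cost = cost, i = i, j = j)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges <- c(merges, paste(merged, collapse = ","))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# Merge sequence of an hclust tree in the same canonical form.
hclust_merges <- function(tree) {
  members <- list()
  out <- character(nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(get(tree$merge[k, 1]), get(tree$merge[k, 2])))
    out[k] <- paste(members[[k]], collapse = ",")
  }
  out
}

# Concentration at which a fitted Hill curve attains an F-percent change,
# found numerically (independent of the closed-form inversion).
hill_root_oracle <- function(fit, F) {
  target <- if (fit$shape == "down") 1 - F / 100 else F / 100
  f <- function(lc) {
    frac <- 1 / (1 + (fit$ac50_param / exp(lc))^fit$hillslope)
    pred <- if (fit$shape == "down") {
      fit$bottom + (1 - fit$bottom) * (1 - frac)
    } else {
      fit$top * frac
    }
    pred - target
  }
  exp(stats::uniroot(f, c(log(fit$ac50_param) - 40, log(fit$ac50_param) + 40),
                     tol = 1e-14)$root)
}

# A clean single-effect chemical for round-trip tests.
one_effect_chem <- function(name, endpoint, ac50, slope = 1, effect = 1) {
  truth_chemical(name, data.frame(endpoint = endpoint, true_ac50 = ac50,
                                  hill_slope = slope, max_effect = effect))
}

# Analytic 50%-change concentration of a simulated effect (same algebra for
# losses and gains: the Hill occupancy at 50% change is 0.5/max_effect).
true_c50_oracle <- function(ac50, slope, max_effect) {
  stopifnot(max_effect > 0.5)
  ac50 * (0.5 / (max_effect - 0.5))^(1 / slope)
}

with_seed_shuffle <- function(x, seed) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sample(x)
}

# the four endpoint labels used throughout
endpoints4 <- c("cell_loss", "cell_gain", "diff_decrease", "diff_increase")

quiet_noise <- function(seed = 1L) {
  noise_model(cv_intensity = 0, background_mean = 0, background_sd = 0,
              seed = seed)
}
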