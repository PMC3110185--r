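# Assay matrix assembly, dichotomization, log-potency scores, association
# tests, pathway scores.

toy_matrix <- function() {
  v <- matrix(c(1e-6, 1.0, 1e-7,
                1.0, 1e-5, 1.0,
                1e-8, 1.0, 1.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("a1", "a2", "a3")))
  assay_matrix(v)
}

test_that("assay matrices validate ids, ranges and completeness", {
  expect_error(assay_matrix(matrix(1, 1, 1)), "rownames")
  v <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(assay_matrix(v), "duplicate column")
  v2 <- matrix(c(2, 0.5, 0.5, 0.5), 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(assay_matrix(v2), "molar")
  v3 <- matrix(c(NA, 0.5, 0.5, 0.5), 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(assay_matrix(v3), "complete")
})

test_that("build_matrix fills the four endpoint columns with 1 M defaults", {
  calls <- data.frame(chemical = rep(c("c1", "c2", "c3"), each = 4),
                      endpoint = rep(endpoints4, 3),
                      active = FALSE, ac50_M = 1.0)
  m <- build_matrix(calls)
  expect_equal(dim(m$values), c(3, 4))
  expect_true(all(m$values == 1.0))
  # one real hit lands in its cell
  calls$ac50_M[calls$chemical == "c2" & calls$endpoint == "diff_decrease"] <- 2.5e-6
  m2 <- build_matrix(calls)
  expect_equal(m2$values["c2", "diff_decrease"], 2.5e-6)
  expect_equal(sum(m2$values < 1), 1)
  expect_error(build_matrix(data.frame(chemical = "a", endpoint = "weird",
                                       ac50_M = 0.1)), "unknown endpoint")
})

test_that("the published fixture builds a 56-chemical matrix with hits", {
  fx <- published_ac50()
  fx$ac50_M <- fx$ac50_uM * 1e-6
  m <- build_matrix(fx)
  expect_equal(nrow(m$values), 56)
  expect_true(all(rowSums(m$values < 1) >= 1))
  # round-trip through CSV is exact
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_matrix(m, path)
  m2 <- read_assay_matrix(path)
  expect_equal(m2$values, m$values)
  expect_equal(m2$kind, m$kind)
})

test_that("dichotomization is the strict below-default rule and idempotent", {
  m <- toy_matrix()
  b <- dichotomize(m)
  expect_equal(as.vector(b["c1", ]), c(1L, 0L, 1L))
  expect_equal(as.vector(b["c2", ]), c(0L, 1L, 0L))
  # 1.0 M is inactive, anything smaller active
  expect_equal(dichotomize(matrix(c(1.0, 1e-6), 1,
                                  dimnames = list("c", c("x", "y")))),
               matrix(c(0L, 1L), 1, dimnames = list("c", c("x", "y"))))
  # idempotence: an already-binary matrix passes through unchanged
  expect_equal(dichotomize(b), b)
})

test_that("log-potency scores map 1 M to 0 and potency to positive scores", {
  expect_equal(scale_scores(matrix(1.0)), matrix(0))
  expect_equal(scale_scores(matrix(1e-6)), matrix(6))
  expect_equal(scale_scores(matrix(1.25e-5)), matrix(4.903090), tolerance = 1e-6)
  expect_error(scale_scores(matrix(0)), "positive")
  m <- toy_matrix()
  s <- scale_scores(m)
  # strictly decreasing in AC50; dichotomize(x)=1 <=> score > 0
  expect_true(all((s > 0) == (dichotomize(m) == 1)))
})

test_that("Fisher association matches the enumeration oracle and flags degeneracy", {
  inp <- c(rep(1, 5), rep(0, 5))
  out <- c(rep(1, 5), rep(0, 5))
  r <- fisher_association(inp, out)
  expect_equal(r$TP, 5)
  expect_equal(r$TN, 5)
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$p_value, fisher_oracle(5, 0, 0, 5), tolerance = 1e-12)
  expect_equal(r$direction, 1)
  # degenerate output margin
  rd <- fisher_association(c(1, 0, 1), c(0, 0, 0))
  expect_equal(rd$p_value, 1)
  expect_true(rd$degenerate)
})

test_that("t-test association handles symmetry, degeneracy and direction", {
  r <- ttest_association(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # zero within-group variance, separated means: guarded, not an error
  rz <- ttest_association(c(0, 0, 0, 0, 6, 6, 6, 6),
                          c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_true(rz$degenerate)
  # a group below size 2 is not testable
  rs <- ttest_association(c(1, 2, 3), c(1, 0, 0))
  expect_true(rs$degenerate)
  # direction positive when output-positives score higher
  rp <- ttest_association(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(rp$direction, 1)
  expect_lt(rp$p_value, 0.05)
})

test_that("t-test type-I error is nominal under a simulated null", {
  set.seed(202)
  rej <- replicate(1000, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, 0.5)
    ttest_association(scores, labels)$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("pathway scores are the minimum AC50 over mapped columns", {
  v <- matrix(c(1e-6, 1e-7, 1.0,
                1.0, 1.0, 1.0,
                1e-5, 1.0, 1e-8),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("a1", "a2", "a3")))
  m <- assay_matrix(v)
  ps <- pathway_score(m, list(pw = c("a1", "a2", "a3")), append = FALSE)
  expect_equal(as.vector(ps$values), c(1e-7, 1.0, 1e-8))
  expect_equal(unname(ps$kind), "pathway_ps")
  # conservation: never exceeds and exactly equals the member minimum
  expect_equal(as.vector(ps$values), unname(apply(v, 1, min)))
  # singleton pathway is the column itself
  one <- pathway_score(m, list(solo = "a2"), append = FALSE)
  expect_equal(as.vector(one$values), unname(v[, "a2"]))
  expect_error(pathway_score(m, list(bad = character(0))), "no columns")
  expect_error(pathway_score(m, list(bad = "zzz")), "unknown columns")
  appended <- pathway_score(m, list(pw = c("a1", "a2")))
  expect_equal(colnames(appended$values), c("a1", "a2", "a3", "PS_pw"))
})

test_that("pathway maps round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pw1 = c("a1", "a2"), pw2 = "a3"), path)
  map <- read_pathway_map(path)
  expect_equal(map, list(pw1 = c("a1", "a2"), pw2 = "a3"))
})

test_that("association screen recovers a planted association first", {
  set.seed(7)
  n <- 40
  v <- matrix(10^runif(n * 4, -8, -4), n, 4,
              dimnames = list(sprintf("c%02d", 1:n), paste0("a", 1:4)))
  v[runif(n * 4) < 0.5] <- 1.0 # half inactive
  planted <- ifelse(runif(n) < 0.5, 10^runif(n, -8, -4), 1.0)
  out <- ifelse(planted < 1, 1e-6, 1.0) # output = dichotomized planted input
  m <- assay_matrix(cbind(v, planted = planted, outcol = out))
  res <- association_screen(m, inputs = c(paste0("a", 1:4), "planted"),
                            outputs = "outcol")
  expect_equal(res$input[1], "planted")
  expect_lt(res$p_value[1], 1e-6)
  expect_true(res$significant[1])
  expect_true(!is.unsorted(res$p_value))
  # empty outputs give an empty table; self-pairs are skipped
  expect_equal(nrow(association_screen(m, "a1", character(0))), 0)
  expect_message(res_self <- association_screen(m, "a1", "a1"), "self-pair")
  expect_equal(nrow(res_self), 0)
})

test_that("LEL columns are dichotomized by dose presence, never log-scaled", {
  v <- cbind(ac = c(1e-6, 1.0, 1e-5),
             lel = c(30, 1e6, 250))
  rownames(v) <- c("c1", "c2", "c3")
  m <- assay_matrix(v, kind = c("in_vitro_ac50", "in_vivo_lel"))
  b <- dichotomize(m)
  expect_equal(as.vector(b[, "lel"]), c(1L, 0L, 1L))
  s <- scale_scores(m)
  expect_equal(colnames(s), "ac")
  res <- association_screen(m, inputs = "lel", outputs = "ac")
  expect_equal(unique(res$method), "fisher")
})
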