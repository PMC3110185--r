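# Control band, activity classification, Hill fitting, AC50, AC_F.

test_that("control band is mean +/- 2 sample SD", {
  b <- control_band(c(0.9, 1.0, 1.1))
  expect_equal(b$mean, 1.0)
  expect_equal(b$sd, 0.1)
  expect_equal(c(b$low, b$high), c(0.8, 1.2))
  b0 <- control_band(c(1, 1, 1))
  expect_equal(c(b0$low, b0$high), c(1, 1))
  expect_lte(b0$low, b0$high)
  expect_error(control_band(1), "at least 2")
})

test_that("activity classification follows the band rule, edges inclusive", {
  b <- control_band(c(0.9, 1.0, 1.1))
  expect_equal(classify_activity(c(1.0, 1.05, 0.95), b), "none")
  expect_equal(classify_activity(c(1.0, 0.9, 0.5, 0.1), b), "down")
  expect_equal(classify_activity(c(1.0, 1.1, 1.5, 2.0), b), "up")
  expect_equal(classify_activity(c(1.5, 1.6, 0.4, 0.3), b), "ushape")
  # values exactly at the band edge count as within
  expect_equal(classify_activity(c(0.8, 1.2), b), "none")
})

test_that("exact downward Hill data are recovered to within 1%", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  y <- 1 - 1 / (1 + (1.25 / conc)^1)
  fit <- fit_hill(conc, y, "down")
  expect_true(fit$converged)
  expect_equal(fit$ac50_param, 1.25, tolerance = 0.01)
  expect_equal(fit$hillslope, 1, tolerance = 0.05)
  expect_equal(fit$bottom, 0, tolerance = 0.01)
  call <- ac50_from_fit(fit, 12.5)
  expect_true(call$active)
  expect_equal(call$ac50_uM, 1.25, tolerance = 0.01)
  expect_false(call$extrapolated)
})

test_that("upward data doubling the control fit with top near 1 (shifted scale)", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  y <- 1 + 1 / (1 + (0.25 / conc)^1.5) # plateau at 2.0
  fit <- fit_hill(conc, y, "up")
  expect_true(fit$converged)
  expect_equal(fit$top, 1, tolerance = 0.02)
  expect_equal(fit$bottom, 0)
  call <- ac50_from_fit(fit, 12.5)
  expect_true(call$active)
  expect_equal(call$ac50_uM, 0.25, tolerance = 0.02)
})

test_that("flat or shallow curves yield the 1 M inactive default", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  flat <- fit_hill(conc, rep(1, 8), "down")
  expect_false(ac50_from_fit(flat, 12.5)$active)
  expect_equal(ac50_from_fit(flat, 12.5)$ac50_M, 1.0)
  # a curve reaching only a 30% change never attains 50%: inactive
  y30 <- 1 - 0.3 / (1 + (1.25 / conc)^1)
  f30 <- fit_hill(conc, y30, "down")
  expect_true(f30$converged)
  expect_false(ac50_from_fit(f30, 12.5)$active)
  # non-converged fits fall back to inactive, never an exception
  nc <- structure(list(shape = "down", converged = FALSE), class = "hill_fit")
  expect_false(ac50_from_fit(nc, 12.5)$active)
  expect_false(fit_hill(conc[1:3], rep(1, 3), "down")$converged)
})

test_that("AC50 crossings above the top tested concentration are flagged extrapolated", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  y <- 1 - 1 / (1 + 18 / conc) # slope 1, midpoint above the 12.5 uM ceiling
  fit <- fit_hill(conc, y, "down")
  call <- ac50_from_fit(fit, 12.5)
  expect_true(call$active)
  expect_true(call$extrapolated)
  expect_equal(call$ac50_uM, 18, tolerance = 0.05)
})

test_that("fitted monotone trends are monotone in concentration", {
  grid <- 10^seq(-3, 2, length.out = 50)
  for (seed in 1:5) {
    set.seed(seed)
    conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
    y <- (1 - 0.9 / (1 + (0.5 / conc)^1.3)) * exp(rnorm(8, 0, 0.05))
    fit <- fit_hill(conc, y, "down")
    pred <- fit$bottom + (1 - fit$bottom) / (1 + (grid / fit$ac50_param)^fit$hillslope)
    expect_true(all(diff(pred) <= 1e-12))
  }
})

test_that("AC50 estimates are equivariant under concentration-unit relabeling", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  set.seed(4)
  y <- (1 - 0.95 / (1 + (0.8 / conc)^1.6)) * exp(rnorm(8, 0, 0.03))
  in_uM <- ac50_from_fit(fit_hill(conc, y, "down"), 12.5)
  in_nM <- ac50_from_fit(fit_hill(conc * 1000, y, "down"), 12500)
  expect_equal(in_nM$ac50_uM / 1000, in_uM$ac50_uM, tolerance = 1e-4)
})

test_that("ac_f inverts the Hill curve and validates its domain", {
  expect_equal(ac_f(3.7, 2.2, 50), 3.7) # F = 50 is the AC50 itself
  expect_equal(ac_f(9, 1, 10), 1.0)
  expect_equal(ac_f(1, 2, 90), 3.0)
  # negative slopes use |slope|
  expect_equal(ac_f(9, -1, 10), 1.0)
  # monotone increasing in F
  f <- ac_f(2, 1.5, c(10, 30, 50, 70, 90))
  expect_true(all(diff(f) > 0))
  expect_error(ac_f(1, 1, 0), "between 0 and 100")
  expect_error(ac_f(1, 1, 100), "between 0 and 100")
  expect_error(ac_f(-1, 1, 50), "ac50")
  expect_error(ac_f(1, 0, 50), "hillslope")
})

test_that("ac_f agrees with numeric root-finding on fitted full-efficacy curves", {
  conc <- rep(c(0.0125, 0.125, 1.25, 12.5), each = 2)
  y <- 1 - 1 / (1 + (0.6 / conc)^2)
  fit <- fit_hill(conc, y, "down")
  for (F in c(10, 25, 50, 75, 90)) {
    expect_equal(ac_f(fit$ac50_param, fit$hillslope, F),
                 hill_root_oracle(fit, F), tolerance = 1e-9)
  }
})

test_that("call_screen recovers truth on a zero-noise screen", {
  chems <- c(
    lapply(1:5, function(i) one_effect_chem(sprintf("ACT%02d", i),
                                            "diff_decrease",
                                            ac50 = 10^runif(1, -1, 0.5))),
    lapply(1:5, function(i) truth_chemical(sprintf("NULL%02d", i)))
  )
  set.seed(11)
  w <- rbind(
    generate_plate(chems = chems[1:8], noise = quiet_noise(1), plate_id = "P1"),
    generate_plate(chems = chems[9:10], noise = quiet_noise(2), plate_id = "P2")
  )
  calls <- call_screen(process_plates(w))
  expect_equal(nrow(calls), 40) # 10 chemicals x 4 endpoints
  nulls <- calls[grepl("NULL", calls$chemical), ]
  expect_false(any(nulls$active))
  expect_true(all(nulls$ac50_M == 1.0))
  acts <- calls[grepl("ACT", calls$chemical), ]
  expect_true(all(acts$active[acts$endpoint == "diff_decrease"]))
  expect_false(any(acts$active[acts$endpoint != "diff_decrease"]))
})

test_that("inactive calls carry ac50_M = 1 exactly and actives lie in (0, 1)", {
  scr <- generate_screen(16, noise = noise_model(seed = 9))
  calls <- call_screen(process_plates(scr$wells))
  expect_true(all(calls$ac50_M[!calls$active] == 1.0))
  act <- calls$ac50_M[calls$active]
  expect_true(all(act > 0 & act < 1))
  expect_equal(calls$extrapolated[calls$active],
               calls$ac50_uM[calls$active] > 12.5)
})
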