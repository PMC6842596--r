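# Unwinding-trace analysis: normalization, exponential fits, relative
# efficiency.

test_that("normalization subtracts baseline and records its mode", {
  tr <- synth_unwinding_trace(5, 0.2, baseline = 1, t_grid = seq(0, 60, 1))
  flat <- tr; flat$fluorescence <- rep(2, nrow(tr))
  nf <- normalize_trace(flat, "fold")
  expect_true(all(nf$fluorescence == 0))
  # fold-change mode: amplitude 5x baseline -> rise of 5 fold-changes
  # (k = 1: the t = 0 point is the pre-reaction baseline)
  nt <- normalize_trace(tr, "fold", k = 1)
  expect_equal(max(nt$fluorescence), 5, tolerance = 0.05)
  expect_equal(attr(nt, "normalization")$mode, "fold")
  # relative mode divides by the stated reference plateau
  nr <- normalize_trace(tr, "relative", k = 1, reference = 5)
  nr2 <- nr; nr2$fluorescence <- nr$fluorescence  # plateau ~1
  expect_equal(max(nr$fluorescence), 1, tolerance = 0.05)
  expect_error(normalize_trace(flat, "fold"),  NA)
  neg <- tr; neg$fluorescence <- neg$fluorescence - 10
  expect_error(normalize_trace(neg, "fold"), "divisor")
  expect_error(normalize_trace(tr[1:3, ], "fold"), "5 points")
})

test_that("noise-free exponential fits recover parameters near-exactly", {
  tr <- synth_unwinding_trace(1, 0.1, baseline = 0.2,
                              t_grid = seq(0, 80, 0.5))
  fit <- fit_exponential(tr)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$rate, 0.1, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.2, tolerance = 1e-6)
  expect_equal(fit$v0, 0.1, tolerance = 1e-6)
  # the two velocity estimates agree within 10% on clean traces
  expect_lt(abs(fit$v0_linear - fit$v0) / fit$v0, 0.10)
})

test_that("fits stay accurate under noise and degrade monotonically", {
  err_at <- function(noise) {
    errs <- vapply(1:40, function(sd) {
      tr <- synth_unwinding_trace(1, 0.1, noise_sd = noise,
                                  t_grid = seq(0, 80, 0.5), seed = sd)
      abs(fit_exponential(tr)$amplitude - 1)
    }, numeric(1))
    median(errs)
  }
  e2 <- err_at(0.02)
  expect_lt(e2, 0.02)
  e5 <- err_at(0.05); e10 <- err_at(0.10)
  expect_lt(e2, e5)
  expect_lt(e5, e10)
})

test_that("flat traces are flagged as no unwinding", {
  flat <- synth_unwinding_trace(1e-9, 0.1, baseline = 1, noise_sd = 1e-4,
                                t_grid = seq(0, 60, 1), seed = 2)
  fit <- fit_exponential(flat)
  expect_true(fit$no_unwinding)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$v0, 0)
})

test_that("relative efficiency reports ratios in percent", {
  t_ref <- synth_unwinding_trace(1, 0.1, t_grid = seq(0, 80, 0.5))
  f_ref <- fit_exponential(t_ref)
  expect_equal(relative_efficiency(f_ref, f_ref)$amplitude_pct, 100,
               tolerance = 1e-9)
  t64 <- synth_unwinding_trace(0.64, 0.1, t_grid = seq(0, 80, 0.5))
  re <- relative_efficiency(fit_exponential(t64), f_ref)
  expect_equal(re$amplitude_pct, 64, tolerance = 0.01)
  zero <- fit_exponential(synth_unwinding_trace(0, 0.1,
                                                t_grid = seq(0, 60, 1)))
  expect_equal(relative_efficiency(zero, f_ref)$amplitude_pct, 0)
  expect_error(relative_efficiency(f_ref, zero), "positive")
})

test_that("efficiency ratios are scale-invariant", {
  mk <- function(scale) {
    t1 <- synth_unwinding_trace(0.7, 0.08, baseline = 0.3, noise_sd = 0.01,
                                t_grid = seq(0, 90, 0.5), seed = 5)
    t2 <- synth_unwinding_trace(1.1, 0.12, baseline = 0.2, noise_sd = 0.01,
                                t_grid = seq(0, 90, 0.5), seed = 6)
    t1$fluorescence <- t1$fluorescence * scale
    t2$fluorescence <- t2$fluorescence * scale
    relative_efficiency(fit_exponential(t1), fit_exponential(t2))
  }
  r1 <- mk(1); r2 <- mk(37.5)
  expect_equal(r1$amplitude_pct, r2$amplitude_pct, tolerance = 1e-6)
  expect_equal(r1$velocity_pct, r2$velocity_pct, tolerance = 1e-6)
})

test_that("trace CSV round-trips", {
  tr <- synth_unwinding_trace(1, 0.1, t_grid = seq(0, 30, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tr), f, row.names = FALSE)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$fluorescence, tr$fluorescence, tolerance = 1e-9)
})
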