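# Reweighting, free-energy estimation, bootstrap errors, detailed balance.

test_that("reweighting removes the constant-force bias exactly", {
  # zero force: uniform weights
  w <- reweight(c(1, 2, 3, 4), force = 0, kT = 1)
  expect_equal(w$w, rep(0.25, 4))
  expect_equal(w$ess, 4)
  # two frames, beta f = 1 (1/nm), x = 0 and 1 nm
  w <- reweight(c(0, 1), force = 1, kT = 1)
  expect_equal(w$w, c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
               tolerance = 1e-14)
  # exact cancellation by enumeration: frames in exact biased proportions
  # exp(+bf x), reweighted with exp(-bf x), recover 50/50 to 1e-12
  bf <- 1.3; dx <- 1
  p_hi <- exp(bf * dx) / (1 + exp(bf * dx))
  x_frames <- c(0, dx)
  w <- reweight(x_frames, force = bf, kT = 1)
  pop_hi <- p_hi * w$w[2] / (p_hi * w$w[2] + (1 - p_hi) * w$w[1])
  expect_equal(pop_hi, 0.5, tolerance = 1e-12)
  expect_error(reweight(c(1, NA), 1, 1), "finite")
  expect_error(reweight(c(1, 2), 1, 0), "positive")
})

test_that("sampled biased ensembles reweight to 50/50", {
  x <- biased_two_state_sampler(dx = 1, beta_f = 1, n = 1e4, seed = 3)
  # biased high-x fraction ~ e/(1+e)
  expect_lt(abs(mean(x == 1) - exp(1) / (1 + exp(1))), 0.02)
  w <- reweight(x, force = 1, kT = 1)
  p_hi <- sum(w$w[x == 1])
  expect_lt(abs(p_hi - 0.5), 0.02)
  expect_equal(sum(w$w), 1, tolerance = 1e-12)
})

test_that("dangling free energies follow the weighted population ratio", {
  mk_series <- function(states, ctx = "CC/GG") {
    d <- data.frame(
      frame = seq_along(states), junction = rep(1L, length(states)),
      state = factor(states, levels = JUNCTION_STATES),
      context = rep(ctx, length(states)),
      stringsAsFactors = FALSE
    )
    class(d) <- c("junction_state_series", "data.frame")
    d
  }
  # equal occupancy -> g = 0
  ser <- mk_series(rep(c("FLIP5", "FLIP3"), 50))
  tab <- dangling_dg(ser)
  expect_equal(tab$g, 0, tolerance = 1e-12)
  # 75/25 -> g = ln 3
  ser <- mk_series(c(rep("FLIP5", 75), rep("FLIP3", 25)))
  tab <- dangling_dg(ser)
  expect_equal(tab$g, log(3), tolerance = 1e-12)
  expect_equal(tab$n5, 75)
  expect_equal(tab$n3, 25)
  # unobserved intermediate -> flagged NA, not zero
  ser <- mk_series(c(rep("FLIP5", 10), rep("CLOSED", 10)))
  tab <- dangling_dg(ser)
  expect_true(is.na(tab$g))
  expect_error(dangling_dg(mk_series(character(0))), "empty")
})

test_that("surrogate chains with stationary ratio e^2 give g = 2 kT", {
  pi5 <- 0.2 * exp(2) / (1 + exp(2))
  pi3 <- 0.2 / (1 + exp(2))
  m <- junction_markov_model(pi = c(0.5, pi5, pi3, 0.3), nu = 1)
  # independent oracle for the stationary distribution
  pist <- stationary_distribution(m$Q)
  expect_equal(log(pist[2] / pist[3]), 2, tolerance = 1e-10)
  sj <- sample_junction_series(m, 3e5, dt = 0.1, seed = 7)
  tab <- dangling_dg(sj$series, n_boot = 100, seed = 2)
  expect_false(is.na(tab$g))
  expect_lt(abs(tab$g - 2), 3 * tab$se + 0.05)
})

test_that("block-bootstrap SE matches the delta method on iid series", {
  # iid Bernoulli intermediate states: SE(g) ~ sqrt(1/n5 + 1/n3)
  set.seed(10)
  n <- 1e4
  states <- sample(c("FLIP5", "FLIP3", "CLOSED"), n, replace = TRUE,
                   prob = c(0.3, 0.15, 0.55))
  ser <- data.frame(
    frame = 1:n, junction = 1L,
    state = factor(states, levels = JUNCTION_STATES), context = "GC/GC",
    stringsAsFactors = FALSE
  )
  class(ser) <- c("junction_state_series", "data.frame")
  se <- bootstrap_se(ser, n_boot = 400, block_len = 1, seed = 5)
  n5 <- sum(states == "FLIP5"); n3 <- sum(states == "FLIP3")
  expect_lt(abs(se - sqrt(1 / n5 + 1 / n3)) / sqrt(1 / n5 + 1 / n3), 0.15)
  # determinism
  se2 <- bootstrap_se(ser, n_boot = 400, block_len = 1, seed = 5)
  expect_identical(se, se2)
  expect_error(bootstrap_se(ser[1:5, ], block_len = 10), "shorter")
})

test_that("bootstrap SE shrinks with series length", {
  ses <- vapply(c(2e4, 8e4, 32e4), function(n) {
    m <- junction_markov_model(pi = c(0.4, 0.25, 0.15, 0.2), nu = 1)
    sj <- sample_junction_series(m, n, dt = 0.1, seed = 42)
    unname(bootstrap_se(sj$series, n_boot = 120, seed = 3))
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  # roughly 1/sqrt(n): a factor-4 length increase halves the SE (loose band)
  expect_lt(ses[2] / ses[1], 0.8)
  expect_gt(ses[2] / ses[1], 0.3)
})

test_that("detailed-balance report flags violations and passes mirrors", {
  mk_ev <- function(n5o, n3o, n5c, n3c) {
    data.frame(
      direction = rep(c("opening", "closing"), c(n5o + n3o, n5c + n3c)),
      pathway = c(rep("via_FLIP5", n5o), rep("via_FLIP3", n3o),
                  rep("via_FLIP5", n5c), rep("via_FLIP3", n3c)),
      context = "CC/GG", start = 1L, end = 2L, stringsAsFactors = FALSE
    )
  }
  rep1 <- detailed_balance_report(mk_ev(60, 40, 60, 40))
  expect_equal(rep1$p_value, 1)
  expect_false(rep1$reject)
  rep2 <- detailed_balance_report(mk_ev(100, 0, 0, 100))
  expect_lt(rep2$p_value, 1e-10)
  expect_true(rep2$reject)
  rep3 <- detailed_balance_report(mk_ev(1, 0, 50, 50))
  expect_true(rep3$skipped)
})

test_that("reversible surrogate chains pass detailed balance at nominal rate", {
  rejections <- vapply(1:30, function(sd) {
    m <- junction_markov_model(pi = c(0.35, 0.25, 0.15, 0.25), nu = 1)
    sj <- sample_junction_series(m, 4e4, dt = 0.1, seed = sd)
    ev <- extract_events(sj$states)
    rep <- detailed_balance_report(ev, alpha = 0.01)
    isTRUE(rep$reject[1])
  }, logical(1))
  expect_lt(mean(rejections), 0.07)
})
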