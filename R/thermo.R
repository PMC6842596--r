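# Bias removal and nearest-neighbour free-energy estimation.
#
# Constant-force trajectories sample the tilted potential U0 - f*x; the
# unbiased (zero-force) equilibrium ensemble is recovered by weighting each
# frame with exp(-f*x/kT).  The free-energy difference between the two
# dangling intermediates of a junction pair is then
#   g = kT * ln( W(FLIP5) / W(FLIP3) )
# per nearest-neighbour context, positive when the 3'-dangling intermediate
# (5'-terminal base flipped out) is the more populated one.  Standard errors
# come from a moving-block bootstrap over time blocks.

#' Frame weights removing the constant-force bias
#'
#' `weight_i` proportional to `exp(-force * x_i / kT)`, normalized to sum to
#' one.  Units must be consistent (e.g. force in pN, x in nm, kT in pN nm =
#' 4.09 at 296 K; or everything in reduced units).
#'
#' @param x End-to-end distance series.
#' @param force The constant pulling force applied during sampling.
#' @param kT Thermal energy in matching units.
#' @return Object of class `frame_weights`: list with `w` (normalized
#'   weights), `ess` (Kish effective sample size `1/sum(w^2)`), `force`,
#'   `kT`.
#' @export
reweight <- function(x, force, kT) {
  if (kT <= 0) stop("kT must be positive")
  if (any(!is.finite(x))) stop("non-finite end-to-end distances")
  a <- -force * x / kT
  w <- exp(a - max(a))
  w <- w / sum(w)
  out <- list(w = w, ess = 1 / sum(w^2), force = force, kT = kT)
  class(out) <- "frame_weights"
  out
}

#' Nearest-neighbour free-energy table of dangling intermediates
#'
#' For every nearest-neighbour context observed in the state series, the
#' reweighted populations of the two junction intermediates give
#' `g = kT ln(W(FLIP5)/W(FLIP3))` (in units of kT), positive when the
#' 3'-dangling intermediate is more populated.  Contexts where either
#' intermediate was never observed are flagged (`g = NA`), not zeroed.
#'
#' @param series A `junction_state_series` (or data.frame with `state` and
#'   `context` columns).
#' @param weights A `frame_weights` (defaults to uniform weights).
#' @param n_boot Bootstrap resamples for the standard error (0 = skip).
#' @param block_len Moving-block length in frames; `NULL` chooses
#'   5 x the integrated autocorrelation time of the intermediate indicator.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame of class `nn_dg_table`: `context`, `g` (kT), `se`,
#'   `n5`, `n3` (raw frame counts), `w5`, `w3` (weighted populations).
#' @export
dangling_dg <- function(series, weights = NULL, n_boot = 0, block_len = NULL,
                        seed = 1) {
  if (nrow(series) == 0L) stop("empty state series")
  st <- as.character(series$state)
  ctx <- series$context
  if (is.null(weights)) {
    w <- rep(1 / nrow(series), nrow(series))
  } else {
    w <- weights$w
    if (length(w) != nrow(series)) stop("weights and series are not aligned")
  }
  sel5 <- st == "FLIP5" & !is.na(ctx)
  sel3 <- st == "FLIP3" & !is.na(ctx)
  contexts <- sort(unique(ctx[(sel5 | sel3)]))
  if (length(contexts) == 0L) {
    stop("no dangling intermediates observed")
  }
  tab <- data.frame(
    context = contexts,
    g = NA_real_, se = NA_real_,
    n5 = 0L, n3 = 0L, w5 = 0, w3 = 0,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(contexts)) {
    c5 <- sel5 & ctx == contexts[i]
    c3 <- sel3 & ctx == contexts[i]
    tab$n5[i] <- sum(c5)
    tab$n3[i] <- sum(c3)
    tab$w5[i] <- sum(w[c5])
    tab$w3[i] <- sum(w[c3])
    if (tab$n5[i] > 0L && tab$n3[i] > 0L) {
      tab$g[i] <- log(tab$w5[i] / tab$w3[i])
    }
  }
  if (n_boot > 0) {
    tab$se <- bootstrap_se(series, weights, n_boot = n_boot,
                           block_len = block_len, seed = seed)[tab$context]
  }
  class(tab) <- c("nn_dg_table", "data.frame")
  tab
}

# Integrated autocorrelation time (in frames) of a 0/1 indicator series,
# by summing the empirical autocorrelation to its first non-positive lag.
.iact <- function(z) {
  if (stats::var(z) == 0) return(1)
  a <- stats::acf(z, lag.max = min(length(z) - 1, 2000), plot = FALSE)$acf[-1]
  m <- which(a <= 0)[1]
  if (is.na(m)) m <- length(a)
  max(1, 1 + 2 * sum(a[seq_len(m - 1)]))
}

#' Moving-block bootstrap standard errors for the free-energy table
#'
#' Resamples contiguous time blocks (preserving autocorrelation), recomputes
#' g per context on each resample, and returns the standard deviation across
#' resamples.  Deterministic for a fixed seed.
#'
#' @inheritParams dangling_dg
#' @param weights A `frame_weights` or `NULL` for uniform.
#' @return Named numeric vector of SEs per context.
#' @export
bootstrap_se <- function(series, weights = NULL, n_boot = 200,
                         block_len = NULL, seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  n <- nrow(series)
  st <- as.character(series$state)
  ctx <- series$context
  w <- if (is.null(weights)) rep(1 / n, n) else weights$w
  if (is.null(block_len)) {
    ind <- as.integer(st %in% c("FLIP5", "FLIP3"))
    block_len <- max(1L, as.integer(round(5 * .iact(ind))))
  }
  block_len <- as.integer(block_len)
  if (block_len > n) stop("series shorter than one block")
  contexts <- sort(unique(ctx[!is.na(ctx) & st %in% c("FLIP5", "FLIP3")]))
  # per-frame contributions to (w5, w3) per context
  nb <- n - block_len + 1L                 # number of admissible block starts
  k <- as.integer(ceiling(n / block_len))  # blocks per resample
  # block partial sums via cumulative sums, per context and intermediate
  gmat <- matrix(0, n_boot, length(contexts))
  starts <- with_local_seed(seed, {
    matrix(sample.int(nb, n_boot * k, replace = TRUE), n_boot, k)
  })
  for (ci in seq_along(contexts)) {
    a5 <- w * (st == "FLIP5" & !is.na(ctx) & ctx == contexts[ci])
    a3 <- w * (st == "FLIP3" & !is.na(ctx) & ctx == contexts[ci])
    cs5 <- c(0, cumsum(a5))
    cs3 <- c(0, cumsum(a3))
    bs5 <- cs5[seq_len(nb) + block_len] - cs5[seq_len(nb)]
    bs3 <- cs3[seq_len(nb) + block_len] - cs3[seq_len(nb)]
    w5 <- matrix(bs5[starts], n_boot, k)
    w3 <- matrix(bs3[starts], n_boot, k)
    gmat[, ci] <- log(rowSums(w5) / rowSums(w3))
  }
  se <- apply(gmat, 2, function(z) stats::sd(z[is.finite(z)]))
  stats::setNames(se, contexts)
}

#' Detailed-balance report for opening/closing pathway usage
#'
#' In equilibrium, opening and closing events traverse each intermediate
#' pathway with statistically identical probabilities.  Per context, the
#' fraction of `via_FLIP5` events (among FLIP5/FLIP3-resolved ones) is
#' compared between opening and closing events with a two-proportion test
#' (chi-squared without continuity correction, equivalent to the
#' two-proportion z-test).
#'
#' @param events Event data.frame from [extract_events()].
#' @param alpha Significance level used for the `reject` flag.
#' @return data.frame: `context`, `n_open`, `n_close`, `frac5_open`,
#'   `frac5_close`, `p_value`, `reject`, `skipped`.
#' @export
detailed_balance_report <- function(events, alpha = 0.01) {
  ev <- events[events$pathway %in% c("via_FLIP5", "via_FLIP3"), , drop = FALSE]
  ctxs <- unique(ev$context)
  rows <- lapply(ctxs, function(cc) {
    e <- ev[is.na(ev$context) == is.na(cc) &
              (is.na(cc) | ev$context == cc), , drop = FALSE]
    op <- e[e$direction == "opening", , drop = FALSE]
    cl <- e[e$direction == "closing", , drop = FALSE]
    n_o <- nrow(op); n_c <- nrow(cl)
    if (n_o < 2 || n_c < 2) {
      return(data.frame(
        context = cc, n_open = n_o, n_close = n_c,
        frac5_open = NA, frac5_close = NA, p_value = NA,
        reject = NA, skipped = TRUE, stringsAsFactors = FALSE
      ))
    }
    x <- c(sum(op$pathway == "via_FLIP5"), sum(cl$pathway == "via_FLIP5"))
    nn <- c(n_o, n_c)
    pv <- if (abs(x[1] / nn[1] - x[2] / nn[2]) < 1e-12) 1 else
      suppressWarnings(stats::prop.test(x, nn, correct = FALSE)$p.value)
    data.frame(
      context = cc, n_open = n_o, n_close = n_c,
      frac5_open = x[1] / n_o, frac5_close = x[2] / n_c,
      p_value = pv, reject = pv < alpha, skipped = FALSE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pool junction state series from several runs
#'
#' Concatenates series and weights (weights renormalized jointly, each run's
#' frames keeping their internal relative weights and runs contributing in
#' proportion to their frame counts), retaining per-run ids.
#'
#' @param series_list List of `junction_state_series`.
#' @param weights_list List of `frame_weights` (or `NULL` for uniform).
#' @return List with pooled `series` and `weights`.
#' @export
pool_runs <- function(series_list, weights_list = NULL) {
  ns <- vapply(series_list, nrow, integer(1))
  ser <- do.call(rbind, lapply(series_list, as.data.frame))
  ser$run <- rep(seq_along(series_list), ns)
  if (is.null(weights_list)) {
    w <- rep(1 / sum(ns), sum(ns))
  } else {
    w <- unlist(lapply(seq_along(weights_list), function(i) {
      weights_list[[i]]$w * ns[i]
    }))
    w <- w / sum(w)
  }
  wt <- list(w = w, ess = 1 / sum(w^2), force = NA, kT = NA)
  class(wt) <- "frame_weights"
  class(ser) <- c("junction_state_series", "data.frame")
  list(series = ser, weights = wt)
}

#' Write the free-energy table as CSV
#'
#' @param table An `nn_dg_table`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_dg_csv <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}
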