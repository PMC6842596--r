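# Junction-state analysis: convert trajectories into per-frame discrete
# states of the single-strand/double-strand junction base pair and into
# opening/closing events with 5'/3' pathway labels.
#
# States of a base pair at the junction:
#   CLOSED - paired and both bases stacked
#   FLIP5  - the base at the 5' terminus (chain A side at the pulled end)
#            has unstacked ("flipped out"), leaving the complementary base
#            dangling on the 3' side: the 3'-dangling intermediate
#   FLIP3  - mirror case: the 5'-dangling intermediate
#   OPEN   - neither intermediate nor closed

JUNCTION_STATES <- c("CLOSED", "FLIP5", "FLIP3", "OPEN")

#' Watson-Crick pairing distance of one frame
#'
#' Distance between the pair's donor/acceptor atoms (purine N1, pyrimidine
#' N3).  Symmetric in the implied argument order; equals the builder's native
#' value on the native frame.
#'
#' @param structure A `native_structure` (provides the atom map).
#' @param xyz Coordinate frame (n_atoms x 3, Angstrom).
#' @param pair Base-pair index (1 = pulled end).
#' @return Distance in Angstrom.
#' @export
pairing_distance <- function(structure, xyz, pair) {
  ij <- wc_atoms_of_pair(structure, pair)
  dist3(xyz[ij[1], ], xyz[ij[2], ])
}

#' Base-base stacking distance of one frame
#'
#' Distance between the two bases' heavy-atom centroids (ring plus
#' exocyclic atoms).
#'
#' @param structure A `native_structure`.
#' @param xyz Coordinate frame.
#' @param res_i,res_j Residue specifications as `c(chain, resno)`, e.g.
#'   `c("A", 1)`.
#' @return Distance in Angstrom.
#' @export
stacking_distance <- function(structure, xyz, res_i, res_j) {
  if (identical(res_i, res_j)) stop("stacking distance of a base with itself")
  ci <- base_centroid(structure, res_i[1], as.integer(res_i[2]), xyz)
  cj <- base_centroid(structure, res_j[1], as.integer(res_j[2]), xyz)
  dist3(ci, cj)
}

#' Centered moving average
#'
#' Window shrinks symmetrically at the boundaries; length is preserved.
#' Used to smooth the pairing/stacking distance channels before state
#' assignment (the analysis averages distance channels over windows of 300
#' time steps).
#'
#' @param x Numeric series.
#' @param window Window width in frames (>= 1).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window == 1L || length(x) == 0L) return(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + (window - 1L - half))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Default junction state thresholds
#'
#' A channel counts as disrupted when its smoothed value exceeds its native
#' value by `delta`; a disrupted channel recovers once it falls back below
#' native + `delta` - `hysteresis` (chatter suppression).
#'
#' @param delta Disruption offset above native (Angstrom).
#' @param hysteresis Re-entry hysteresis (Angstrom).
#' @return List of threshold parameters.
#' @export
junction_thresholds <- function(delta = 2.5, hysteresis = 0.5) {
  stopifnot(delta > 0, hysteresis >= 0, hysteresis < delta)
  list(delta = delta, hysteresis = hysteresis)
}

# Hysteresis thresholding of one channel: returns logical "disrupted".
.hyst <- function(x, hi, lo) {
  up <- x > hi
  dn <- x <= lo
  s <- ifelse(up, 1L, ifelse(dn, 0L, NA_integer_))
  if (is.na(s[1])) s[1] <- 0L
  idx <- cummax(seq_along(s) * !is.na(s))
  s[idx] == 1L
}

#' Assign per-frame junction states
#'
#' Works on the distance channels recorded by [run_dynamics()] (or supplied
#' directly as a matrix with columns `pairing_k`, `stack5_k`, `stack3_k`).
#' Channels are smoothed with a centered moving average, then each base pair
#' k (1..n-1; the innermost pair has no inward stacking partner and is
#' classified by pairing only) is assigned:
#' CLOSED if pairing and both stacking channels are below their thresholds;
#' FLIP5 / FLIP3 if exactly the 5'/3' base's stacking channel is disrupted
#' while the partner base remains stacked; OPEN otherwise.  The junction
#' index is the outermost pair (smallest k, counting from the pulled end)
#' not yet OPEN.
#'
#' @param trajectory An `unzip_trajectory`, or a channel matrix.
#' @param thresholds See [junction_thresholds()].
#' @param window Smoothing window in saved frames; defaults to 300 time
#'   steps' worth of frames given the trajectory's `save_stride`.
#' @param native Named numeric vector of native channel values (defaults to
#'   the first frame values for a trajectory started in the native state,
#'   which equal the builder's ideal values).
#' @return A `junction_state_series` data.frame: `frame`, `junction`
#'   (pair index, n+1 when fully open), `state` (factor), `context`
#'   (nearest-neighbour label, NA at the innermost pair), plus the per-pair
#'   state matrix in attribute `pair_states`.
#' @export
assign_states <- function(trajectory, thresholds = junction_thresholds(),
                          window = NULL, native = NULL) {
  if (inherits(trajectory, "unzip_trajectory")) {
    chan <- trajectory$channels
    n_bp <- trajectory$n_bp
    seq1 <- trajectory$seq1
    ntype <- trajectory$nucleic_type
    if (is.null(window)) {
      window <- max(1L, as.integer(round(300 / trajectory$config$save_stride)))
    }
  } else {
    chan <- as.matrix(trajectory)
    n_bp <- sum(grepl("^pairing_", colnames(chan)))
    seq1 <- attr(trajectory, "seq1")
    ntype <- attr(trajectory, "nucleic_type")
    if (is.null(window)) window <- 1L
  }
  if (is.null(chan) || ncol(chan) == 0) stop("trajectory has no channels")
  if (is.null(native)) {
    native <- chan[1, ]
  }
  sm <- apply(chan, 2, smooth_series, window = window)
  if (is.null(dim(sm))) {
    sm <- matrix(sm, nrow = 1, dimnames = list(NULL, colnames(chan)))
  }
  hi <- native + thresholds$delta
  lo <- hi - thresholds$hysteresis

  nf <- nrow(sm)
  pair_states <- matrix("CLOSED", nf, n_bp)
  for (k in seq_len(n_bp - 1L)) {
    dp <- .hyst(sm[, paste0("pairing_", k)], hi[paste0("pairing_", k)],
                lo[paste0("pairing_", k)])
    d5 <- .hyst(sm[, paste0("stack5_", k)], hi[paste0("stack5_", k)],
                lo[paste0("stack5_", k)])
    d3 <- .hyst(sm[, paste0("stack3_", k)], hi[paste0("stack3_", k)],
                lo[paste0("stack3_", k)])
    st <- rep("OPEN", nf)
    st[!dp & !d5 & !d3] <- "CLOSED"
    st[d5 & !d3] <- "FLIP5"
    st[d3 & !d5] <- "FLIP3"
    pair_states[, k] <- st
  }
  dp <- .hyst(sm[, paste0("pairing_", n_bp)], hi[paste0("pairing_", n_bp)],
              lo[paste0("pairing_", n_bp)])
  pair_states[, n_bp] <- ifelse(dp, "OPEN", "CLOSED")

  open_m <- pair_states == "OPEN"
  junction <- apply(open_m, 1, function(z) {
    w <- which(!z)
    if (length(w)) w[1] else n_bp + 1L
  })
  state <- pair_states[cbind(seq_len(nf), pmin(junction, n_bp))]
  state[junction > n_bp] <- "OPEN"
  ctx <- rep(NA_character_, nf)
  has_ctx <- junction < n_bp
  if (!is.null(seq1) && any(has_ctx)) {
    ctx[has_ctx] <- nn_context(seq1, junction[has_ctx], ntype)
  }
  out <- data.frame(
    frame = seq_len(nf),
    junction = junction,
    state = factor(state, levels = JUNCTION_STATES),
    context = ctx,
    stringsAsFactors = FALSE
  )
  attr(out, "pair_states") <- pair_states
  attr(out, "window") <- window
  attr(out, "seq1") <- seq1
  if (!is.null(seq1)) {
    attr(out, "contexts") <- nn_context(seq1, seq_len(n_bp - 1L), ntype)
  }
  class(out) <- c("junction_state_series", "data.frame")
  out
}

#' Nearest-neighbour context label
#'
#' The context of the junction pair `k` is written `XY/X'Y'`: `XY` is the
#' dinucleotide read 5'->3' on the strand that presents its 5' terminus at
#' the junction (the opening pair first, then the stacked pair inward), and
#' `X'Y'` the complementary dinucleotide read 5'->3'.  Both strands are
#' retained, so strand-swapped cases (GG/CC vs CC/GG) stay distinct.
#'
#' @param seq1 The 5'-strand sequence, 5'->3' (junction side first).
#' @param k Junction pair index (vectorized), 1 <= k < nchar(seq1).
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return Character vector of context labels.
#' @export
nn_context <- function(seq1, k, nucleic_type = "DNA") {
  comp <- WC_COMP[[nucleic_type]]
  b <- strsplit(seq1, "")[[1]]
  paste0(b[k], b[k + 1], "/", comp[b[k + 1]], comp[b[k]])
}

#' All 16 nearest-neighbour contexts
#'
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return Character vector of the 16 context labels.
#' @export
all_contexts <- function(nucleic_type = "DNA") {
  ab <- NUC_ALPHABET[[nucleic_type]]
  g <- expand.grid(second = ab, first = ab, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(g)), function(i) {
    nn_context(paste0(g$first[i], g$second[i]), 1L, nucleic_type)
  }, character(1))
}

#' Extract opening/closing events from a state series
#'
#' A pair-level state series is segmented into complete CLOSED -> OPEN
#' (opening) and OPEN -> CLOSED (closing) excursions.  Dwells shorter than
#' `min_dwell` frames are absorbed into the preceding state (debouncing).
#' The pathway label is the intermediate (FLIP5/FLIP3) with the longest
#' total dwell between the terminal CLOSED and OPEN frames; `direct` if no
#' intermediate was visited, `ambiguous` on an exact tie.  Excursions that
#' return to the starting macrostate without reaching the other are
#' discarded.
#'
#' @param states Character/factor vector of per-frame states (one pair), or
#'   a `junction_state_series` (its junction-pair states are used and events
#'   are extracted per pair from the `pair_states` attribute).
#' @param min_dwell Debounce length in frames.
#' @param context Optional context label attached to the events.
#' @return data.frame with `direction` ("opening"/"closing"), `pathway`
#'   ("via_FLIP5", "via_FLIP3", "direct", "ambiguous"), `context`, `start`,
#'   `end` (frame indices).
#' @export
extract_events <- function(states, min_dwell = 1L, context = NA_character_) {
  if (inherits(states, "junction_state_series")) {
    ps <- attr(states, "pair_states")
    seq1 <- attr(states, "seq1")
    out <- lapply(seq_len(ncol(ps) - 1L), function(k) {
      extract_events(ps[, k], min_dwell = min_dwell,
                     context = attr(states, "contexts")[k])
    })
    return(do.call(rbind, out))
  }
  s <- as.character(states)
  if (length(s) == 0L) {
    return(data.frame(
      direction = character(0), pathway = character(0),
      context = character(0), start = integer(0), end = integer(0)
    ))
  }
  r <- rle(s)
  # debounce: merge short dwells into the previous retained state
  if (min_dwell > 1L && length(r$lengths) > 1L) {
    keep_v <- character(0)
    keep_l <- integer(0)
    for (t in seq_along(r$lengths)) {
      if (r$lengths[t] < min_dwell && length(keep_v) > 0L) {
        keep_l[length(keep_l)] <- keep_l[length(keep_l)] + r$lengths[t]
      } else if (length(keep_v) > 0L && r$values[t] == keep_v[length(keep_v)]) {
        keep_l[length(keep_l)] <- keep_l[length(keep_l)] + r$lengths[t]
      } else {
        keep_v <- c(keep_v, r$values[t])
        keep_l <- c(keep_l, r$lengths[t])
      }
    }
    r <- list(values = keep_v, lengths = keep_l)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  macro <- which(r$values %in% c("CLOSED", "OPEN"))
  ev <- list()
  if (length(macro) >= 2L) {
    for (t in seq_len(length(macro) - 1L)) {
      a <- macro[t]; b <- macro[t + 1L]
      sa <- r$values[a]; sb <- r$values[b]
      if (sa == sb) next
      between <- seq(a + 1L, length.out = b - a - 1L)
      d5 <- sum(r$lengths[between][r$values[between] == "FLIP5"])
      d3 <- sum(r$lengths[between][r$values[between] == "FLIP3"])
      pathway <- if (d5 == 0 && d3 == 0) "direct"
        else if (d5 > d3) "via_FLIP5"
        else if (d3 > d5) "via_FLIP3"
        else "ambiguous"
      ev[[length(ev) + 1L]] <- data.frame(
        direction = if (sa == "CLOSED") "opening" else "closing",
        pathway = pathway, context = context,
        start = ends[a], end = starts[b],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(ev) == 0L) {
    return(data.frame(
      direction = character(0), pathway = character(0),
      context = character(0), start = integer(0), end = integer(0)
    ))
  }
  do.call(rbind, ev)
}

#' Write a junction state series as TSV
#'
#' @param series A `junction_state_series`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_states_tsv <- function(series, file) {
  utils::write.table(as.data.frame(series), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
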