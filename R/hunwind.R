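# The h-unwind helix-unwindability index.
#
# A helicase loads on an overhang of the tracking strand and translocates
# into the duplex, peeling off the displaced strand by steric exclusion.
# Unwinding is easiest when the displaced strand's junction base flips out
# readily: stacked displaced bases are the bottleneck.  Stepping base pair
# by base pair in the helicase's travel direction, the nearest-neighbour
# free-energy table gives the probability that the displaced base (rather
# than its partner) is the flipped-out one:
#   p = 1 / (1 + exp(-s g / kT)),   s = +1 if the displaced base's flip is
# the FLIP5 (3'-dangling) intermediate of that context, s = -1 otherwise.
# h-unwind is the mean of p over the junction steps: it is inversely
# related to the population of stacked nucleobases on the displaced strand,
# so higher values predict more efficient unwinding.
#
# Which strand presents its 5' terminus at the advancing junction is set by
# the helicase's entry end: a 5'->3' helicase tracks along its strand's 5'
# overhang, so the tracking strand is the 5'-strand at every junction
# (s = -1 throughout); for a 3'->5' helicase the displaced strand is the
# 5'-strand (s = +1).

#' Define an unwinding task
#'
#' @param strand1,strand2 The duplex strands, both 5'->3'; `strand2` must be
#'   the reverse complement of `strand1`.
#' @param tracking Which strand the helicase translocates along (1 or 2).
#' @param directionality `"5to3"` or `"3to5"` translocation polarity.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return An `unwinding_task`.
#' @export
unwinding_task <- function(strand1, strand2, tracking = 1,
                           directionality = c("5to3", "3to5"),
                           nucleic_type = "DNA") {
  directionality <- match.arg(directionality)
  if (reverse_complement(strand1, nucleic_type) != strand2) {
    stop("strands are not reverse complements")
  }
  stopifnot(tracking %in% c(1, 2))
  t <- list(
    strand1 = strand1, strand2 = strand2,
    tracking = as.integer(tracking),
    displaced = if (tracking == 1) 2L else 1L,
    directionality = directionality,
    nucleic_type = nucleic_type
  )
  class(t) <- "unwinding_task"
  t
}

# The strand that presents its 5' terminus at every junction as the
# helicase advances (see header comment).
.five_prime_strand <- function(task) {
  if (task$directionality == "5to3") task$tracking else task$displaced
}

#' h-unwind score of an unwinding task
#'
#' @param task An [unwinding_task()].
#' @param table An `nn_dg_table` (g in kT units), e.g. from [dangling_dg()];
#'   every context stepped through must be present with finite `g`.
#' @param aggregate `"mean"` (default: mean flip probability) or
#'   `"log"` (exponential of the mean log probability), the latter provided
#'   for sensitivity analysis.
#' @return An `unwind_score`: list with `h_unwind`, `steps` (data.frame:
#'   junction, context, s, g, p), `aggregate`.
#' @export
hunwind <- function(task, table, aggregate = c("mean", "log")) {
  aggregate <- match.arg(aggregate)
  g_of <- stats::setNames(table$g, table$context)
  fps <- .five_prime_strand(task)
  seq5 <- if (fps == 1L) task$strand1 else task$strand2
  n <- nchar(seq5)
  # junction steps in travel order: contexts of pairs 1..n-1 read on the
  # 5'-strand; the last pair reuses its only available context
  ks <- c(seq_len(n - 1L), n - 1L)
  ctx <- nn_context(seq5, ks, task$nucleic_type)
  s_sign <- if (fps == task$displaced) 1 else -1
  missing <- setdiff(unique(ctx), names(g_of)[is.finite(g_of)])
  if (length(missing)) {
    stop("context(s) missing from table: ", paste(missing, collapse = ", "))
  }
  g <- unname(g_of[ctx])
  p <- 1 / (1 + exp(-s_sign * g))
  h <- switch(aggregate, mean = mean(p), log = exp(mean(log(p))))
  out <- list(
    h_unwind = h,
    steps = data.frame(
      junction = seq_len(n), context = ctx, s = s_sign, g = g, p = p,
      stringsAsFactors = FALSE
    ),
    aggregate = aggregate,
    task = task
  )
  class(out) <- "unwind_score"
  out
}

#' @export
print.unwind_score <- function(x, ...) {
  cat(sprintf(
    "<unwind_score> h-unwind = %.4f (%s aggregate, %d steps, displaced strand %d, %s)\n",
    x$h_unwind, x$aggregate, nrow(x$steps), x$task$displaced,
    x$task$directionality
  ))
  invisible(x)
}

#' The four homopurine/homopyrimidine benchmark constructs
#'
#' Duplexes with a 21-nt homopurine-class ((AG) repeat) strand paired to its
#' homopyrimidine complement ((CT) repeat).  `Pu_5-3`/`Py_5-3` are the same
#' double helix with tracking/displaced roles swapped, processed by a 5'->3'
#' helicase; `Pu_3-5`/`Py_3-5` likewise for a 3'->5' helicase.  `Pu`/`Py`
#' names the strand class being displaced.
#'
#' @param n_bp Duplex length (default 21).
#' @param nucleic_type `"DNA"` (default) or `"RNA"`.
#' @return Named list of four [unwinding_task()]s.
#' @export
design_constructs <- function(n_bp = 21, nucleic_type = "DNA") {
  pu <- paste(rep(c("A", "G"), length.out = n_bp), collapse = "")
  py <- reverse_complement(pu, nucleic_type)
  list(
    `Pu_5-3` = unwinding_task(py, pu, tracking = 1,
                              directionality = "5to3",
                              nucleic_type = nucleic_type),
    `Py_5-3` = unwinding_task(pu, py, tracking = 1,
                              directionality = "5to3",
                              nucleic_type = nucleic_type),
    `Pu_3-5` = unwinding_task(py, pu, tracking = 1,
                              directionality = "3to5",
                              nucleic_type = nucleic_type),
    `Py_3-5` = unwinding_task(pu, py, tracking = 1,
                              directionality = "3to5",
                              nucleic_type = nucleic_type)
  )
}

#' Rank unwinding predictions
#'
#' @param scores Named list of `unwind_score`s (>= 2).
#' @param tol Scores closer than this are flagged as tied.
#' @return data.frame sorted by descending h-unwind with a `tied` flag.
#' @export
rank_predictions <- function(scores, tol = 1e-9) {
  if (length(scores) < 2) stop("need at least two scores to rank")
  h <- vapply(scores, function(s) s$h_unwind, numeric(1))
  ord <- order(h, decreasing = TRUE)
  h <- h[ord]
  tied <- rep(FALSE, length(h))
  for (i in seq_along(h)) {
    tied[i] <- any(abs(h[-i] - h[i]) < tol)
  }
  data.frame(
    construct = names(h), h_unwind = unname(h), rank = seq_along(h),
    tied = tied, stringsAsFactors = FALSE
  )
}

#' A uniform toy free-energy table
#'
#' Every context in which the 5'-strand junction base is a purine gets
#' `g = -g_mag` (purine flip disfavoured) and every pyrimidine-opening
#' context `g = +g_mag`; useful as a closed-form reference ("purines have
#' lower propensity to flip out than pyrimidines").
#'
#' @param g_mag Magnitude in kT.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return An `nn_dg_table`.
#' @export
toy_dg_table <- function(g_mag = 1, nucleic_type = "DNA") {
  ctx <- all_contexts(nucleic_type)
  first <- substr(ctx, 1, 1)
  tab <- data.frame(
    context = ctx,
    g = ifelse(first %in% PURINES, -g_mag, g_mag),
    se = 0, n5 = NA, n3 = NA, w5 = NA, w3 = NA,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("nn_dg_table", "data.frame")
  tab
}
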