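# Construction of Calpha positions for target residues covered by no
# template: terminal gaps grow outward from the adjacent covered residue,
# internal gaps are closed left-to-right under distance restraints to the
# right anchor. "Sample points around A" is realized as uniform-direction,
# uniform-radius shell sampling with a try budget per residue; among
# candidates none of which is clash-free, the one with fewest clashes wins,
# ties broken by the larger minimum distance to existing atoms.

#' Distance restraints for closing an internal gap
#'
#' For a gap with k residues remaining and current anchor separation d_AB,
#' the next placed point must lie within [max(3.5, dd (k-1)),
#' max(4.5, max(3.8 k, dd k))] of the far anchor, where dd = d_AB / (k + 1).
#'
#' @param d_AB distance between the current left anchor and the right anchor
#'   (Angstrom), > 0.
#' @param k number of gap residues still to place, >= 1.
#' @return c(lower, upper) in Angstrom.
#' @export
internal_gap_bounds <- function(d_AB, k) {
  if (k < 1L) stop("no gap remains (k must be >= 1)")
  if (d_AB <= 0) stop("anchor distance must be positive")
  dd <- d_AB / (k + 1)
  c(lower = max(3.5, dd * (k - 1)),
    upper = max(4.5, max(3.8 * k, dd * k)))
}

#' Sample a point on a spherical shell
#'
#' Uniform direction on the sphere, radius uniform in [r_min, r_max].
#'
#' @param center length-3 coordinate.
#' @param r_min,r_max shell radii in Angstrom (default 3.5 and 4.5, the
#'   clash and chain-break distances).
#' @param n number of points.
#' @return n x 3 matrix (or length-3 vector when n = 1).
#' @export
sample_shell_point <- function(center, r_min = 3.5, r_max = 4.5, n = 1L) {
  stopifnot(r_min < r_max)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- stats::runif(n, r_min, r_max)
  out <- sweep(v * r, 2, as.numeric(center), "+")
  if (n == 1L) as.numeric(out) else out
}

gap_clash_stats <- function(candidates, existing, clash_dist = 3.5) {
  if (is.null(existing) || nrow(existing) == 0L)
    return(list(clashes = rep(0L, nrow(candidates)),
                min_dist = rep(Inf, nrow(candidates))))
  d2 <- outer(rowSums(candidates^2), rowSums(existing^2), "+") -
    2 * candidates %*% t(existing)
  d2[d2 < 0] <- 0
  list(clashes = rowSums(d2 < clash_dist^2),
       min_dist = sqrt(apply(d2, 1, min)))
}

pick_candidate <- function(candidates, existing, feasible = NULL,
                           clash_dist = 3.5) {
  st <- gap_clash_stats(candidates, existing, clash_dist)
  ok <- if (is.null(feasible)) rep(TRUE, nrow(candidates)) else feasible
  pool <- which(ok)
  if (length(pool) == 0L) pool <- seq_len(nrow(candidates))
  clash_free <- pool[st$clashes[pool] == 0L]
  if (length(clash_free)) {
    # earliest clash-free feasible candidate (cheap and reproducible)
    best <- clash_free[which.max(st$min_dist[clash_free])]
  } else {
    o <- order(st$clashes[pool], -st$min_dist[pool])
    best <- pool[o[1]]
  }
  list(point = candidates[best, ], clashes = st$clashes[best])
}

#' Locate gap runs in a model
#'
#' @param model \code{ca_model} whose unplaced residues have provenance
#'   \code{"none"}.
#' @return list of runs, each with \code{kind} ("terminal-N", "terminal-C" or
#'   "internal"), \code{indices} (target indices) and \code{anchors}.
#' @export
find_gap_runs <- function(model) {
  unplaced <- model$index[model$provenance == "none"]
  runs <- contiguous_groups(unplaced)
  lapply(runs, function(r) {
    r <- as.integer(r)
    at_n <- min(r) == model$index[1]
    at_c <- max(r) == model$index[length(model$index)]
    if (at_n && at_c) stop("no covered residue in model range")
    if (at_n) list(kind = "terminal-N", indices = r, anchors = max(r) + 1L)
    else if (at_c) list(kind = "terminal-C", indices = r, anchors = min(r) - 1L)
    else list(kind = "internal", indices = r,
              anchors = c(min(r) - 1L, max(r) + 1L))
  })
}

#' Build a terminal gap by outward shell sampling
#'
#' Starting at the covered residue adjacent to the gap, each gap residue is
#' placed 3.5--4.5 Angstrom from its predecessor, avoiding clashes
#' (>= 3.5 Angstrom to all placed atoms), then becomes the anchor for the
#' next one.
#'
#' @param run gap run from \code{\link{find_gap_runs}}, kind terminal-N or -C.
#' @param model \code{ca_model} with the anchor placed.
#' @param tries shell-sample budget per residue (default 500).
#' @return the model with the gap residues placed (provenance "gap").
#' @export
build_terminal_gap <- function(run, model, tries = 500L) {
  if (length(run$indices) == 0L) return(model)
  order_idx <- if (run$kind == "terminal-N") rev(run$indices) else run$indices
  a <- model$xyz[model_row(model, run$anchors), ]
  for (i in order_idx) {
    cand <- sample_shell_point(a, n = tries)
    existing <- model$xyz[apply(is.finite(model$xyz), 1, all), , drop = FALSE]
    sel <- pick_candidate(cand, existing)
    r <- model_row(model, i)
    model$xyz[r, ] <- sel$point
    model$provenance[r] <- "gap"
    a <- sel$point
  }
  model
}

#' Close an internal gap under distance restraints
#'
#' Gap residues are placed left to right. Each point lies 3.5--4.5 Angstrom
#' from its predecessor (shell sampling around the advancing anchor A) and
#' within \code{\link{internal_gap_bounds}}(d_AB, k) of the fixed right
#' anchor B, where d_AB is recomputed and k decremented as A advances. When no
#' clash-free candidate satisfies the bounds within the try budget, the
#' least-clashing feasible candidate is used.
#'
#' @param run gap run of kind "internal".
#' @param model \code{ca_model} with both anchors placed.
#' @param tries shell-sample budget per residue (default 500).
#' @return the model with the gap filled.
#' @export
build_internal_gap <- function(run, model, tries = 500L) {
  if (length(run$indices) == 0L) return(model)
  a <- model$xyz[model_row(model, run$anchors[1]), ]
  b <- model$xyz[model_row(model, run$anchors[2]), ]
  if (sqrt(sum((a - b)^2)) < 1e-9) stop("internal gap anchors are identical")
  k <- length(run$indices)
  for (i in run$indices) {
    d_ab <- sqrt(sum((a - b)^2))
    bounds <- internal_gap_bounds(d_ab, k)
    cand <- sample_shell_point(a, n = tries)
    d_to_b <- sqrt(rowSums(sweep(cand, 2, b)^2))
    feasible <- d_to_b >= bounds[1] & d_to_b <= bounds[2]
    existing <- model$xyz[apply(is.finite(model$xyz), 1, all), , drop = FALSE]
    sel <- pick_candidate(cand, existing, feasible = feasible)
    r <- model_row(model, i)
    model$xyz[r, ] <- sel$point
    model$provenance[r] <- "gap"
    a <- sel$point
    k <- k - 1L
  }
  model
}

#' Fill every gap run in a model
#'
#' Runs are processed from the N- to the C-terminus; terminal and internal
#' gaps use their respective builders. Gap residues are frozen afterwards
#' (not resampled by annealing).
#'
#' @param model \code{ca_model} with covered residues placed and gaps
#'   provenance "none".
#' @param tries per-residue shell budget.
#' @return fully placed model.
#' @export
fill_gaps <- function(model, tries = 500L) {
  runs <- find_gap_runs(model)
  for (run in runs) {
    model <- if (run$kind == "internal") build_internal_gap(run, model, tries)
             else build_terminal_gap(run, model, tries)
  }
  model
}
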