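#' Rigid-body transform
#'
#' A proper rotation plus translation acting on row-vector coordinates as
#' \code{x \%*\% t(R) + t}.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation in Angstrom.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a \code{rigid_transform}.
#' @param coords n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{moving} onto \code{fixed} over paired points, via SVD of the
#' cross-covariance matrix with the usual determinant sign correction.
#'
#' @param moving,fixed n x 3 coordinate matrices of paired points, n >= 3.
#' @return List with \code{transform} (a \code{rigid_transform}), \code{rmsd}
#'   (the minimized RMSD in Angstrom) and \code{degenerate} (TRUE when the
#'   point set is rank-deficient, e.g. collinear; the least-squares solution
#'   is still returned).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as_coord_matrix(moving)
  fixed <- as_coord_matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate sets differ in length")
  if (nrow(moving) < 3L) stop("need at least 3 paired points")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("non-finite coordinates")
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  t_vec <- cf - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t_vec)
  moved <- apply_transform(tr, moving)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(transform = tr, rmsd = rmsd, degenerate = degenerate)
}

#' RMSD of paired coordinates without superposition
#' @param a,b n x 3 matrices.
#' @return Root-mean-square deviation in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rotation about an axis (Rodrigues formula)
#'
#' @param u unit length-3 axis vector (|u| = 1 within 1e-6).
#' @param theta rotation angle in radians.
#' @return A \code{rigid_transform} with zero translation.
#' @export
rotation_about_axis <- function(u, theta) {
  u <- as.numeric(u)
  if (length(u) != 3L || abs(sqrt(sum(u^2)) - 1) > 1e-6)
    stop("axis must be a unit 3-vector")
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  rigid_transform(R, c(0, 0, 0))
}

#' TM-score d0 length normalization
#' @param l_target target length.
#' @return d0 in Angstrom, clamped at 0.5 for short targets.
#' @export
tm_d0 <- function(l_target) {
  if (l_target < 1) stop("L_target must be >= 1")
  max(0.5, 1.24 * sign(l_target - 15) * abs(l_target - 15)^(1 / 3) - 1.8)
}

tm_from_dist <- function(d, d0, l_target) sum(1 / (1 + (d / d0)^2)) / l_target

#' Template-modeling score of paired coordinate sets
#'
#' Length-normalized structural similarity in (0, 1]. Superposes the common
#' residues with the Kabsch algorithm, then iteratively re-superposes on the
#' subset of residues closer than d0 until the residue subset converges,
#' keeping the best score seen. d0 = 1.24 (L-15)^(1/3) - 1.8, clamped at 0.5.
#'
#' @param model,reference n x 3 paired coordinates over the common residues.
#' @param l_target normalizing length (defaults to the number of pairs).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference, l_target = nrow(as_coord_matrix(reference))) {
  tm_superpose(model, reference, l_target)$tm
}

#' TM-score-maximizing superposition
#'
#' The trimmed-fit search behind \code{\link{tm_score}}: an initial Kabsch fit
#' over all common residues, then repeated refits restricted to the residues
#' currently within d0, keeping the transform with the highest TM-score. This
#' mirrors the superposition of the TM-score program and is robust to
#' localized structural disagreement.
#'
#' @param model,reference n x 3 paired coordinates over the common residues.
#' @param l_target normalizing length (defaults to the number of pairs).
#' @return list with \code{tm} and \code{transform} (a
#'   \code{rigid_transform} mapping model onto reference).
#' @export
tm_superpose <- function(model, reference,
                         l_target = nrow(as_coord_matrix(reference))) {
  model <- as_coord_matrix(model); reference <- as_coord_matrix(reference)
  if (nrow(model) == 0L) stop("no common residues")
  stopifnot(nrow(model) == nrow(reference))
  d0 <- tm_d0(l_target)
  if (nrow(model) < 3L) {
    # too few points for a meaningful superposition; translate centroids only
    shift <- colMeans(reference) - colMeans(model)
    d <- sqrt(rowSums((sweep(model, 2, -shift) - reference)^2))
    return(list(tm = tm_from_dist(d, d0, l_target),
                transform = rigid_transform(diag(3), shift)))
  }
  n <- nrow(model)
  # seed superpositions: all residues, plus contiguous windows so that a
  # well-agreeing fragment can anchor the fit even when the global Kabsch
  # frame is dragged away by a disagreeing region
  w <- max(4L, min(20L, n %/% 3L))
  starts <- unique(c(1L, seq(1L, max(1L, n - w + 1L),
                             by = max(1L, w %/% 2L)), max(1L, n - w + 1L)))
  seeds <- c(list(seq_len(n)),
             lapply(starts, function(s) s:min(n, s + w - 1L)))
  seeds <- Filter(function(ix) length(ix) >= 3L, seeds)
  best <- -Inf
  best_tr <- NULL
  for (ix in seeds) {
    sup <- kabsch_superpose(model[ix, , drop = FALSE],
                            reference[ix, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(sup$transform, model) - reference)^2))
    tm <- tm_from_dist(d, d0, l_target)
    if (tm > best) { best <- tm; best_tr <- sup$transform }
    subset_prev <- NULL
    for (iter in seq_len(20L)) {
      subset <- d < pmax(d0, sort(d)[3L])  # keep at least 3 closest points
      if (sum(subset) < 3L || identical(subset, subset_prev)) break
      sup <- kabsch_superpose(model[subset, , drop = FALSE],
                              reference[subset, , drop = FALSE])
      d <- sqrt(rowSums((apply_transform(sup$transform, model) -
                           reference)^2))
      tm <- tm_from_dist(d, d0, l_target)
      if (tm > best) { best <- tm; best_tr <- sup$transform }
      subset_prev <- subset
    }
  }
  list(tm = best, transform = best_tr)
}

#' Global distance test (total score) of paired coordinates
#'
#' Mean over distance cutoffs 1, 2, 4, 8 Angstrom of the largest fraction of
#' residues within the cutoff over a set of trial superpositions: one Kabsch
#' fit on all residues plus restarts on contiguous 20-residue windows. This is
#' an approximation of the full GDT search, used for evaluation only.
#'
#' @param model,reference n x 3 paired coordinates.
#' @return GDT-TS in [0, 1].
#' @export
gdt_ts <- function(model, reference) {
  model <- as_coord_matrix(model); reference <- as_coord_matrix(reference)
  if (nrow(model) == 0L) stop("empty input")
  stopifnot(nrow(model) == nrow(reference))
  n <- nrow(model)
  cutoffs <- c(1, 2, 4, 8)
  if (n < 3L) {
    shift <- colMeans(reference) - colMeans(model)
    d <- sqrt(rowSums((sweep(model, 2, -shift) - reference)^2))
    return(mean(vapply(cutoffs, function(ct) mean(d <= ct), 1.0)))
  }
  starts <- unique(c(1L, seq(1L, max(1L, n - 19L), by = 10L),
                     max(1L, n - 19L)))
  window_sets <- lapply(starts, function(s) s:min(n, s + 19L))
  window_sets <- Filter(function(ix) length(ix) >= 3L, window_sets)
  trials <- c(list(seq_len(n)), window_sets)
  best <- rep(0, length(cutoffs))
  for (ix in trials) {
    sup <- kabsch_superpose(model[ix, , drop = FALSE],
                            reference[ix, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(sup$transform, model) - reference)^2))
    frac <- vapply(cutoffs, function(ct) mean(d <= ct), 1.0)
    best <- pmax(best, frac)
  }
  mean(best)
}
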