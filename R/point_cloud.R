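# Per-residue weighted point clouds from superposed templates, and sampling
# of candidate positions from the per-residue multivariate normal.

#' Build per-residue weighted point clouds
#'
#' For each target residue covered by at least one superposed template, the
#' covering templates' Calpha positions form a weighted point cloud with
#' centroid p_avg_i = (1/sw_i) sum_j w_j p_ij and spread
#' wad_i = (1/sw_i) sum_j w_j ||p_ij - p_avg_i|| (the weighted average
#' distance). A residue is unfixed when wad_i > 0.5 Angstrom; unfixed residues
#' are resampled during annealing.
#'
#' @param templates superposed, trimmed templates.
#' @param weights data.frame from \code{\link{compute_weights}} (column
#'   \code{total} is used as w_j).
#' @param unfixed_cut spread threshold in Angstrom (default 0.5, strict).
#' @return named list (by target index) of clouds, each a list with fields
#'   \code{i}, \code{points} (n_i x 3), \code{weights}, \code{n}, \code{sw},
#'   \code{p_avg}, \code{wad}, \code{unfixed}.
#' @export
build_clouds <- function(templates, weights, unfixed_cut = 0.5) {
  ids <- vapply(templates, `[[`, "", "id")
  w <- weights$total[match(ids, weights$id)]
  if (anyNA(w)) stop("weights missing for some templates")
  covered <- sort(unique(unlist(lapply(templates, `[[`, "idx"))))
  clouds <- lapply(covered, function(i) {
    has <- vapply(templates, function(t) i %in% t$idx, TRUE)
    pts <- do.call(rbind, lapply(templates[has], function(t)
      t$xyz[match(i, t$idx), , drop = FALSE]))
    wj <- w[has]
    sw <- sum(wj)
    p_avg <- colSums(pts * wj) / sw
    d <- sqrt(rowSums(sweep(pts, 2, p_avg)^2))
    wad <- sum(wj * d) / sw
    list(i = i, points = pts, weights = wj, n = sum(has), sw = sw,
         p_avg = p_avg, wad = wad, unfixed = wad > unfixed_cut)
  })
  names(clouds) <- covered
  clouds
}

#' Partition cloud residues into fixed and unfixed
#'
#' A residue is unfixed when its weighted average distance is strictly
#' greater than 0.5 Angstrom.
#'
#' @param clouds list from \code{\link{build_clouds}}.
#' @return list with integer vectors \code{fixed} and \code{unfixed}.
#' @export
classify_unfixed <- function(clouds) {
  i <- unname(vapply(clouds, `[[`, 0L, "i"))
  un <- unname(vapply(clouds, `[[`, TRUE, "unfixed"))
  list(fixed = i[!un], unfixed = i[un])
}

#' Sample candidate positions for a residue
#'
#' Draws i.i.d. points from the residue's three-dimensional normal
#' distribution: mean p_avg_i, isotropic diagonal covariance with standard
#' deviation wad_i per coordinate (off-diagonals 0), via
#' \code{MASS::mvrnorm}. A floor of 1e-6 Angstrom on the standard deviation
#' avoids a degenerate density when a residue is forced to resample.
#'
#' Randomness comes from R's global generator; seed at the entry point for
#' reproducibility.
#'
#' @param cloud one cloud from \code{\link{build_clouds}}.
#' @param count number of draws (default 100).
#' @return count x 3 matrix of sampled coordinates.
#' @export
sample_candidates <- function(cloud, count = 100L) {
  if (count < 1L) stop("count must be >= 1")
  if (!is.null(cloud$unfixed) && cloud$unfixed && cloud$wad <= 0)
    stop("unfixed residue with non-positive spread")
  sd <- max(cloud$wad, 1e-6)
  matrix(MASS::mvrnorm(n = count, mu = cloud$p_avg,
                       Sigma = diag(sd^2, 3)),
         ncol = 3, byrow = FALSE)
}
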