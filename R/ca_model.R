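#' Calpha-trace model
#'
#' Ordered per-residue Calpha coordinates over a contiguous target index
#' range, with per-residue provenance.
#'
#' @param index contiguous integer target indices.
#' @param xyz n x 3 coordinate matrix (rows may be NA before gap building).
#' @param provenance per-residue origin: one of \code{"fixed"} (template
#'   covered, cloud spread <= 0.5 A), \code{"unfixed"} (template covered,
#'   resampled during annealing), \code{"gap"} (built by shell sampling), or
#'   \code{"none"} (not yet placed).
#' @param codes optional one-letter residue codes.
#' @return Object of class \code{ca_model}.
#' @export
ca_model <- function(index, xyz, provenance = rep("none", length(index)),
                     codes = NULL) {
  index <- as.integer(index)
  if (length(index) && !all(diff(index) == 1L))
    stop("model index range must be contiguous")
  xyz <- as_coord_matrix(xyz)
  stopifnot(nrow(xyz) == length(index), length(provenance) == length(index))
  structure(list(index = index, xyz = xyz,
                 provenance = as.character(provenance), codes = codes),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  n <- length(x$index)
  placed <- sum(apply(is.finite(x$xyz), 1, all))
  cat("Cα-trace model: residues ", x$index[1], "-", x$index[n],
      " (", n, " residues, ", placed, " placed)\n", sep = "")
  tab <- table(factor(x$provenance, c("fixed", "unfixed", "gap", "none")))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (placed == n)
    cat("  clashes:", count_clashes(x), "\n")
  invisible(x)
}

model_row <- function(model, target_index) {
  match(as.integer(target_index), model$index)
}

#' Consecutive Calpha distances of a model
#' @param model a placed \code{ca_model}.
#' @return numeric vector of length n-1.
#' @export
consecutive_distances <- function(model) {
  xyz <- model$xyz
  sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}

#' Count Calpha clashes in a model
#'
#' Number of unordered non-adjacent residue pairs closer than the clash
#' distance (3.5 Angstrom).
#'
#' @param model a fully placed \code{ca_model}.
#' @param clash_dist clash cutoff in Angstrom.
#' @return integer clash count.
#' @export
count_clashes <- function(model, clash_dist = 3.5) {
  xyz <- if (inherits(model, "ca_model")) model$xyz else as_coord_matrix(model)
  n <- nrow(xyz)
  if (n < 3L) return(0L)
  dm <- as.matrix(stats::dist(xyz))
  close <- dm < clash_dist
  close[row(close) >= col(close)] <- FALSE      # upper triangle only
  close[cbind(seq_len(n - 1L), seq(2L, n))] <- FALSE  # adjacent pairs exempt
  sum(close)
}

#' Clashes between two coordinate sets
#'
#' Counts pairs (one atom from each set) closer than the cutoff; used for
#' inter-domain clash checks where the junction pair is adjacent in sequence
#' and therefore exempt.
#'
#' @param a,b coordinate matrices.
#' @param clash_dist cutoff in Angstrom.
#' @param exempt optional 2-column matrix of (row in a, row in b) pairs to
#'   ignore.
#' @return integer count.
#' @export
cross_clashes <- function(a, b, clash_dist = 3.5, exempt = NULL) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  close <- d2 < clash_dist^2
  if (!is.null(exempt)) close[exempt] <- FALSE
  sum(close)
}

min_cross_distance <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}
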