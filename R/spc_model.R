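#' Fit a multi-template Calpha model
#'
#' Front end to the full modeling pipeline
#' (\code{\link{build_full_model}}): reads the target--template alignment,
#' weights and selects templates, superposes them, builds per-residue point
#' clouds, fills gaps, refines unfixed residues by simulated annealing and
#' combines domains. Returns a fitted-model object with print, summary, plot
#' and coef methods.
#'
#' @param alignment path to an alignment file, or an \code{spc_alignment}.
#' @param seed integer seed controlling all randomness of the run.
#' @param iter_multiplier optional integer in [1, 500]; iterations =
#'   n_unfixed * multiplier instead of the default clamp(1000/n_unfixed,
#'   20, 100).
#' @param energy energy backend: \code{"default"} or
#'   \code{"external:<command>"}, or a function(model) -> numeric.
#' @param max_templates optional cap on selected templates.
#' @return object of class \code{spcmodel}: fields \code{model}
#'   (\code{ca_model}), \code{report}, \code{domains}, \code{call}.
#' @examples
#' case <- make_case("single-full", seed = 7)
#' fit <- spc_model(case$alignment, seed = 7)
#' fit
#' coef(fit)[1:3, ]
#' @export
spc_model <- function(alignment, seed = 1L, iter_multiplier = NULL,
                      energy = "default", max_templates = NULL) {
  config <- anneal_config(seed = seed, iter_multiplier = iter_multiplier)
  res <- build_full_model(alignment, config = config, energy = energy,
                          max_templates = max_templates)
  res$call <- match.call()
  class(res) <- c("spcmodel", class(res))
  res
}

#' @export
print.spcmodel <- function(x, ...) {
  r <- x$report
  cat("Multi-template Cα model for", r$target,
      "(", r$length, "residues )\n")
  cat("  templates selected:", paste(r$selected, collapse = ", "), "\n")
  cat("  domains:", length(r$domains))
  for (d in r$domains)
    cat("  [", d$range[1], "-", d$range[2], "]", sep = "")
  cat("\n")
  cat("  unfixed residues:", paste(r$n_unfixed, collapse = ", "), "\n")
  cat("  clashes (final model):", r$clashes_model, "\n")
  invisible(x)
}

#' @export
summary.spcmodel <- function(object, ...) {
  r <- object$report
  cat("Template weights (five-term):\n")
  print(r$weights, digits = 4)
  cat("\nDomains:\n")
  for (k in seq_along(r$domains)) {
    d <- r$domains[[k]]
    cat(sprintf("  D%d %d-%d  templates: %s  unfixed: %d", k, d$range[1],
                d$range[2], paste(d$templates, collapse = ","),
                r$n_unfixed[k]))
    if (is.finite(r$E_initial[k]))
      cat(sprintf("  E: %.3f -> %.3f  clashes: %d -> %d",
                  r$E_initial[k], r$E_final[k],
                  r$clashes_initial[k], r$clashes_final[k]))
    cat("\n")
  }
  cat("\nFinal model clashes:", r$clashes_model, "\n")
  maxd <- max(consecutive_distances(object$model))
  cat("Max consecutive Cα distance:", round(maxd, 3), "Å\n")
  invisible(object)
}

#' Coordinates of the fitted model
#' @param object an \code{spcmodel} fit.
#' @param ... unused.
#' @return L x 3 matrix of Calpha coordinates, rownames = target indices.
#' @export
coef.spcmodel <- function(object, ...) {
  m <- object$model$xyz
  rownames(m) <- object$model$index
  colnames(m) <- c("x", "y", "z")
  m
}

#' Plot annealing traces of a fit
#'
#' Energy (and clash count) per iteration for each annealed domain.
#'
#' @param x an \code{spcmodel} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.spcmodel <- function(x, ...) {
  traces <- Filter(Negate(is.null), lapply(x$domains, `[[`, "anneal"))
  traces <- Filter(function(a) nrow(a$trace) > 0, traces)
  if (!length(traces)) {
    message("nothing annealed (no unfixed residues)")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(length(traces), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]$trace
    plot(tr$iteration, tr$E, type = "l", xlab = "iteration", ylab = "energy",
         main = paste("domain", k), ...)
    graphics::points(tr$iteration[tr$accepted], tr$E[tr$accepted], pch = 20)
    plot(tr$iteration, tr$clashes, type = "s", xlab = "iteration",
         ylab = "clashes", main = "", ...)
  }
  invisible(x)
}
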