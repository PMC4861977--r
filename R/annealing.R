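# Simulated-annealing refinement of the Calpha trace: resample unfixed
# residues from their cloud distributions, validate against chain and clash
# restraints, score with a pluggable energy, accept/reject with a
# deterministic threshold, cool, and keep the best model.

#' Annealing configuration
#'
#' @param seed integer seed for R's global generator (NULL: leave RNG state).
#' @param iter_multiplier optional integer in [1, 500]; when given, the
#'   iteration count (and initial temperature) is n_unfixed * multiplier
#'   instead of the default clamp(1000 / n_unfixed, 20, 100).
#' @param samples_per_residue candidate draws per unfixed residue per
#'   iteration (default 100).
#' @param clash_dist,chain_dist clash (3.5 A) and chain-break (4.5 A) cutoffs.
#' @return list of class \code{anneal_config}.
#' @export
anneal_config <- function(seed = NULL, iter_multiplier = NULL,
                          samples_per_residue = 100L,
                          clash_dist = 3.5, chain_dist = 4.5) {
  if (!is.null(iter_multiplier) &&
      (iter_multiplier < 1 || iter_multiplier > 500))
    stop("iteration multiplier must be in [1, 500]")
  stopifnot(clash_dist < chain_dist)
  structure(list(seed = seed, iter_multiplier = iter_multiplier,
                 samples_per_residue = as.integer(samples_per_residue),
                 clash_dist = clash_dist, chain_dist = chain_dist),
            class = "anneal_config")
}

#' Initial temperature and iteration count
#'
#' By default N = T0 = 1000 / n_unfixed, clamped into [20, 100]. With an
#' iteration multiplier m in [1, 500], N = T0 = n_unfixed * m. With no
#' unfixed residues N = 0 and the initial model is final.
#'
#' @param n_unfixed number of unfixed residues (>= 0).
#' @param iter_multiplier optional integer in [1, 500].
#' @return list with \code{T0} and \code{N} (equal).
#' @export
initial_temperature <- function(n_unfixed, iter_multiplier = NULL) {
  stopifnot(n_unfixed >= 0)
  if (n_unfixed == 0) return(list(T0 = 0, N = 0))
  if (!is.null(iter_multiplier)) {
    if (iter_multiplier < 1 || iter_multiplier > 500)
      stop("iteration multiplier must be in [1, 500]")
    n <- n_unfixed * iter_multiplier
  } else {
    n <- min(100, max(20, 1000 / n_unfixed))
  }
  list(T0 = n, N = n)
}

#' Validate a candidate position against spatial restraints
#'
#' A candidate for residue i is valid iff its distance to each placed
#' adjacent residue lies in [clash_dist, chain_dist] (no clash, no broken
#' chain) and its distance to every placed non-adjacent residue is at least
#' clash_dist.
#'
#' @param candidate length-3 coordinate.
#' @param residue_index target index of the residue being moved.
#' @param model \code{ca_model} providing all other positions.
#' @param config \code{anneal_config}.
#' @return logical.
#' @export
validate_point <- function(candidate, residue_index, model,
                           config = anneal_config()) {
  ok <- validate_points(matrix(candidate, ncol = 3), residue_index, model,
                        config)
  ok[1]
}

# vectorized validity over a candidate matrix
validate_points <- function(candidates, residue_index, model, config) {
  r <- model_row(model, residue_index)
  placed <- apply(is.finite(model$xyz), 1, all)
  placed[r] <- FALSE
  if (!any(placed)) return(rep(TRUE, nrow(candidates)))
  xyz <- model$xyz[placed, , drop = FALSE]
  rows <- which(placed)
  d2 <- outer(rowSums(candidates^2), rowSums(xyz^2), "+") -
    2 * candidates %*% t(xyz)
  d2[d2 < 0] <- 0
  adj <- abs(rows - r) == 1L
  lo2 <- config$clash_dist^2
  hi2 <- config$chain_dist^2
  ok <- rowSums(d2[, !adj, drop = FALSE] < lo2) == 0L
  if (any(adj)) {
    da <- d2[, adj, drop = FALSE]
    ok <- ok & rowSums(da < lo2 | da > hi2) == 0L
  }
  ok
}

#' Propose a resampled model
#'
#' Visits unfixed residues in ascending target index; for each, draws up to
#' \code{samples_per_residue} candidates from its cloud distribution and
#' installs the first valid one, updating the working model immediately so
#' later residues see it. A residue with no valid candidate keeps its current
#' position.
#'
#' @param model current \code{ca_model}.
#' @param clouds list from \code{\link{build_clouds}}.
#' @param config \code{anneal_config}.
#' @return proposed \code{ca_model}.
#' @export
propose_model <- function(model, clouds, config = anneal_config()) {
  unfixed <- sort(vapply(Filter(function(cl) cl$unfixed, clouds), `[[`, 0L, "i"))
  unfixed <- unfixed[unfixed %in% model$index]
  for (i in unfixed) {
    cl <- clouds[[as.character(i)]]
    cand <- sample_candidates(cl, config$samples_per_residue)
    ok <- validate_points(cand, i, model, config)
    hit <- which(ok)
    if (length(hit)) {
      model$xyz[model_row(model, i), ] <- cand[hit[1], ]
    }
  }
  model
}

#' Acceptance rule of the annealing protocol
#'
#' Downhill moves (E_new < E_old) are always accepted and cool the system by
#' 1. For uphill moves the acceptance probability p = exp(-(E_new - E_old)/T)
#' is compared with the deterministic threshold 0.5: accepted iff p > 0.5
#' (equivalently dE < T log 2); the temperature then drops by
#' d = 0.2 (E_new - E_old) (iteration / N), floored at 1e-6, whether or not
#' the move is accepted.
#'
#' @param E_new,E_old energies of proposal and current model.
#' @param Temp current temperature (> 0).
#' @param iteration current iteration (1-based).
#' @param N total iteration count.
#' @return list with \code{accepted} and \code{T_next}.
#' @export
accept_step <- function(E_new, E_old, Temp, iteration, N) {
  stopifnot(Temp > 0, N >= 1)
  if (E_new < E_old) return(list(accepted = TRUE, T_next = Temp - 1))
  p <- exp(-(E_new - E_old) / Temp)
  d <- max(0.2 * (E_new - E_old) * (iteration / N), 1e-6)
  list(accepted = p > 0.5, T_next = Temp - d)
}

#' Default Calpha-trace energy
#'
#' A simple deterministic, rigid-motion-invariant pseudo-energy (lower is
#' better): a harmonic bond term on consecutive distances around 3.8 A, a
#' soft-sphere repulsion below 4.0 A for non-adjacent pairs, and a weak
#' radius-of-gyration restraint toward 2.2 L^0.38 (the empirical scaling of
#' globular proteins).
#'
#' @param model \code{ca_model} (fully placed).
#' @return energy (numeric scalar).
#' @export
default_ca_energy <- function(model) {
  xyz <- if (inherits(model, "ca_model")) model$xyz else as_coord_matrix(model)
  n <- nrow(xyz)
  dadj <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  e_bond <- sum((dadj - 3.8)^2)
  dm <- as.matrix(stats::dist(xyz))
  up <- row(dm) < col(dm) - 1L  # non-adjacent, unordered
  viol <- pmax(0, 4.0 - dm[up])
  e_rep <- sum(viol^2)
  ctr <- colMeans(xyz)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  e_rg <- 0.01 * (rg - 2.2 * n^0.38)^2
  e_bond + e_rep + e_rg
}

#' Resolve an energy backend by name
#'
#' \code{"default"} gives \code{\link{default_ca_energy}};
#' \code{"external:<command>"} returns a function that writes the model as a
#' PDB file, runs the command with the file as argument, and reads a single
#' number from its standard output (hook for user-supplied statistical
#' potentials).
#'
#' @param name backend name.
#' @return function(model) -> numeric.
#' @export
energy_backend <- function(name = "default") {
  if (identical(name, "default")) return(default_ca_energy)
  if (startsWith(name, "external:")) {
    cmd <- sub("^external:", "", name)
    return(function(model) {
      f <- tempfile(fileext = ".pdb")
      on.exit(unlink(f))
      write_pdb_model(model, f)
      out <- system2(cmd, args = shQuote(f), stdout = TRUE)
      val <- suppressWarnings(as.numeric(out[length(out)]))
      if (!is.finite(val)) stop("external energy command returned no number")
      val
    })
  }
  stop("unknown energy backend: ", name)
}

#' Run the simulated-annealing loop
#'
#' Starting from a complete initial model, iterates propose -> score ->
#' accept/reject -> cool until the iteration budget is exhausted or the
#' temperature reaches 0. Gap-built residues are frozen; only template-covered
#' unfixed residues are resampled. Returns the lowest-energy accepted model
#' (the initial model counts), with the last-accepted model and a per-iteration
#' trace also available.
#'
#' @param initial complete \code{ca_model} (gaps filled).
#' @param clouds list from \code{\link{build_clouds}}.
#' @param energy function(model) -> numeric, or a backend name.
#' @param config \code{anneal_config}.
#' @return list of class \code{anneal_result}: \code{best}, \code{E_best},
#'   \code{last}, \code{E_last}, \code{trace} (data.frame iteration, T, E,
#'   clashes, accepted), \code{N}, \code{T0}, \code{n_unfixed}.
#' @export
run_annealing <- function(initial, clouds, energy = default_ca_energy,
                          config = anneal_config()) {
  if (is.character(energy)) energy <- energy_backend(energy)
  unfixed <- classify_unfixed(clouds)$unfixed
  unfixed <- unfixed[unfixed %in% initial$index]
  temp <- initial_temperature(length(unfixed), config$iter_multiplier)
  e0 <- energy(initial)
  if (!is.finite(e0)) stop("energy of initial model is non-finite")
  state <- list(current = initial, E_old = e0, best = initial, E_best = e0,
                T = temp$T0, N = temp$N)
  trace <- list()
  iter <- 0L
  while (iter < state$N && state$T > 0) {
    iter <- iter + 1L
    proposal <- propose_model(state$current, clouds, config)
    e_new <- energy(proposal)
    if (!is.finite(e_new)) stop("energy returned a non-finite value")
    step <- accept_step(e_new, state$E_old, state$T, iter, state$N)
    if (step$accepted) {
      state$current <- proposal
      state$E_old <- e_new
      if (e_new < state$E_best) {
        state$best <- proposal
        state$E_best <- e_new
      }
    }
    state$T <- step$T_next
    trace[[iter]] <- data.frame(iteration = iter, T = state$T, E = e_new,
                                clashes = count_clashes(proposal,
                                                        config$clash_dist),
                                accepted = step$accepted)
  }
  trace <- if (length(trace)) do.call(rbind, trace)
           else data.frame(iteration = integer(), T = numeric(), E = numeric(),
                           clashes = integer(), accepted = logical())
  structure(list(best = state$best, E_best = state$E_best,
                 last = state$current, E_last = state$E_old,
                 trace = trace, N = state$N, T0 = temp$T0,
                 n_unfixed = length(unfixed)),
            class = "anneal_result")
}

#' Write an annealing trace as tab-separated text
#'
#' Columns: iteration, T, E, clashes, accepted.
#'
#' @param result \code{anneal_result} (or the full-model report's trace).
#' @param path output file.
#' @export
write_trace <- function(result, path) {
  tr <- if (inherits(result, "anneal_result")) result$trace else result
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
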