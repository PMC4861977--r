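# Top-level orchestration: per-domain modeling (single-template shortcut or
# point-cloud sampling + annealing), and the six-step moving-rotation
# combination of adjacent domain models.

#' Model a region covered by a single template
#'
#' The template's Calpha coordinates are copied verbatim onto the covered
#' residues; uncovered residues are then built by the gap builder. The point
#' cloud method is not invoked.
#'
#' @param template trimmed \code{spc_template} with coordinates.
#' @param target \code{spc_target}.
#' @param range optional c(start, end) model range (default 1..L).
#' @param tries gap-builder shell budget.
#' @return complete \code{ca_model}.
#' @export
model_single_template <- function(template, target,
                                  range = c(1L, target$length),
                                  tries = 500L) {
  idx <- seq(range[1], range[2])
  xyz <- matrix(NA_real_, length(idx), 3)
  prov <- rep("none", length(idx))
  hit <- template$idx[template$idx >= range[1] & template$idx <= range[2]]
  rows <- match(hit, idx)
  xyz[rows, ] <- template$xyz[match(hit, template$idx), , drop = FALSE]
  prov[rows] <- "fixed"
  model <- ca_model(idx, xyz, prov, codes = target$residues[idx])
  fill_gaps(model, tries = tries)
}

rotation_axis_grid <- function(step = 0.1) {
  g <- seq(-1, 1, by = step)
  axes <- as.matrix(expand.grid(ux = g, uy = g, uz = g))
  nrm <- sqrt(rowSums(axes^2))
  keep <- nrm > 1e-9
  axes <- axes[keep, , drop = FALSE] / nrm[keep]
  axes
}

#' Combine two adjacent domain models by moving and rotating
#'
#' Implements the six-step junction search: (1) take the last residue A of
#' the left domain and the first residue B of the right domain; (2) if their
#' distance is outside [3.5, 4.5] Angstrom, translate the right domain along
#' the A-B direction to bring it to 4.0; (3) exit if the joined model has
#' fewer than 15 inter-domain clashes, no severe clash (< 2 Angstrom) and no
#' broken junction; otherwise (4) shell-sample a junction point C 3.5--4.5
#' Angstrom from A with no clash against the left domain, (5) translate the
#' right domain so B lands on C, and (6) grid-search rotations of the right
#' domain about C (axis components on a [-1, 1] grid of step 0.1, angles on a
#' 10-degree grid), keeping the orientation with fewest inter-domain clashes
#' and stopping early at zero.
#'
#' @param d1,d2 \code{ca_model}s whose index ranges are adjacent
#'   (d1 immediately precedes d2). d1 is never modified; d2 moves rigidly.
#' @param clash_limit exit threshold on inter-domain clashes (default 15).
#' @param severe_dist severe-clash cutoff (default 2.0 Angstrom).
#' @param junction_tries shell budget for the junction point.
#' @param theta_step rotation-angle grid step in degrees.
#' @return concatenated \code{ca_model}. Warns when no orientation reaches
#'   fewer than \code{clash_limit} clashes (the best found is returned).
#' @export
combine_domains <- function(d1, d2, clash_limit = 15L, severe_dist = 2.0,
                            junction_tries = 200L, theta_step = 10) {
  if (d2$index[1] != d1$index[length(d1$index)] + 1L)
    stop("domain ranges are not adjacent")
  a <- d1$xyz[nrow(d1$xyz), ]
  concat <- function(d2xyz) {
    ca_model(c(d1$index, d2$index), rbind(d1$xyz, d2xyz),
             c(d1$provenance, d2$provenance),
             codes = if (!is.null(d1$codes)) c(d1$codes, d2$codes) else NULL)
  }
  junction_ok <- function(d2xyz) {
    d_ab <- sqrt(sum((a - d2xyz[1, ])^2))
    d_ab >= 3.5 && d_ab <= 4.5
  }
  inter_clashes <- function(d2xyz) {
    cross_clashes(d1$xyz, d2xyz, exempt = cbind(nrow(d1$xyz), 1L))
  }
  # step 1-2: bring the junction distance into range by translation
  b <- d2$xyz[1, ]
  d_ab <- sqrt(sum((a - b)^2))
  if (d_ab < 3.5 || d_ab > 4.5) {
    dir <- if (d_ab < 1e-9) c(1, 0, 0) else (b - a) / d_ab
    shift <- (a + 4.0 * dir) - b
    d2$xyz <- sweep(d2$xyz, 2, shift, "+")
  }
  # step 3: early exit (severe = any non-junction pair under severe_dist)
  cl <- inter_clashes(d2$xyz)
  severe <- min(
    min_cross_distance(d1$xyz[-nrow(d1$xyz), , drop = FALSE], d2$xyz),
    if (nrow(d2$xyz) > 1L)
      min_cross_distance(d1$xyz, d2$xyz[-1L, , drop = FALSE]) else Inf
  ) < severe_dist
  if (cl < clash_limit && !severe && junction_ok(d2$xyz))
    return(concat(d2$xyz))
  # step 4: junction point C, clash-free against D1
  cand <- sample_shell_point(a, n = junction_tries)
  st <- gap_clash_stats(cand, d1$xyz[-nrow(d1$xyz), , drop = FALSE])
  pool <- which(st$clashes == 0L)
  cpt <- if (length(pool)) cand[pool[1], ]
         else cand[order(st$clashes, -st$min_dist)[1], ]
  # step 5: translate so B lands on C
  d2$xyz <- sweep(d2$xyz, 2, cpt - d2$xyz[1, ], "+")
  # step 6: rotate about C, fewest inter-domain clashes wins
  axes <- rotation_axis_grid(0.1)
  thetas <- seq(0, 2 * pi - 1e-9, by = theta_step * pi / 180)
  centered <- sweep(d2$xyz, 2, cpt)
  best_xyz <- d2$xyz
  best_cl <- inter_clashes(d2$xyz)
  if (best_cl > 0L) {
    found <- FALSE
    for (t in thetas) {
      if (found) break
      for (ai in seq_len(nrow(axes))) {
        R <- rotation_about_axis(axes[ai, ], t)$rotation
        rot <- sweep(centered %*% t(R), 2, cpt, "+")
        cl <- inter_clashes(rot)
        if (cl < best_cl) {
          best_cl <- cl
          best_xyz <- rot
          if (cl == 0L) { found <- TRUE; break }
        }
      }
    }
  }
  if (best_cl >= clash_limit)
    warning("domain combination left ", best_cl, " inter-domain clashes")
  concat(best_xyz)
}

model_domain <- function(segment, templates, weights, target, config,
                         energy = default_ca_energy, tries = 500L) {
  rng <- segment$range
  members <- Filter(function(t) t$id %in% segment$templates, templates)
  members <- lapply(members, function(t) {
    keep <- t$idx >= rng[1] & t$idx <= rng[2]
    t$idx <- t$idx[keep]; t$res <- t$res[keep]
    t$xyz <- t$xyz[keep, , drop = FALSE]
    t
  })
  members <- Filter(function(t) length(t$idx) > 0L, members)
  if (length(members) == 1L) {
    model <- model_single_template(members[[1]], target, range = rng,
                                   tries = tries)
    return(list(model = model, anneal = NULL, clouds = NULL,
                n_unfixed = 0L, E_initial = NA_real_, E_final = NA_real_,
                clashes_initial = count_clashes(model),
                clashes_final = count_clashes(model)))
  }
  clouds <- build_clouds(members, weights)
  idx <- seq(rng[1], rng[2])
  xyz <- matrix(NA_real_, length(idx), 3)
  prov <- rep("none", length(idx))
  for (cl in clouds) {
    r <- match(cl$i, idx)
    if (is.na(r)) next
    xyz[r, ] <- cl$p_avg
    prov[r] <- if (cl$unfixed) "unfixed" else "fixed"
  }
  model <- ca_model(idx, xyz, prov, codes = target$residues[idx])
  model <- fill_gaps(model, tries = tries)
  clashes0 <- count_clashes(model)
  ann <- run_annealing(model, clouds, energy = energy, config = config)
  list(model = ann$best, anneal = ann, clouds = clouds,
       n_unfixed = ann$n_unfixed,
       E_initial = energy_of(energy, model),
       E_final = ann$E_best,
       clashes_initial = clashes0,
       clashes_final = count_clashes(ann$best))
}

energy_of <- function(energy, model) {
  if (is.character(energy)) energy <- energy_backend(energy)
  energy(model)
}

#' Build a full-length model from an alignment and template structures
#'
#' Runs the whole pipeline: load and trim templates, compute five-term
#' weights, select templates, superpose them (per overlap-connected group),
#' filter structurally inconsistent regions, divide the target into domains,
#' model each domain (single-template copy, or weighted-average initial model
#' + gap building + simulated annealing), and combine adjacent domain models
#' left to right with the moving-rotation search.
#'
#' @param alignment \code{spc_alignment} from \code{\link{parse_alignment}},
#'   or a path to an alignment file.
#' @param config \code{anneal_config} (its \code{seed}, when non-NULL, seeds
#'   all randomness of the run).
#' @param energy energy backend name or function.
#' @param max_templates optional cap on the number of selected templates.
#' @return list of class \code{spc_result}: \code{model} (full-length
#'   \code{ca_model}), \code{report} (weights, selection, domains, energies,
#'   clash counts), \code{domains} (per-domain details incl. annealing
#'   traces).
#' @export
build_full_model <- function(alignment, config = anneal_config(),
                             energy = "default", max_templates = NULL) {
  if (is.character(alignment)) alignment <- parse_alignment(alignment)
  if (!is.null(config$seed)) set.seed(config$seed)
  target <- alignment$target
  templates <- lapply(alignment$templates, load_template_structure,
                      base_dir = alignment$dir)
  templates <- lapply(templates, trim_and_reindex, target = target)
  weights <- compute_weights(alignment, templates)
  selected <- select_templates(templates, weights)
  if (!is.null(max_templates) && length(selected) > max_templates)
    selected <- selected[seq_len(max_templates)]
  selected <- superpose_templates(selected)
  selected <- filter_inconsistent_regions(selected)
  segments <- divide_domains(selected, target$length)
  domain_fits <- lapply(segments, model_domain, templates = selected,
                        weights = weights, target = target, config = config,
                        energy = energy)
  model <- domain_fits[[1]]$model
  if (length(domain_fits) > 1L) {
    for (k in seq(2L, length(domain_fits)))
      model <- combine_domains(model, domain_fits[[k]]$model)
  }
  report <- list(
    target = target$id,
    length = target$length,
    weights = weights,
    selected = vapply(selected, `[[`, "", "id"),
    domains = lapply(segments, function(s)
      list(range = s$range, templates = s$templates)),
    n_unfixed = vapply(domain_fits, `[[`, 0L, "n_unfixed"),
    E_initial = vapply(domain_fits, `[[`, 1.0, "E_initial"),
    E_final = vapply(domain_fits, `[[`, 1.0, "E_final"),
    clashes_initial = vapply(domain_fits, `[[`, 0L, "clashes_initial"),
    clashes_final = vapply(domain_fits, `[[`, 0L, "clashes_final"),
    clashes_model = count_clashes(model))
  structure(list(model = model, report = report, domains = domain_fits,
                 alignment = alignment),
            class = "spc_result")
}
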