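# Synthetic-data generator: ground-truth Calpha chains, noisy/rotated/partial
# template copies, and the alignment files tying them together, so the full
# pipeline is testable with no downloads.

random_rotation <- function() {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  rotation_about_axis(u, stats::runif(1, 0, 2 * pi))
}

# Restore valid chain geometry after noising: real template structures keep
# consecutive Calpha distances near 3.8 A however far they diverge globally.
# Out-of-range bonds are clamped back into [lo + margin, hi - margin] by
# moving both endpoints symmetrically along the bond axis; a handful of sweeps
# converges. Only bonds between consecutive target indices are touched.
repair_chain_geometry <- function(xyz, idx = seq_len(nrow(xyz)),
                                  lo = 3.5, hi = 4.5, margin = 0.1,
                                  max_sweeps = 200L) {
  consec <- which(diff(idx) == 1L)
  for (s in seq_len(max_sweeps)) {
    ok <- TRUE
    for (k in consec) {
      v <- xyz[k + 1L, ] - xyz[k, ]
      d <- sqrt(sum(v^2))
      tgt <- if (d < lo) lo + margin else if (d > hi) hi - margin else next
      ok <- FALSE
      mid <- (xyz[k, ] + xyz[k + 1L, ]) / 2
      half <- v / d * (tgt / 2)
      xyz[k, ] <- mid - half
      xyz[k + 1L, ] <- mid + half
    }
    if (ok) break
  }
  xyz
}

#' Generate a self-avoiding Calpha chain
#'
#' Styles: \code{"helix"} uses ideal alpha-helix Calpha geometry (rise 1.5
#' Angstrom and 100 degrees per residue; the radius is solved so consecutive
#' Calpha atoms are exactly 3.8 Angstrom apart, giving ~2.28 Angstrom);
#' \code{"random-walk"} grows a chain with 3.8 Angstrom steps rejecting any
#' conformation bringing non-adjacent residues closer than 4.0 Angstrom;
#' \code{"zigzag"} is a planar extended chain with a 2.05 Angstrom axial step
#' (so residues i and i+4 are exactly 8.2 Angstrom apart).
#'
#' @param length number of residues (>= 3).
#' @param style one of "helix", "random-walk", "zigzag".
#' @param seed optional integer seed.
#' @return length x 3 coordinate matrix with consecutive distances
#'   3.8 +/- 0.01 Angstrom and no non-adjacent pair closer than 4.0 Angstrom.
#' @export
make_chain <- function(length, style = c("helix", "random-walk", "zigzag"),
                       seed = NULL) {
  stopifnot(length >= 3L)
  style <- match.arg(style)
  if (!is.null(seed)) set.seed(seed)
  if (style == "helix") {
    rise <- 1.5
    turn <- 100 * pi / 180
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
    i <- seq_len(length) - 1L
    xyz <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  } else if (style == "zigzag") {
    ax <- 2.05
    perp <- sqrt(3.8^2 - ax^2)
    i <- seq_len(length) - 1L
    xyz <- cbind(ax * i, perp * (i %% 2L), 0)
  } else {
    xyz <- matrix(NA_real_, length, 3)
    xyz[1, ] <- c(0, 0, 0)
    xyz[2, ] <- c(3.8, 0, 0)
    for (k in seq(3L, length)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        p <- sample_shell_point(xyz[k - 1L, ], r_min = 3.79, r_max = 3.81)
        d <- sqrt(rowSums(sweep(xyz[seq_len(k - 2L), , drop = FALSE], 2, p)^2))
        if (all(d >= 4.0)) {
          xyz[k, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("self-avoiding walk stalled at residue ", k)
    }
  }
  unname(xyz)
}

random_target_sequence <- function(length) {
  sample(blosum62_order, length, replace = TRUE)
}

#' Make a noisy partial template from a ground-truth chain
#'
#' Restricts the truth to a coverage interval, applies a random rigid
#' rotation and translation, and adds isotropic Gaussian noise whose 3-D RMS
#' displacement equals \code{noise_sd} (per-coordinate sd = noise_sd/sqrt(3)),
#' so the Kabsch RMSD back onto the truth is approximately \code{noise_sd}.
#' Optionally writes the template as a PDB file. The alignment mapping is the
#' identity on the interval.
#'
#' @param truth L x 3 ground-truth coordinates.
#' @param coverage c(first, last) covered target indices.
#' @param noise_sd RMS displacement in Angstrom.
#' @param id template identifier.
#' @param target_res one-letter target residue codes (length L); template
#'   residues copy them (identity alignment).
#' @param path optional PDB output path.
#' @param seed optional integer seed.
#' @return \code{spc_template} with coordinates (and \code{source_path} set
#'   when written).
#' @export
make_template <- function(truth, coverage, noise_sd = 0, id = "t1",
                          target_res = NULL, path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- as_coord_matrix(truth)
  idx <- seq(coverage[1], coverage[2])
  if (length(idx) == 0L || coverage[1] < 1L || coverage[2] > nrow(truth))
    stop("coverage interval outside the truth chain")
  xyz <- truth[idx, , drop = FALSE]
  if (noise_sd > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd / sqrt(3)),
                        ncol = 3)
    xyz <- repair_chain_geometry(xyz)
  }
  tr <- random_rotation()
  xyz <- sweep(apply_transform(tr, xyz), 2, stats::runif(3, -20, 20), "+")
  res <- if (is.null(target_res)) rep("A", length(idx)) else target_res[idx]
  tpl <- spc_template(id, idx, res, xyz,
                      source_path = if (is.null(path)) NA_character_
                                    else basename(path))
  if (!is.null(path)) {
    write_pdb_model(ca_model(idx, xyz, rep("fixed", length(idx)),
                             codes = res), path)
  }
  tpl
}

#' Make a template with an arbitrary (possibly gapped) index set
#' @noRd
make_template_idx <- function(truth, idx, noise_sd = 0, id = "t1",
                              target_res = NULL, path = NULL) {
  truth <- as_coord_matrix(truth)
  idx <- as.integer(idx)
  xyz <- truth[idx, , drop = FALSE]
  if (noise_sd > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd / sqrt(3)),
                        ncol = 3)
    xyz <- repair_chain_geometry(xyz, idx = idx)
  }
  tr <- random_rotation()
  xyz <- sweep(apply_transform(tr, xyz), 2, stats::runif(3, -20, 20), "+")
  res <- if (is.null(target_res)) rep("A", length(idx)) else target_res[idx]
  tpl <- spc_template(id, idx, res, xyz,
                      source_path = if (is.null(path)) NA_character_
                                    else basename(path))
  if (!is.null(path))
    write_pdb_model(ca_model_sparse(idx, xyz, res), path)
  tpl
}

# a PDB for a non-contiguous index set: write residues at their target numbers
ca_model_sparse <- function(idx, xyz, res) {
  n <- length(idx)
  m <- structure(list(index = idx, xyz = as_coord_matrix(xyz),
                      provenance = rep("fixed", n), codes = res),
                 class = "ca_model")
  m
}

write_alignment_file <- function(target_id, target_res, templates, path) {
  L <- length(target_res)
  lines <- c(paste(">target", target_id), paste(target_res, collapse = ""))
  for (t in templates) {
    row <- rep("-", L)
    row[t$idx] <- t$res
    hdr <- paste0(">tpl ", t$id, " file=", t$source_path)
    if (!is.na(t$evalue)) hdr <- paste0(hdr, " evalue=", t$evalue)
    lines <- c(lines, hdr, paste(row, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a self-contained test scenario
#'
#' Writes a directory with a ground-truth PDB (\code{truth.pdb}), template
#' PDBs and an alignment file (\code{alignment.fasta}) consumable by
#' \code{\link{build_full_model}}. Scenarios:
#' \describe{
#'   \item{single-full}{one noise-free template covering the whole target.}
#'   \item{multi-overlap}{three noisy overlapping templates, one domain.}
#'   \item{two-domain-no-overlap}{two templates with disjoint coverage
#'     separated by an uncovered linker; domain division yields 2 domains.}
#'   \item{gapped-terminal}{one template leaving N- and C-terminal gaps.}
#'   \item{gapped-internal}{one template with a 3-residue internal gap whose
#'     anchors sit exactly 8.2 Angstrom apart (zigzag truth geometry).}
#'   \item{inconsistent-template}{three templates; one has a structurally
#'     scrambled region overlapping the others.}
#' }
#'
#' @param name scenario id.
#' @param dir output directory (created).
#' @param seed integer seed; all randomness of the scenario flows from it.
#' @return list with \code{alignment} (file path), \code{truth} (file path),
#'   \code{truth_xyz}, \code{target_res} and \code{dir}.
#' @export
make_case <- function(name = c("single-full", "multi-overlap",
                               "two-domain-no-overlap", "gapped-terminal",
                               "gapped-internal", "inconsistent-template"),
                      dir = tempfile("case_"), seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb <- function(f) file.path(dir, f)

  if (name == "single-full") {
    L <- 40L
    truth <- make_chain(L, "helix")
    res <- random_target_sequence(L)
    tpls <- list(make_template(truth, c(1L, L), 0, "t1", res, pdb("t1.pdb")))
  } else if (name == "multi-overlap") {
    L <- 60L
    truth <- make_chain(L, "random-walk")
    res <- random_target_sequence(L)
    tpls <- list(
      make_template(truth, c(1L, 45L), 1.0, "t1", res, pdb("t1.pdb")),
      make_template(truth, c(10L, 60L), 1.0, "t2", res, pdb("t2.pdb")),
      make_template(truth, c(5L, 55L), 1.0, "t3", res, pdb("t3.pdb")))
  } else if (name == "two-domain-no-overlap") {
    # scaled-down two-template pattern: disjoint coverages, uncovered linker
    L <- 112L
    truth <- make_chain(L, "helix")
    res <- random_target_sequence(L)
    tpls <- list(
      make_template(truth, c(9L, 28L), 0.3, "d1", res, pdb("d1.pdb")),
      make_template(truth, c(31L, 112L), 0.3, "d2", res, pdb("d2.pdb")))
  } else if (name == "gapped-terminal") {
    L <- 70L
    truth <- make_chain(L, "helix")
    res <- random_target_sequence(L)
    tpls <- list(make_template(truth, c(11L, 60L), 0, "t1", res, pdb("t1.pdb")))
  } else if (name == "gapped-internal") {
    L <- 60L
    truth <- make_chain(L, "zigzag")  # anchors of a 3-residue gap: 8.2 A apart
    res <- random_target_sequence(L)
    tpls <- list(make_template_idx(truth, c(1:30, 34:60), 0, "t1", res,
                                   pdb("t1.pdb")))
  } else {  # inconsistent-template
    # t2 overlaps the others over 30-50 with a scrambled left part, and is
    # still selected because it alone covers 51-80; filtering should delete
    # the scrambled overlap but keep the sole coverage
    L <- 80L
    truth <- make_chain(L, "random-walk")
    res <- random_target_sequence(L)
    t1 <- make_template(truth, c(1L, 50L), 0.3, "t1", res, pdb("t1.pdb"))
    t2 <- make_template(truth, c(30L, 80L), 0.3, "t2", res)
    bad <- 1:10  # target residues 30-39 scrambled; 40-50 stay consistent
    t2$xyz[bad, ] <- t2$xyz[bad, ][sample(length(bad)), , drop = FALSE] +
      matrix(stats::rnorm(length(bad) * 3, sd = 4), ncol = 3)
    t2$source_path <- "t2.pdb"
    write_pdb_model(ca_model(t2$idx, t2$xyz, rep("fixed", length(t2$idx)),
                             codes = t2$res), pdb("t2.pdb"))
    t3 <- make_template(truth, c(1L, 45L), 0.3, "t3", res, pdb("t3.pdb"))
    tpls <- list(t1, t2, t3)
  }

  truth_model <- ca_model(seq_len(nrow(truth)), truth,
                          rep("fixed", nrow(truth)), codes = res)
  write_pdb_model(truth_model, pdb("truth.pdb"))
  aln <- write_alignment_file("target1", res, tpls, pdb("alignment.fasta"))
  list(alignment = aln, truth = pdb("truth.pdb"), truth_xyz = truth,
       target_res = res, dir = dir)
}
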