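# Template weighting, selection, consistency filtering, superposition and
# domain detection. All operations act on trimmed, target-indexed templates.

# Standard BLOSUM62 substitution matrix (half-bit scores), 20 standard
# residues. Embedded as static data; cross-checked against Biostrings in the
# test suite.
blosum62_order <- c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V")
BLOSUM62 <- matrix(c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4),
  nrow = 20, byrow = TRUE,
  dimnames = list(blosum62_order, blosum62_order))

blosum62_score <- function(a, b) {
  ok <- a %in% blosum62_order & b %in% blosum62_order
  s <- rep(NA_real_, length(a))
  s[ok] <- BLOSUM62[cbind(a[ok], b[ok])]
  s
}

#' Sequence similarity term of a template weight
#'
#' Each covered target/template residue pair is scored with BLOSUM62; a
#' negative score s is transformed to exp(s), a non-negative score to s + 1,
#' and the transformed score is divided by 12 to scale it to [0, 1]. The term
#' is the mean over the n covered positions. Pairs involving a non-standard
#' residue ("X") contribute 0.
#'
#' @param template trimmed \code{spc_template}.
#' @param target \code{spc_target}.
#' @return similarity in [0, 1].
#' @export
sequence_similarity <- function(template, target) {
  if (length(template$idx) == 0L) stop("template has empty coverage")
  s <- blosum62_score(target$residues[template$idx], template$res)
  tr <- ifelse(is.na(s), 0, ifelse(s < 0, exp(s), s + 1) / 12)
  mean(tr)
}

sequence_identity <- function(template, target) {
  tgt <- target$residues[template$idx]
  mean(tgt == template$res & tgt != "X")
}

common_idx <- function(a, b) intersect(a$idx, b$idx)

tm_between <- function(a, b, min_shared = 3L) {
  shared <- common_idx(a, b)
  if (length(shared) < min_shared) return(NA_real_)
  tm_score(a$xyz[match(shared, a$idx), , drop = FALSE],
           b$xyz[match(shared, b$idx), , drop = FALSE],
           l_target = length(shared))
}

#' Compute the five-term template weights
#'
#' Each template's weight is the sum of (1) its average pairwise TM-score
#' against the other templates over their shared residues, (2) coverage
#' (covered / L), (3) sequence identity over covered residues, (4) the
#' BLOSUM62 similarity term (\code{\link{sequence_similarity}}) and
#' (5) exp(-e-value), with e-value taken as 0 when absent. A template without
#' peers (single template, or no pair shares >= 3 residues) takes avg_tm = 1.
#'
#' @param alignment \code{spc_alignment} (target is used for L and sequence).
#' @param templates list of trimmed \code{spc_template}s with coordinates.
#' @return data.frame with columns id, avg_tm, coverage, identity, similarity,
#'   e_term, total.
#' @export
compute_weights <- function(alignment, templates = alignment$templates) {
  target <- alignment$target
  m <- length(templates)
  avg_tm <- vapply(seq_len(m), function(j) {
    peers <- setdiff(seq_len(m), j)
    tms <- vapply(peers, function(k) tm_between(templates[[j]], templates[[k]]),
                  1.0)
    tms <- tms[!is.na(tms)]
    if (length(tms) == 0L) 1.0 else mean(tms)
  }, 1.0)
  coverage <- vapply(templates, template_coverage, 1.0, target = target)
  identity <- vapply(templates, sequence_identity, 1.0, target = target)
  similarity <- vapply(templates, sequence_similarity, 1.0, target = target)
  ev <- vapply(templates, function(t) {
    if (is.na(t$evalue)) 0 else t$evalue
  }, 1.0)
  e_term <- exp(-ev)
  data.frame(id = vapply(templates, `[[`, "", "id"),
             avg_tm = avg_tm, coverage = coverage, identity = identity,
             similarity = similarity, e_term = e_term,
             total = avg_tm + coverage + identity + similarity + e_term,
             stringsAsFactors = FALSE)
}

max_contiguous_run <- function(idx) {
  if (length(idx) == 0L) return(0L)
  idx <- sort(unique(idx))
  runs <- rle(c(1L, diff(idx)) == 1L)
  # split into maximal consecutive stretches
  grp <- cumsum(c(TRUE, diff(idx) != 1L))
  max(tabulate(grp))
}

#' Select templates by weight, novel coverage and structural agreement
#'
#' The highest-weight template is always selected. Remaining candidates are
#' examined in descending weight order; a candidate is kept if it covers at
#' least 10 contiguous target residues not covered by any already-selected
#' template, or if its pairwise TM-score with the top-weight template exceeds
#' 0.7. All candidates are examined.
#'
#' @param templates list of trimmed \code{spc_template}s with coordinates.
#' @param weights data.frame from \code{\link{compute_weights}}.
#' @param min_new_run contiguous new-coverage threshold (default 10).
#' @param tm_cut TM-score threshold against the top template (default 0.7).
#' @return list of selected templates in descending weight order.
#' @export
select_templates <- function(templates, weights, min_new_run = 10L,
                             tm_cut = 0.7) {
  ids <- vapply(templates, `[[`, "", "id")
  ord <- order(-weights$total[match(ids, weights$id)])
  templates <- templates[ord]
  selected <- templates[1]
  covered <- templates[[1]]$idx
  top <- templates[[1]]
  for (cand in templates[-1]) {
    new_run <- max_contiguous_run(setdiff(cand$idx, covered))
    keep <- new_run >= min_new_run
    if (!keep) {
      tm <- tm_between(top, cand)
      keep <- !is.na(tm) && tm > tm_cut
    }
    if (keep) {
      selected <- c(selected, list(cand))
      covered <- union(covered, cand$idx)
    }
  }
  selected
}

overlap_components <- function(templates, min_shared = 1L) {
  m <- length(templates)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (comp[a] != comp[b] &&
          length(common_idx(templates[[a]], templates[[b]])) >= min_shared) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Superpose selected templates onto a center template
#'
#' Within each overlap-connected group of templates, the highest-weight
#' member is the center and stays fixed. Every other template is rigidly
#' transformed by a Kabsch fit over the target residues it shares with its
#' anchor: the center when they share residues, otherwise the
#' already-superposed template sharing the most residues with it. Templates
#' sharing fewer than 3 residues with every superposable anchor are excluded
#' with a warning.
#'
#' @param templates selected templates in descending weight order.
#' @return list of templates with coordinates replaced by their superposed
#'   values.
#' @export
superpose_templates <- function(templates) {
  m <- length(templates)
  if (m == 1L) return(templates)
  comp <- overlap_components(templates, min_shared = 1L)
  done <- logical(m)
  out <- templates
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    center <- members[1]  # templates come ordered by weight
    done[center] <- TRUE
    pending <- setdiff(members, center)
    while (length(pending)) {
      placed <- FALSE
      for (j in pending) {
        anchors <- members[done[members]]
        nshared <- vapply(anchors, function(a)
          length(common_idx(out[[j]], out[[a]])), 0L)
        # prefer the center when it shares residues, else the richest overlap
        cand <- if (length(common_idx(out[[j]], out[[center]])) >= 3L) center
                else if (max(nshared) >= 3L) anchors[which.max(nshared)]
                else next
        shared <- common_idx(out[[j]], out[[cand]])
        # TM-style trimmed fit: robust to localized disagreement in the
        # shared region (the plain Kabsch frame would be dragged by it)
        sup <- tm_superpose(
          out[[j]]$xyz[match(shared, out[[j]]$idx), , drop = FALSE],
          out[[cand]]$xyz[match(shared, out[[cand]]$idx), , drop = FALSE],
          l_target = length(shared))
        out[[j]]$xyz <- apply_transform(sup$transform, out[[j]]$xyz)
        done[j] <- TRUE
        placed <- TRUE
      }
      pending <- setdiff(members, which(done))
      if (!placed && length(pending)) {
        warning("template(s) ", paste(vapply(out[pending], `[[`, "", "id"),
                                      collapse = ", "),
                " share too few residues with any anchor; excluded")
        break
      }
    }
  }
  out[done]
}

contiguous_groups <- function(idx) {
  if (length(idx) == 0L) return(list())
  idx <- sort(idx)
  split(idx, cumsum(c(TRUE, diff(idx) != 1L)))
}

#' Remove structurally inconsistent template regions
#'
#' For each non-top template, the maximal contiguous runs of its residues
#' shared with at least one other selected template are checked: a run is
#' consistent when its TM-score (over shared residues, normalized by the
#' shared length) against at least one other selected template reaches the
#' cutoff. An inconsistent run longer than 5 residues is bisected and its
#' halves re-tested, so a localized structural disagreement is deleted without
#' discarding the agreeing remainder; short inconsistent leaves are removed.
#' Residues that are a region's sole coverage are never tested, hence
#' retained. Templates emptied by filtering are dropped.
#'
#' @param templates superposed templates, top-weight first.
#' @param tm_cut consistency threshold (default 0.7).
#' @return filtered template list.
#' @export
filter_inconsistent_regions <- function(templates, tm_cut = 0.7) {
  m <- length(templates)
  if (m <= 1L) return(templates)
  out <- templates
  for (j in seq(2L, m)) {
    others <- out[-j]
    other_cov <- sort(unique(unlist(lapply(others, `[[`, "idx"))))
    shared_here <- intersect(out[[j]]$idx, other_cov)
    drop_idx <- integer()
    for (run in contiguous_groups(shared_here))
      drop_idx <- c(drop_idx,
                    inconsistent_residues(as.integer(run), out[[j]], others,
                                          tm_cut))
    if (length(drop_idx)) {
      keep <- !(out[[j]]$idx %in% drop_idx)
      out[[j]]$idx <- out[[j]]$idx[keep]
      out[[j]]$res <- out[[j]]$res[keep]
      out[[j]]$xyz <- out[[j]]$xyz[keep, , drop = FALSE]
    }
  }
  Filter(function(t) length(t$idx) > 0L, out)
}

# recursive consistency check of one contiguous run of template residues
inconsistent_residues <- function(run, tpl, others, tm_cut) {
  tms <- vapply(others, function(o) {
    shared <- intersect(run, o$idx)
    if (length(shared) < 3L) return(NA_real_)
    tm_score(tpl$xyz[match(shared, tpl$idx), , drop = FALSE],
             o$xyz[match(shared, o$idx), , drop = FALSE],
             l_target = length(shared))
  }, 1.0)
  tms <- tms[!is.na(tms)]
  if (length(tms) == 0L || any(tms >= tm_cut)) return(integer())
  if (length(run) < 6L) return(run)
  half <- length(run) %/% 2L
  c(inconsistent_residues(run[seq_len(half)], tpl, others, tm_cut),
    inconsistent_residues(run[seq(half + 1L, length(run))], tpl, others,
                          tm_cut))
}

#' Divide the target into domains from template coverage
#'
#' Templates sharing at least one target residue are joined into one group;
#' each group's covered span seeds a domain. Uncovered linker residues between
#' two domains are split at the midpoint of the uncovered run (the extra
#' residue of an odd run goes to the left domain); uncovered terminal runs
#' attach to the adjacent domain. The returned segments partition 1..L.
#'
#' @param templates selected (filtered) templates.
#' @param L target length.
#' @return list of segments, each a list with \code{range} (c(start, end)) and
#'   \code{templates} (ids of the group's templates).
#' @export
divide_domains <- function(templates, L) {
  comp <- overlap_components(templates, min_shared = 1L)
  spans <- lapply(unique(comp), function(cid) {
    members <- templates[comp == cid]
    idx <- unlist(lapply(members, `[[`, "idx"))
    list(range = c(min(idx), max(idx)),
         templates = vapply(members, `[[`, "", "id"))
  })
  spans <- spans[order(vapply(spans, function(s) s$range[1], 1))]
  # merge groups with overlapping spans: interleaved coverage without shared
  # residues cannot be modeled as separate rigid domains
  merged <- list(spans[[1]])
  for (s in spans[-1]) {
    last <- merged[[length(merged)]]
    if (s$range[1] <= last$range[2]) {
      last$range <- c(last$range[1], max(last$range[2], s$range[2]))
      last$templates <- c(last$templates, s$templates)
      merged[[length(merged)]] <- last
    } else merged <- c(merged, list(s))
  }
  k <- length(merged)
  starts <- vapply(merged, function(s) s$range[1], 1)
  ends <- vapply(merged, function(s) s$range[2], 1)
  bounds_start <- numeric(k); bounds_end <- numeric(k)
  bounds_start[1] <- 1
  bounds_end[k] <- L
  if (k > 1L) for (i in seq_len(k - 1L)) {
    g <- ends[i] + 1L
    h <- starts[i + 1L] - 1L
    glen <- h - g + 1L
    left_extra <- ceiling(glen / 2)  # ties to the left domain
    bounds_end[i] <- ends[i] + left_extra
    bounds_start[i + 1L] <- bounds_end[i] + 1L
  }
  lapply(seq_len(k), function(i)
    list(range = c(as.integer(bounds_start[i]), as.integer(bounds_end[i])),
         templates = merged[[i]]$templates))
}
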