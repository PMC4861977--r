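make_tpl <- function(id, idx, xyz, res = rep("A", length(idx)), evalue = NA) {
  spc_template(id, idx, res, xyz, evalue = evalue)
}

test_that("sequence similarity applies the BLOSUM62 transform and /12 scaling", {
  tgt <- spc_target("t", rep("W", 10))
  tpl <- make_tpl("x", 1:10, helix40()[1:10, ], res = rep("W", 10))
  # Trp-Trp scores 11 -> (11+1)/12 = 1
  expect_equal(sequence_similarity(tpl, tgt), 1.0)
  # a score-0 pair (Ala-Gly) sits on the non-negative branch: (0+1)/12
  tgt2 <- spc_target("t", rep("A", 10))
  tpl2 <- make_tpl("x", 1:10, helix40()[1:10, ], res = rep("G", 10))
  expect_equal(sequence_similarity(tpl2, tgt2), 1 / 12)
  # a negative pair (Trp vs Gly, -2... use Asp-Trp = -4) contributes e^s/12
  tgt3 <- spc_target("t", rep("D", 10))
  tpl3 <- make_tpl("x", 1:10, helix40()[1:10, ], res = rep("W", 10))
  expect_equal(sequence_similarity(tpl3, tgt3), exp(-4) / 12,
               tolerance = 1e-12)
})

test_that("embedded BLOSUM62 matches the Biostrings reference matrix", {
  skip_if_not_installed("Biostrings")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ref <- BLOSUM62  # Biostrings copy, 24x24 with ambiguity codes
  mine <- spcmodel:::BLOSUM62
  expect_equal(mine, ref[rownames(mine), colnames(mine)],
               ignore_attr = TRUE)
})

test_that("five-term weights reach 5 only for a perfect template and use exp(-evalue)", {
  L <- 20L
  tgt <- spc_target("t", rep("W", L))
  xyz <- helix40()[1:L, ]
  tpl <- make_tpl("x", 1:L, xyz, res = rep("W", L), evalue = 0)
  aln <- structure(list(target = tgt, templates = list(tpl)),
                   class = "spc_alignment")
  w <- compute_weights(aln)
  expect_equal(w$total, 5.0)
  expect_equal(w$avg_tm, 1.0)   # single template: no peers

  tpl2 <- make_tpl("y", 1:L, xyz, res = rep("W", L), evalue = 2)
  aln$templates <- list(tpl, tpl2)
  w <- compute_weights(aln)
  expect_equal(w$e_term, c(1, exp(-2)))
  expect_equal(exp(-2), 0.1353, tolerance = 1e-3)
  # rigid copies of each other: avg TM-score 1 for both
  tr <- rotation_about_axis(c(0, 1, 0), 0.8)
  tpl3 <- make_tpl("z", 1:L, apply_transform(tr, xyz), res = rep("W", L))
  aln$templates <- list(tpl, tpl3)
  w <- compute_weights(aln)
  expect_equal(w$avg_tm, c(1, 1), tolerance = 1e-6)
  # absent e-value counts as 0
  expect_equal(w$e_term[2], 1.0)
})

test_that("template selection keeps novel-coverage or structurally consistent candidates", {
  L <- 80L
  truth <- make_chain(L, "helix")
  t1 <- make_tpl("T1", 1:50, truth[1:50, ])
  t2 <- make_tpl("T2", 1:50,
                 apply_transform(rotation_about_axis(c(1, 0, 0), 1.2),
                                 truth[1:50, ]))        # rigid copy: TM = 1
  t3 <- make_tpl("T3", 55:70, truth[55:70, ])           # 16 new residues
  set.seed(9)
  bad <- truth[c(45:50, 71:79), ]
  bad[1:6, ] <- bad[sample(6), ] + matrix(rnorm(18, sd = 8), 6, 3)
  t4 <- make_tpl("T4", c(45:50, 71:79), bad)            # 9 new, low TM
  w <- data.frame(id = c("T1", "T2", "T3", "T4"),
                  total = c(4, 3, 2.5, 2))
  sel <- select_templates(list(t1, t2, t3, t4), w)
  ids <- vapply(sel, `[[`, "", "id")
  expect_equal(ids, c("T1", "T2", "T3"))
  # single template is always selected
  expect_equal(vapply(select_templates(list(t1), w[1, ]), `[[`, "", "id"),
               "T1")
})

test_that("superposition anchors to the center, chaining through overlaps", {
  truth <- make_chain(100, "helix")
  mk <- function(id, rng) {
    tr <- rotation_about_axis(c(0.6, 0.8, 0), runif(1, 0.5, 2))
    xyz <- sweep(apply_transform(tr, truth[rng, ]), 2, runif(3, -30, 30), "+")
    make_tpl(id, rng, xyz)
  }
  set.seed(12)
  tpls <- list(mk("T1", 1:40), mk("T2", 10:50), mk("T3", 20:60),
               mk("T4", 35:80), mk("T5", 65:100))
  sup <- superpose_templates(tpls)
  expect_equal(length(sup), 5L)
  expect_equal(sup[[1]]$xyz, tpls[[1]]$xyz)  # center unchanged
  # every template recovered the common frame: pairwise shared-residue rmsd ~ 0
  for (a in 1:4) for (b in (a + 1):5) {
    shared <- intersect(sup[[a]]$idx, sup[[b]]$idx)
    if (length(shared) < 3) next
    expect_lt(coord_rmsd(sup[[a]]$xyz[match(shared, sup[[a]]$idx), ],
                         sup[[b]]$xyz[match(shared, sup[[b]]$idx), ]), 1e-6)
  }
  # identical-coordinate templates map onto each other exactly
  two <- superpose_templates(list(make_tpl("a", 1:40, truth[1:40, ]),
                                  make_tpl("b", 1:40, truth[1:40, ])))
  expect_lt(coord_rmsd(two[[1]]$xyz, two[[2]]$xyz), 1e-9)
  # 90-degree rotated copy of the center is recovered
  rot <- apply_transform(rotation_about_axis(c(0, 0, 1), pi / 2),
                         truth[1:40, ])
  two <- superpose_templates(list(make_tpl("a", 1:40, truth[1:40, ]),
                                  make_tpl("b", 1:40, rot)))
  expect_lt(coord_rmsd(two[[1]]$xyz, two[[2]]$xyz), 1e-6)
})

test_that("superposition never worsens shared-residue RMSD to the anchor", {
  set.seed(21)
  truth <- make_chain(60, "random-walk")
  tpls <- lapply(1:3, function(k)
    make_tpl(paste0("t", k), 1:60,
             sweep(apply_transform(rotation_about_axis(c(0, 0, 1), k), truth),
                   2, rnorm(3, sd = 10), "+") +
               matrix(rnorm(180, sd = 0.5), 60, 3)))
  sup <- superpose_templates(tpls)
  for (k in 2:3) {
    before <- coord_rmsd(tpls[[k]]$xyz, tpls[[1]]$xyz)
    after <- coord_rmsd(sup[[k]]$xyz, sup[[1]]$xyz)
    expect_lte(after, before + 1e-9)
  }
})

test_that("structurally inconsistent overlap fragments are removed, sole coverage kept", {
  set.seed(33)
  truth <- make_chain(60, "random-walk")
  t1 <- make_tpl("t1", 1:60, truth)
  # t2: right half agrees, left overlap region scrambled
  xyz2 <- truth[1:40, ]
  xyz2[1:20, ] <- xyz2[sample(20), ] + matrix(rnorm(60, sd = 6), 20, 3)
  t2 <- make_tpl("t2", 1:40, xyz2)
  # t3 is a rigid copy over its overlap: retained
  t3 <- make_tpl("t3", 10:50, truth[10:50, ])
  filt <- filter_inconsistent_regions(list(t1, t2, t3))
  ids <- vapply(filt, `[[`, "", "id")
  t2f <- filt[[which(ids == "t2")]]
  expect_false(any(1:20 %in% t2f$idx))      # scrambled fragment deleted
  expect_true(all(21:40 %in% t2f$idx))      # agreeing remainder kept
  t3f <- filt[[which(ids == "t3")]]
  expect_equal(t3f$idx, 10:50)              # consistent fragment retained
  # sole-coverage low-TM fragment is never tested, hence retained
  t1b <- make_tpl("t1b", 1:50, truth[1:50, ])
  t4 <- make_tpl("t4", c(30:40, 55:60),
                 rbind(truth[30:40, ], truth[55:60, ] +
                         matrix(rnorm(18, sd = 9), 6, 3)))
  filt <- filter_inconsistent_regions(list(t1b, t4))
  t4f <- filt[[2]]
  expect_true(all(55:60 %in% t4f$idx))
})

test_that("domain division follows overlap connectivity and the midpoint rule", {
  xyz <- function(n) helix40()[seq_len(min(n, 40)), , drop = FALSE]
  # disjoint coverages 34-112 and 122-448 on a 448-residue target: 2 domains
  d1 <- spc_template("a", 34:112, rep("A", 79))
  d2 <- spc_template("b", 122:448, rep("A", 327))
  doms <- divide_domains(list(d1, d2), 448L)
  expect_length(doms, 2L)
  expect_equal(doms[[1]]$range[1], 1L)
  expect_equal(doms[[2]]$range[2], 448L)
  expect_equal(doms[[1]]$range[2] + 1L, doms[[2]]$range[1])
  # overlapping templates form one domain
  doms <- divide_domains(list(spc_template("a", 1:60, rep("A", 60)),
                              spc_template("b", 50:100, rep("A", 51))), 100L)
  expect_length(doms, 1L)
  expect_equal(doms[[1]]$range, c(1L, 100L))
  # midpoint rule, ties to the left: A 1-40, B 30-70, C 90-120, L = 130
  doms <- divide_domains(list(spc_template("a", 1:40, rep("A", 40)),
                              spc_template("b", 30:70, rep("A", 41)),
                              spc_template("c", 90:120, rep("A", 31))), 130L)
  expect_length(doms, 2L)
  expect_equal(doms[[1]]$range, c(1L, 80L))
  expect_equal(doms[[2]]$range, c(81L, 130L))
})

test_that("domain segments always partition 1..L", {
  set.seed(14)
  for (rep in 1:20) {
    L <- sample(50:300, 1)
    ntpl <- sample(1:5, 1)
    tpls <- lapply(seq_len(ntpl), function(k) {
      a <- sample(seq_len(L - 10L), 1)
      b <- min(L, a + sample(9:80, 1))
      spc_template(paste0("t", k), a:b, rep("A", b - a + 1L))
    })
    doms <- divide_domains(tpls, L)
    covered <- unlist(lapply(doms, function(d) seq(d$range[1], d$range[2])))
    expect_equal(sort(covered), seq_len(L))      # disjoint and complete
    starts <- vapply(doms, function(d) d$range[1], 1)
    expect_true(!is.unsorted(starts))
  }
})
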