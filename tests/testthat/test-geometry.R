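test_that("Kabsch superposition recovers rigid motions and matches the quaternion oracle", {
  pts <- helix40()[1:10, ]
  # identical sets
  s <- kabsch_superpose(pts, pts)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  # pure translation
  s <- kabsch_superpose(pts, sweep(pts, 2, c(5, 0, 0), "+"))
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$transform$translation, c(5, 0, 0), tolerance = 1e-8)
  # rotated + noised copy vs independent quaternion eigen-solution
  set.seed(101)
  for (rep in 1:5) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- rotation_about_axis(u, runif(1, 0, 2 * pi))$rotation
    B <- A %*% t(R) + matrix(rnorm(30, sd = 0.3), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd,
                 quaternion_superpose(A, B)$rmsd, tolerance = 1e-6)
  }
  # optimal rmsd never exceeds the untransformed rmsd
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  expect_lte(kabsch_superpose(A, B)$rmsd, coord_rmsd(A, B) + 1e-12)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3")
  expect_error(kabsch_superpose(A[1:5, ], B), "length")
})

test_that("Kabsch flags a degenerate (collinear) point set but still solves", {
  A <- cbind(seq_len(5) * 1.0, 0, 0)
  B <- cbind(0, seq_len(5) * 1.0, 0)
  s <- kabsch_superpose(A, B)
  expect_true(s$degenerate)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
})

test_that("axis-angle rotation follows the Rodrigues formula", {
  q <- apply_transform(rotation_about_axis(c(0, 0, 1), pi / 2),
                       matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(q), c(0, 1, 0), tolerance = 1e-12)
  u <- c(1, 1, 1) / sqrt(3)
  expect_equal(rotation_about_axis(u, 0)$rotation, diag(3), tolerance = 1e-12)
  # compare against quaternion arithmetic on several random axes and vectors
  set.seed(7)
  for (rep in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    th <- runif(1, -2 * pi, 2 * pi)
    v <- rnorm(3)
    expect_equal(as.numeric(apply_transform(rotation_about_axis(u, th),
                                            matrix(v, 1))),
                 quat_rotate(v, u, th), tolerance = 1e-9)
    # inverse rotation composes to the identity
    RR <- rotation_about_axis(u, th)$rotation %*%
      rotation_about_axis(u, -th)$rotation
    expect_equal(RR, diag(3), tolerance = 1e-12)
  }
  expect_error(rotation_about_axis(c(1, 1, 0), 1), "unit")
})

test_that("TM-score has the stated closed form and limits", {
  xyz <- helix40()
  expect_equal(tm_score(xyz, xyz), 1.0, tolerance = 1e-12)
  # every pairwise deviation enormous -> score near 0
  set.seed(2)
  far <- xyz + matrix(rnorm(length(xyz), sd = 500), ncol = 3)
  expect_lt(tm_score(far, xyz), 0.05)
  # all residues exactly at d0: each term is 1/2
  d0 <- tm_d0(100)
  expect_equal(spcmodel:::tm_from_dist(rep(d0, 100), d0, 100), 0.5)
  expect_equal(tm_d0(100), 1.24 * (100 - 15)^(1 / 3) - 1.8)
  expect_equal(tm_d0(10), 0.5)  # clamp for short targets
  expect_error(tm_score(xyz[0, , drop = FALSE], xyz[0, , drop = FALSE]),
               "common")
})

test_that("structure metrics are invariant under joint rigid motion", {
  xyz <- helix40()
  set.seed(3)
  model <- xyz + matrix(rnorm(length(xyz), sd = 1.5), ncol = 3)
  tr <- rotation_about_axis(c(0, 1, 0), 1.1)
  mv <- function(m) sweep(apply_transform(tr, m), 2, c(3, -8, 12), "+")
  expect_equal(tm_score(mv(model), mv(xyz)), tm_score(model, xyz),
               tolerance = 1e-9)
  expect_equal(gdt_ts(mv(model), mv(xyz)), gdt_ts(model, xyz),
               tolerance = 1e-9)
})

test_that("GDT-TS scores identical, rigidly shifted and half-broken models correctly", {
  xyz <- helix40()
  expect_equal(gdt_ts(xyz, xyz), 1.0, tolerance = 1e-12)
  expect_equal(gdt_ts(sweep(xyz, 2, c(10, 0, 0), "+"), xyz), 1.0,
               tolerance = 1e-12)
  # half exact, half non-rigidly displaced by ~100 A: oracle is a direct
  # cutoff count after superposing on the exact half
  set.seed(4)
  model <- xyz
  broken <- 21:40
  model[broken, ] <- model[broken, ] +
    matrix(rnorm(length(broken) * 3, sd = 100), ncol = 3)
  g <- gdt_ts(model, xyz)
  sup <- kabsch_superpose(model[1:20, ], xyz[1:20, ])
  d <- sqrt(rowSums((apply_transform(sup$transform, model) - xyz)^2))
  oracle <- mean(vapply(c(1, 2, 4, 8), function(ct) mean(d <= ct), 1.0))
  expect_gte(g, oracle - 1e-9)   # gdt_ts maximizes over more superpositions
  expect_equal(g, 0.5, tolerance = 0.05)
})
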