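test_that("temperature schedule clamps 1000/n_unfixed into [20, 100]", {
  expect_equal(initial_temperature(50), list(T0 = 20, N = 20))
  expect_equal(initial_temperature(5), list(T0 = 100, N = 100))   # 200 -> 100
  expect_equal(initial_temperature(200), list(T0 = 20, N = 20))   # 5 -> 20
  expect_equal(initial_temperature(0), list(T0 = 0, N = 0))
  # multiplier overrides the default schedule
  expect_equal(initial_temperature(30, 5), list(T0 = 150, N = 150))
  expect_error(initial_temperature(30, 0), "\\[1, 500\\]")
  expect_error(initial_temperature(30, 501), "\\[1, 500\\]")
  expect_error(anneal_config(iter_multiplier = 900), "\\[1, 500\\]")
})

test_that("point validation enforces clash and chain restraints", {
  # residues 1,2,4 collinear; 5 sits 3.4 A above the +y candidate spot
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(NA, NA, NA), c(7.6, 0, 0),
               c(5.7, 6.69, 0))
  m <- ca_model(1:5, xyz, c("fixed", "fixed", "unfixed", "fixed", "fixed"))
  cfg <- anneal_config()
  # 3.8 A from both neighbours, >= 3.5 A from everything else: valid
  expect_true(validate_point(c(5.7, -3.29, 0), 3, m, cfg))
  # same geometry on the +y side clashes with residue 5 at 3.4 A
  expect_false(validate_point(c(5.7, 3.29, 0), 3, m, cfg))
  # 4.6 A from the adjacent residue 2: broken chain
  expect_false(validate_point(c(3.8, -4.6, 0), 3, m, cfg))
  # full-chain case: an in-place helix residue validates
  truth <- make_chain(20, "helix")
  mh <- ca_model(1:20, truth, rep("fixed", 20))
  expect_true(validate_point(truth[10, ], 10, mh, cfg))
})

test_that("validation agrees with a brute-force checker on random models", {
  set.seed(23)
  cfg <- anneal_config()
  for (rep in 1:100) {
    n <- sample(8:25, 1)
    xyz <- matrix(runif(n * 3, 0, 12), n, 3)
    m <- ca_model(seq_len(n), xyz, rep("fixed", n))
    i <- sample(n, 1)
    cand <- runif(3, 0, 12)
    expect_equal(validate_point(cand, i, m, cfg),
                 brute_validate(cand, i, m))
  }
})

test_that("acceptance is downhill-always, uphill iff dE < T ln 2, with stated cooling", {
  # downhill: accepted, temperature drops by exactly 1
  s <- accept_step(9, 10, Temp = 50, iteration = 3, N = 20)
  expect_true(s$accepted)
  expect_equal(s$T_next, 49)
  # zero gap: p = 1 > 0.5, accepted
  expect_true(accept_step(10, 10, 50, 3, 20)$accepted)
  # analytic boundary: dE = T ln 2 gives p = 0.5 exactly -> rejected
  T0 <- 40
  expect_false(accept_step(10 + T0 * log(2), 10, T0, 3, 20)$accepted)
  expect_true(accept_step(10 + T0 * log(2) - 1e-9, 10, T0, 3, 20)$accepted)
  # uphill cooling: d = 0.2 dE (iter/N), positive
  s <- accept_step(15, 10, 50, 10, 20)
  expect_equal(s$T_next, 50 - 0.2 * 5 * (10 / 20))
  expect_lt(accept_step(10, 10, 50, 10, 20)$T_next, 50)  # floored decrement
})

test_that("default energy scores ideal chains at ~0 and is rigid-motion invariant", {
  truth <- make_chain(30, "helix")
  m <- ca_model(1:30, truth, rep("fixed", 30))
  e <- default_ca_energy(m)
  # bonded and repulsion terms vanish; only the weak Rg restraint remains
  ctr <- colMeans(truth)
  rg <- sqrt(mean(rowSums(sweep(truth, 2, ctr)^2)))
  expect_equal(e, 0.01 * (rg - 2.2 * 30^0.38)^2, tolerance = 1e-9)
  # pushing a residue to 3.0 A from a non-neighbor raises E by >= 1.0
  m2 <- m
  dir <- truth[1, ] - truth[15, ]
  m2$xyz[1, ] <- truth[15, ] + dir / sqrt(sum(dir^2)) * 3.0
  expect_gte(default_ca_energy(m2) - e, 1.0)
  # rigid-motion invariance
  m3 <- m
  m3$xyz <- sweep(apply_transform(rotation_about_axis(c(0, 1, 0), 0.4),
                                  m$xyz), 2, c(11, -4, 2), "+")
  expect_equal(default_ca_energy(m3), e, tolerance = 1e-9)
})

test_that("clash counting matches a brute-force double loop", {
  truth <- make_chain(30, "helix")
  expect_equal(count_clashes(ca_model(1:30, truth, rep("fixed", 30))), 0L)
  two <- truth
  two[25, ] <- two[5, ] + c(3.4, 0, 0)
  m <- ca_model(1:30, two, rep("fixed", 30))
  expect_equal(count_clashes(m), brute_clashes(two))
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    xyz <- matrix(runif(n * 3, 0, 10), n, 3)
    expect_equal(count_clashes(ca_model(seq_len(n), xyz, rep("fixed", n))),
                 brute_clashes(xyz))
  }
})

test_that("proposals only move unfixed residues to valid positions", {
  truth <- make_chain(25, "helix")
  m <- ca_model(1:25, truth, rep("fixed", 25))
  cfg <- anneal_config()
  # a cloud whose mean sits in a clash pocket: every candidate invalid
  clouds <- list(`10` = list(i = 10L, p_avg = truth[20, ], wad = 0.01,
                             unfixed = TRUE))
  set.seed(41)
  prop <- propose_model(m, clouds, cfg)
  expect_identical(prop$xyz, m$xyz)  # no-op when nothing validates
  # a single well-separated unfixed residue moves only itself
  clouds <- list(`10` = list(i = 10L, p_avg = truth[10, ], wad = 0.08,
                             unfixed = TRUE))
  set.seed(41)
  prop <- propose_model(m, clouds, cfg)
  expect_equal(prop$xyz[-10, ], m$xyz[-10, ])
  expect_false(all(prop$xyz[10, ] == m$xyz[10, ]))
  expect_true(validate_point(prop$xyz[10, ], 10, m, cfg))
})

test_that("proposals never break chains at unfixed adjacencies", {
  set.seed(43)
  truth <- make_chain(30, "random-walk")
  tpls <- lapply(1:3, function(k) make_template(truth, c(1, 30), 1.0,
                                                paste0("t", k)))
  sup <- superpose_templates(tpls)
  w <- data.frame(id = paste0("t", 1:3), total = rep(1, 3))
  clouds <- build_clouds(sup, w)
  pavg <- t(sapply(clouds, `[[`, "p_avg"))
  prov <- ifelse(sapply(clouds, `[[`, "unfixed"), "unfixed", "fixed")
  m <- ca_model(1:30, pavg, prov)
  cfg <- anneal_config()
  broken0 <- sum(consecutive_distances(m) > 4.5)
  for (rep in 1:100) {
    prop <- propose_model(m, clouds, cfg)
    expect_lte(sum(consecutive_distances(prop) > 4.5), broken0)
  }
})

test_that("annealing terminates, cools monotonically and returns the best accepted model", {
  set.seed(47)
  truth <- make_chain(40, "random-walk")
  tpls <- lapply(1:4, function(k) make_template(truth, c(1, 40), 1.2,
                                                paste0("t", k)))
  sup <- superpose_templates(tpls)
  w <- data.frame(id = paste0("t", 1:4), total = rep(1, 4))
  clouds <- build_clouds(sup, w)
  pavg <- t(sapply(clouds, `[[`, "p_avg"))
  prov <- ifelse(sapply(clouds, `[[`, "unfixed"), "unfixed", "fixed")
  m <- ca_model(1:40, pavg, prov)
  ann <- run_annealing(m, clouds, config = anneal_config())
  expect_lte(nrow(ann$trace), ceiling(ann$N))  # N = 1000/n_unfixed may be fractional
  expect_true(all(diff(c(ann$T0, ann$trace$T)) < 0))      # strictly cooling
  expect_lte(ann$E_best, default_ca_energy(m))            # never worse
  expect_equal(ann$E_best, default_ca_energy(ann$best), tolerance = 1e-9)
  acc <- ann$trace$E[ann$trace$accepted]
  expect_equal(ann$E_best, min(c(default_ca_energy(m), acc)))
  # clash count does not increase
  expect_lte(count_clashes(ann$best), count_clashes(m))

  # no unfixed residues: initial model returned untouched, zero iterations
  fixed_clouds <- lapply(clouds, function(cl) { cl$unfixed <- FALSE; cl })
  ann0 <- run_annealing(m, fixed_clouds, config = anneal_config())
  expect_identical(ann0$best$xyz, m$xyz)
  expect_equal(nrow(ann0$trace), 0L)
})

test_that("annealing runs are bit-reproducible under a fixed seed", {
  set.seed(53)
  truth <- make_chain(25, "random-walk")
  tpls <- lapply(1:3, function(k) make_template(truth, c(1, 25), 1.0,
                                                paste0("t", k)))
  sup <- superpose_templates(tpls)
  w <- data.frame(id = paste0("t", 1:3), total = rep(1, 3))
  clouds <- build_clouds(sup, w)
  pavg <- t(sapply(clouds, `[[`, "p_avg"))
  prov <- ifelse(sapply(clouds, `[[`, "unfixed"), "unfixed", "fixed")
  m <- ca_model(1:25, pavg, prov)
  set.seed(99); a <- run_annealing(m, clouds, config = anneal_config())
  set.seed(99); b <- run_annealing(m, clouds, config = anneal_config())
  expect_identical(a$best$xyz, b$best$xyz)
  expect_identical(a$trace, b$trace)
})

test_that("energy backends resolve by name and reject unknown names", {
  expect_identical(energy_backend("default"), default_ca_energy)
  expect_error(energy_backend("nope"), "unknown")
  f <- energy_backend("external:cat")
  expect_true(is.function(f))
})
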