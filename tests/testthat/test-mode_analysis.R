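test_that("square fluctuations: symmetry, pseudo-inverse oracle, monotonicity", {
  dimer_modes <- suppressWarnings(enm_modes(make_dimer(), n_modes = "all"))
  f <- square_fluctuations(dimer_modes, m_modes = 1)
  expect_equal(f[1], f[2], tolerance = 1e-12)

  h <- make_helix(12)
  modes <- enm_modes(h, n_modes = "all")
  f_all <- square_fluctuations(modes, m_modes = length(modes$values))
  ## oracle: trace of the 3x3 diagonal blocks of the Hessian pseudo-inverse
  H <- build_hessian(h)$matrix
  eg <- eigen(H, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  G <- eg$vectors[, keep] %*% (t(eg$vectors[, keep]) / eg$values[keep])
  oracle <- vapply(seq_len(h$n_sites), function(i)
    sum(diag(G)[(3 * i - 2):(3 * i)]), 0)
  expect_equal(f_all, oracle, tolerance = 1e-8)

  ## per-residue monotone non-decreasing in the number of modes
  f_prev <- square_fluctuations(modes, m_modes = 5)
  for (m in c(10, 20, length(modes$values))) {
    f_m <- square_fluctuations(modes, m_modes = m)
    expect_true(all(f_m >= f_prev - 1e-12))
    f_prev <- f_m
  }
  expect_warning(square_fluctuations(modes, m_modes = 1000), "available")
})

test_that("helix ends fluctuate more than the core (classic ENM end effect)", {
  modes <- expect_connected_modes(make_helix(20), n_modes = "all")
  f <- square_fluctuations(modes, m_modes = 20)
  expect_gt(f[1], median(f[8:13]))
  expect_gt(f[20], median(f[8:13]))
})

test_that("effective force constant: analytic spring compliances", {
  ## one spring of constant gamma has stiffness gamma
  modes <- suppressWarnings(enm_modes(make_dimer(), n_modes = "all"))
  expect_equal(effective_force_constant(modes, 1, 2), 1.0,
               tolerance = 1e-10)
  g2 <- suppressWarnings(
    enm_modes(make_dimer(), enm_params(gamma = 3), n_modes = "all"))
  expect_equal(effective_force_constant(g2, 1, 2), 3.0, tolerance = 1e-10)

  ## two springs in series are softer: kappa_13 = gamma/2 < kappa_12
  tri <- make_trimer()
  tri_modes <- suppressWarnings(
    enm_modes(tri, enm_params(cutoff_rc = 5), n_modes = "all"))
  k12 <- effective_force_constant(tri_modes, 1, 2)
  k13 <- effective_force_constant(tri_modes, 1, 3)
  expect_equal(k12, 1.0, tolerance = 1e-9)
  expect_equal(k13, 0.5, tolerance = 1e-9)
  expect_lt(k13, k12)
  expect_equal(k12, effective_force_constant(tri_modes, 2, 1),
               tolerance = 1e-12)

  ## rotation invariance
  set.seed(5)
  db <- make_dumbbell(n_per_lobe = 8, seed = 4)
  m1 <- enm_modes(db$model, n_modes = "all")
  rot <- db$model
  rot$xyz <- tcrossprod(rot$xyz, random_rotation())
  m2 <- enm_modes(rot, n_modes = "all")
  expect_equal(effective_force_constant(m1, 3, 11),
               effective_force_constant(m2, 3, 11), tolerance = 1e-8)

  ## partial mode sets are refused
  part <- enm_modes(db$model, n_modes = 10)
  expect_error(effective_force_constant(part, 1, 2), "all non-zero modes")
})

test_that("residue stiffness equals the mean pairwise force constant", {
  modes <- suppressWarnings(enm_modes(make_dimer(), n_modes = "all"))
  s <- residue_stiffness(modes)
  expect_equal(s[1], s[2], tolerance = 1e-12)
  expect_equal(s[1], 1.0, tolerance = 1e-10)

  db <- make_dumbbell(n_per_lobe = 8, seed = 4)
  m <- enm_modes(db$model, n_modes = "all")
  s <- residue_stiffness(m)
  brute <- vapply(seq_len(db$model$n_sites), function(i)
    mean(vapply(setdiff(seq_len(db$model$n_sites), i), function(j)
      effective_force_constant(m, i, j), 0)), 0)
  expect_equal(s, brute, tolerance = 1e-8)

  ## pairs reached through the thin linker are softer than pairs
  ## inside one lobe (springs in series)
  db2 <- make_dumbbell(seed = 2)
  m2 <- enm_modes(db2$model, n_modes = "all")
  a <- db2$domains$lobeA; b <- db2$domains$lobeB
  set.seed(1)
  within <- replicate(40, {
    ij <- sample(a, 2)
    effective_force_constant(m2, ij[1], ij[2])
  })
  across <- replicate(40, effective_force_constant(
    m2, sample(a, 1), sample(b, 1)))
  expect_lt(median(across), median(within))
})

test_that("collectivity spans [1/N, 1] and matches the entropy formula", {
  n <- 10
  uniform <- rep(1 / sqrt(3 * n), 3 * n)
  one_site <- c(1, rep(0, 3 * n - 1))
  fm <- fake_modes(values = c(1, 2),
                   vectors = cbind(uniform, one_site))
  expect_equal(collectivity(fm, 1), 1.0, tolerance = 1e-12)
  expect_equal(collectivity(fm, 2), 1 / n, tolerance = 1e-12)

  set.seed(9)
  for (rep_i in 1:5) {
    v <- rnorm(3 * 50); v <- v / sqrt(sum(v^2))
    fmr <- fake_modes(1, matrix(v, ncol = 1))
    p <- rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)
    p <- p / sum(p)
    oracle <- exp(-sum(p * log(p))) / 50
    expect_equal(collectivity(fmr, 1), oracle, tolerance = 1e-12)
    expect_gte(oracle, 1 / 50); expect_lte(oracle, 1 + 1e-12)
    ## invariant to global sign (scale fixed by normalization)
    fneg <- fake_modes(1, matrix(-v, ncol = 1))
    expect_equal(collectivity(fneg, 1), oracle, tolerance = 1e-12)
  }
})

test_that("axis components: orthogonality, zero sum, domain signs", {
  ## pure-x mode has zero z-components
  n <- 6
  vx <- rep(c(1, 0, 0), n) / sqrt(n)
  fm <- fake_modes(1, matrix(vx, ncol = 1))
  expect_equal(axis_components(fm, 1, c(0, 0, 1)), rep(0, n))
  expect_equal(axis_components(fm, 1, c(1, 0, 0)), rep(1 / sqrt(n), n))

  ## real connected-network modes are orthogonal to uniform translation
  modes <- expect_connected_modes(make_helix(15), n_modes = "all")
  for (k in c(1, 3, 10))
    for (ax in list(c(0, 0, 1), c(1, 0, 0)))
      expect_lt(abs(sum(axis_components(modes, k, ax))), 1e-8)
})

test_that("domain means: brute-force equality and whole-model zero", {
  db <- make_dumbbell(seed = 3)
  al <- align_pulling_axis(db$model, db$pulling)
  modes <- enm_modes(al$model, n_modes = "all")
  dm <- domain_map(al$model, lobeA = db$domains$lobeA,
                   lobeB = db$domains$lobeB)
  for (k in 1:5) {
    got <- domain_mean_axis_displacement(modes, k, dm)
    ci <- axis_components(modes, k)
    expect_equal(got[["lobeA"]], mean(ci[db$domains$lobeA]),
                 tolerance = 1e-12)
    expect_equal(got[["lobeB"]], mean(ci[db$domains$lobeB]),
                 tolerance = 1e-12)
  }
  whole <- domain_map(al$model, all = seq_len(al$model$n_sites))
  expect_lt(abs(domain_mean_axis_displacement(modes, 2, whole)), 1e-10)
  expect_error(domain_map(al$model, a = 1:10, b = 5:20), "disjoint")
})

test_that("separating-mode selection finds the constructed dumbbell mode", {
  db <- make_dumbbell(seed = 1)
  al <- align_pulling_axis(db$model, db$pulling)
  modes <- enm_modes(al$model, n_modes = "all")
  dm <- domain_map(al$model, lobeA = db$domains$lobeA,
                   lobeB = db$domains$lobeB)
  sel <- select_separating_modes(modes, dm)
  expect_gt(length(sel$selected), 0)
  top <- sel$selected[1]
  means <- domain_mean_axis_displacement(modes, top, dm)
  expect_lt(means[1] * means[2], 0)   # opposite directions along z
  ## the top mode has the largest candidate separation
  expect_equal(max(sel$report$separation[sel$report$opposite]),
               unname(abs(means[1] - means[2])), tolerance = 1e-12)

  ## label-swap and axis-flip invariance
  dm_swap <- domain_map(al$model, lobeB = db$domains$lobeB,
                        lobeA = db$domains$lobeA)
  sel_swap <- select_separating_modes(modes, dm_swap)
  expect_identical(sel$selected, sel_swap$selected)
  sel_flip <- select_separating_modes(modes, dm, axis = c(0, 0, -1))
  expect_identical(sel$selected, sel_flip$selected)

  ## report is emitted even when nothing passes
  strict <- mode_selection_criteria(first_k = 1, top_collectivity = 1,
                                    of_first = 1)
  sel1 <- select_separating_modes(modes, dm, criteria = strict)
  expect_s3_class(sel1, "mode_selection")
  expect_true(is.data.frame(sel1$report))
  expect_error(select_separating_modes(modes, whole <- domain_map(
    al$model, all = 1:10)), "exactly 2 domains")
})
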