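test_that("two-bead network has the analytic single-spring solution", {
  d <- make_dimer(3.8)
  expect_warning(modes <- enm_modes(d, n_modes = "all"), "5")
  expect_identical(modes$n_zero_modes, 5L)
  expect_length(modes$values, 1L)
  expect_equal(modes$values[1], 2.0, tolerance = 1e-10)
  v_expected <- c(1, 0, 0, -1, 0, 0) / sqrt(2)
  expect_equal(abs(sum(modes$vectors[, 1] * v_expected)), 1,
               tolerance = 1e-10)

  ## single stretched spring: V = (gamma/2) (d - d0)^2
  stretched <- rbind(c(0, 0, 0), c(4.8, 0, 0))
  expect_equal(enm_energy(d, stretched), 0.5)
  expect_identical(enm_energy(d, d$xyz), 0)
})

test_that("Hessian matches finite differences of the network energy", {
  h <- make_helix(10)
  H <- build_hessian(h)
  n3 <- 3 * h$n_sites
  eps <- 1e-5
  fd <- matrix(0, n3, n3)
  perturb <- function(v) h$xyz + matrix(v, ncol = 3, byrow = TRUE)
  for (a in seq_len(n3)) for (b in a:n3) {
    ea <- replace(numeric(n3), a, eps)
    eb <- replace(numeric(n3), b, eps)
    val <- (enm_energy(h, perturb(ea + eb)) - enm_energy(h, perturb(ea - eb)) -
              enm_energy(h, perturb(eb - ea)) + enm_energy(h, perturb(-ea - eb))) /
      (4 * eps^2)
    fd[a, b] <- fd[b, a] <- val
  }
  expect_lt(max(abs(fd - H$matrix)), 1e-5)
})

test_that("network energy equals the quadratic form for small displacements", {
  h <- make_helix(10)
  H <- build_hessian(h)
  set.seed(3)
  eta <- rnorm(30) * 1e-3
  quad <- 0.5 * sum(eta * (H$matrix %*% eta))
  full <- enm_energy(h, h$xyz + matrix(eta, ncol = 3, byrow = TRUE))
  expect_equal(full, quad, tolerance = 1e-4)
  expect_error(enm_energy(h, h$xyz[1:5, ]), "shape")
})

test_that("Hessian structure: symmetry, translation invariance, PSD", {
  db <- make_dumbbell(n_per_lobe = 10, seed = 2)
  H <- build_hessian(db$model)$matrix
  expect_lt(max(abs(H - t(H))), 1e-12)
  for (axis in 1:3) {
    tr <- rep(0, 3); tr[axis] <- 1
    u <- rep(tr, nrow(db$model$xyz))
    expect_lt(max(abs(H %*% u)), 1e-10)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})

test_that("mode computation: counts, residuals, orthonormality", {
  db <- make_dumbbell(n_per_lobe = 10, seed = 2)
  H <- build_hessian(db$model)
  modes <- compute_modes(H, n_modes = "all")
  expect_identical(modes$n_zero_modes, 6L)
  lam_max <- max(modes$values)
  for (k in c(1, 5, length(modes$values))) {
    resid <- H$matrix %*% modes$vectors[, k] -
      modes$values[k] * modes$vectors[, k]
    expect_lt(max(abs(resid)), 1e-8 * lam_max)
  }
  gram <- crossprod(modes$vectors)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)

  ## truncation request honoured
  few <- compute_modes(H, n_modes = 10)
  expect_length(few$values, 10L)
  expect_false(few$complete)
  expect_equal(few$values, modes$values[1:10])
})

test_that("eigenvalues agree with an independently assembled quadratic form", {
  db <- make_dumbbell(n_per_lobe = 10, seed = 6)
  xyz <- db$model$xyz
  n <- nrow(xyz)
  ## independent assembly: H = sum over contacts of gamma * d_c d_c^T
  ## where d_c is the 3N gradient of the bond length at the reference
  D <- as.matrix(dist(xyz))
  Href <- matrix(0, 3 * n, 3 * n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] >= 15) next
    e <- (xyz[j, ] - xyz[i, ]) / D[i, j]
    g <- numeric(3 * n)
    g[(3 * j - 2):(3 * j)] <- e
    g[(3 * i - 2):(3 * i)] <- -e
    Href <- Href + tcrossprod(g)
  }
  ours <- enm_modes(db$model, n_modes = "all")
  ref <- sort(eigen(Href, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ours$values, ref[ref > 1e-8 * max(ref)], tolerance = 1e-8)
})

test_that("eigenvalues are rigid-transform invariant and scale with gamma", {
  set.seed(21)
  h <- make_helix(15)
  base <- enm_modes(h, n_modes = "all")
  for (rep_i in 1:3) {
    moved <- h
    moved$xyz <- tcrossprod(h$xyz, random_rotation()) +
      matrix(rnorm(3, sd = 20), nrow(h$xyz), 3, byrow = TRUE)
    m2 <- enm_modes(moved, n_modes = "all")
    expect_equal(m2$values, base$values, tolerance = 1e-8)
  }
  scaled <- enm_modes(h, enm_params(gamma = 2.5), n_modes = "all")
  expect_equal(scaled$values, 2.5 * base$values, tolerance = 1e-10)
  expect_lt(max(abs(abs(colSums(scaled$vectors * base$vectors)) - 1)), 1e-6)
})

test_that("disconnected networks are flagged", {
  far <- coarse_model(rbind(c(0, 0, 0), c(3.8, 0, 0), c(100, 0, 0),
                            c(103.8, 0, 0), c(100, 3.8, 0)),
                      rep("ALA", 5), rep("A", 5), 1:5)
  expect_warning(H <- build_hessian(far), "disconnected")
  expect_identical(H$n_components, 2L)
})

test_that("modes cross-check against an independent ANM implementation", {
  h <- make_helix(12)
  p <- tempfile(fileext = ".pdb")
  write_coarse_pdb(h, p)
  model <- read_coarse_pdb(p)   # same rounded coordinates for both routes
  ours <- enm_modes(model, enm_params(cutoff_rc = 15, gamma = 1),
                    n_modes = "all")
  ref <- bio3d::nma(bio3d::read.pdb(p), ff = "anm", cutoff = 15,
                    mass = FALSE, temp = NULL)
  lam_ref <- ref$L[ref$L > 1e-8 * max(ref$L)]
  expect_equal(ours$values, lam_ref, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mode sets serialize to the text interchange format", {
  modes <- expect_connected_modes(make_helix(8), n_modes = 5)
  p <- tempfile(fileext = ".nmd")
  write_nmd(modes, p)
  lines <- readLines(p)
  expect_identical(sum(grepl("^mode ", lines)), 5L)
  f1 <- strsplit(lines[grepl("^mode 1 ", lines)], " ")[[1]]
  expect_equal(as.numeric(f1[3]), modes$values[1], tolerance = 1e-9)
  expect_length(f1, 3 + 3 * modes$n_sites)
})
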