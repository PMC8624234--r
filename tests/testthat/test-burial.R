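test_that("residue radii follow the volume table in closed form", {
  m <- coarse_model(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                    c("TRP", "GLY", "TRP"), rep("A", 3), 1:3)
  r <- residue_radii(m)
  v <- residue_volume_table()
  expect_equal(4 / 3 * pi * r^3, unname(v[c("TRP", "GLY", "TRP")]),
               tolerance = 1e-9)
  expect_identical(r[1], r[3])

  ## radius ordering matches volume ordering across the whole table
  codes <- names(v)
  mt <- coarse_model(cbind(seq_along(codes) * 50, 0, 0), codes,
                     rep("A", length(codes)), seq_along(codes))
  expect_identical(order(residue_radii(mt)), order(unname(v)))

  ## unknown codes fall back with a warning
  mu <- coarse_model(rbind(c(0, 0, 0), c(10, 0, 0)), c("XYZ", "ALA"),
                     c("A", "A"), 1:2)
  expect_warning(ru <- residue_radii(mu), "unknown code")
  expect_equal(ru[1], (3 * v[["GLY"]] / (4 * pi))^(1 / 3))
})

test_that("exposed fractions: isolation, occlusion cage, quadrature", {
  params <- burial_params()
  ## two distant beads occlude nothing
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(exposed_fractions(far, c(3, 3), params), c(1, 1))

  ## icosahedral cage of large neighbours fully occludes the centre
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  ico <- ico / sqrt(1 + phi^2) * 4      # vertices at 4 A
  cage <- rbind(c(0, 0, 0), ico)
  radii <- c(2, rep(4, 12))
  fr <- exposed_fractions(cage, radii, params)
  expect_identical(fr[1], 0)
  ## independent oracle: direct point-rejection count for the centre
  S <- sweep(fsnma:::sphere_points(params$n_sphere_points) *
               (radii[1] + params$probe_radius), 2, cage[1, ], `+`)
  covered <- rep(FALSE, nrow(S))
  for (j in 2:13)
    covered <- covered |
      rowSums(sweep(S, 2, cage[j, ])^2) < (radii[j] + params$probe_radius)^2
  expect_identical(fr[1], mean(!covered))

  ## adding a neighbour never increases anyone's exposure
  base <- rbind(c(0, 0, 0), c(5, 0, 0))
  fr2 <- exposed_fractions(base, c(3, 3), params)
  fr3 <- exposed_fractions(rbind(base, c(2.5, 4, 0)), c(3, 3, 3), params)
  expect_true(all(fr3[1:2] <= fr2 + 1e-12))

  ## quadrature convergence: doubling the points moves fractions < 0.01
  db <- make_dumbbell(n_per_lobe = 12, seed = 2)
  r <- residue_radii(db$model)
  f1 <- exposed_fractions(db$model$xyz, r, burial_params(n_sphere_points = 960))
  f2 <- exposed_fractions(db$model$xyz, r, burial_params(n_sphere_points = 1920))
  expect_lt(max(abs(f1 - f2)), 0.01)

  expect_error(exposed_fractions(rbind(c(0, 0, 0), c(0, 0, 0)), c(2, 2),
                                 params), "degenerate|coincident")
})

test_that("burial classification and volume totals behave at the extremes", {
  db <- make_dumbbell(seed = 6)
  params <- burial_params()
  rep0 <- classify_buried(db$model, params = params, domains = db$domains)
  expect_true(all(rep0$residues$buried ==
                    (rep0$residues$exposed_fraction < 0.05)))
  expect_lte(sum(rep0$domain_buried_volume), rep0$total_buried_volume)

  ## nothing buried when everything is exposed
  far <- coarse_model(cbind(seq_len(5) * 100, 0, 0), rep("ALA", 5),
                      rep("A", 5), 1:5)
  rf <- classify_buried(far, params = params)
  expect_identical(rf$total_buried_volume, 0)

  ## near-saturating threshold buries every partially occluded residue
  sat <- burial_params(exposure_threshold = 0.999)
  rs <- classify_buried(db$model, params = sat)
  occluded <- rs$residues$exposed_fraction < 0.999
  expect_identical(rs$total_buried_volume,
                   sum(rs$residues$volume[occluded]))
  expect_gt(mean(occluded), 0.9)   # a compact cluster occludes nearly all

  ## 3x uniform expansion empties the core
  blown <- db$model
  blown$xyz <- blown$xyz * 3
  expect_identical(classify_buried(blown, params = params)$total_buried_volume,
                   0)

  ## rigid transforms change buried volume only by quadrature error
  set.seed(31)
  moved <- db$model
  moved$xyz <- tcrossprod(moved$xyz, random_rotation()) + 13.7
  rm_ <- classify_buried(moved, params = params)
  expect_equal(rm_$total_buried_volume, rep0$total_buried_volume,
               tolerance = 0.15)
})

test_that("ensemble burial statistics aggregate per-frame reports", {
  db <- loose_dumbbell(seed = 2)
  al <- align_pulling_axis(db$model, db$pulling)
  dm <- domain_map(al$model, lobeA = db$domains$lobeA,
                   lobeB = db$domains$lobeB)
  modes <- enm_modes(al$model, n_modes = "all")

  ## a 1-frame undeformed "ensemble" reproduces the static report
  still <- fsnma:::new_ensemble(al$model,
                                array(al$model$xyz,
                                      c(1, al$model$n_sites, 3)),
                                matrix(0, 1, 1), 1L, 0)
  eb1 <- ensemble_burial(still, dm)
  static <- classify_buried(al$model, domains = dm)
  expect_equal(eb1$stats$mean, unname(static$domain_buried_volume))
  expect_identical(eb1$stats$sd, c(0, 0))

  ## nonzero-restricted means never fall below the overall means
  ens <- sample_ensemble(modes, deformation_spec(1:3, 6, 12, seed = 3))
  eb <- ensemble_burial(ens, dm)
  expect_true(all(eb$stats$mean_nonzero >= eb$stats$mean - 1e-9))
  expect_identical(eb$stats$n_frames, c(12L, 12L))
  expect_true(all(eb$stats$n_nonzero <= 12L))
})
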