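## Mean amino-acid residue volumes (Angstrom^3), Zamyatnin (1972)
## Prog. Biophys. Mol. Biol. 24:107-123 -- the customary table of mean
## residue volumes in protein interiors.  Data, swappable via
## burial_params(volume_table = ...).
.residue_volumes <- c(
  ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

#' Bundled mean residue volume table
#'
#' @return Named numeric vector, 3-letter code to mean residue volume
#'   in Angstrom^3.
#' @export
residue_volume_table <- function() .residue_volumes

#' Burial analysis parameters
#'
#' The buried core is the complement of the solvent-exposed surface:
#' a residue is buried when the exposed fraction of its probe-inflated
#' C-alpha sphere falls below `exposure_threshold`.  The sphere radius
#' of each residue is derived from its mean residue volume, so the
#' same model applies to intact structures and to C-alpha-only
#' deformed frames, keeping the comparison consistent.
#'
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points Quadrature points per sphere (default 960;
#'   deterministic golden-spiral placement, so results are seed-free).
#' @param exposure_threshold Exposed-area fraction below which a
#'   residue counts as buried (default 0.05).
#' @param volume_table Named residue-volume map (Angstrom^3).
#' @param fallback_code Residue code whose volume is used for unknown
#'   residue names (default `"GLY"`, with a warning).
#' @return An object of class `burial_params`.
#' @export
burial_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                          exposure_threshold = 0.05,
                          volume_table = residue_volume_table(),
                          fallback_code = "GLY") {
  stopifnot(probe_radius >= 0, n_sphere_points >= 32L,
            exposure_threshold > 0, exposure_threshold < 1,
            all(volume_table > 0), fallback_code %in% names(volume_table))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 exposure_threshold = exposure_threshold,
                 volume_table = volume_table,
                 fallback_code = fallback_code),
            class = "burial_params")
}

#' Per-residue sphere radii from mean residue volumes
#'
#' `r_i = (3 V_i / 4 pi)^(1/3)`; unknown residue codes fall back to
#' the configured code's volume with a warning.
#'
#' @param model A [coarse_model()].
#' @param params [burial_params()].
#' @return Numeric vector of radii (Angstrom).
#' @export
residue_radii <- function(model, params = burial_params()) {
  stopifnot(inherits(model, "coarse_model"))
  v <- params$volume_table[model$residue_name]
  unknown <- is.na(v)
  if (any(unknown)) {
    warning(sum(unknown), " residue(s) with unknown code (",
            paste(unique(model$residue_name[unknown]), collapse = ","),
            ") assigned the ", params$fallback_code, " volume")
    v[unknown] <- params$volume_table[params$fallback_code]
  }
  (3 * as.numeric(v) / (4 * pi))^(1 / 3)
}

residue_volumes_of <- function(model, params) {
  v <- params$volume_table[model$residue_name]
  v[is.na(v)] <- params$volume_table[params$fallback_code]
  as.numeric(v)
}

## deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Fraction of each residue sphere accessible to solvent
#'
#' Numerical solvent-accessible-surface quadrature on probe-inflated
#' spheres: for each residue, the fraction of deterministically placed
#' surface points on its sphere of radius `r_i + probe` not contained
#' in any neighbour's inflated sphere.  Bit-reproducible at fixed
#' `n_sphere_points`; converges as points are added.
#'
#' @param coords N x 3 coordinates (or a [coarse_model()]).
#' @param radii Per-residue sphere radii from [residue_radii()].
#' @param params [burial_params()].
#' @return Numeric vector of exposed fractions in `[0, 1]`.
#' @export
exposed_fractions <- function(coords, radii, params = burial_params()) {
  xyz <- as_xyz(coords)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  R <- radii + params$probe_radius
  S <- sphere_points(params$n_sphere_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (any(d2[i, nb] < 1e-18))
      stop("coincident sphere centres: burial geometry degenerate")
    if (!length(nb)) { out[i] <- 1; next }
    pts <- sweep(S * R[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (pts[free, 1L] - xyz[j, 1L])^2 +
        (pts[free, 2L] - xyz[j, 2L])^2 +
        (pts[free, 3L] - xyz[j, 3L])^2
      free[free] <- dj2 >= R[j]^2
    }
    out[i] <- mean(free)
  }
  out
}

#' Classify buried residues and total their volumes
#'
#' A residue is buried when its exposed fraction is below the
#' threshold; a domain's buried volume is the summed mean residue
#' volume of its buried members -- the packing proxy used to rank
#' domain structural integrity.
#'
#' @param model A [coarse_model()] (residue names supply volumes).
#' @param fractions Exposed fractions from [exposed_fractions()], or
#'   `NULL` to compute them from the model's coordinates.
#' @param params [burial_params()].
#' @param domains Optional [domain_map()] for per-domain totals.
#' @return An object of class `burial_report`: list with `residues`
#'   (data frame: `chain_id`, `residue_seq`, `residue_name`,
#'   `exposed_fraction`, `buried`, `volume`), `domain_buried_volume`
#'   (named vector, if domains given), `total_buried_volume`,
#'   `threshold`.
#' @export
classify_buried <- function(model, fractions = NULL,
                            params = burial_params(), domains = NULL) {
  stopifnot(inherits(model, "coarse_model"))
  if (is.null(fractions))
    fractions <- exposed_fractions(model$xyz, residue_radii(model, params),
                                   params)
  stopifnot(length(fractions) == model$n_sites,
            all(fractions >= 0 & fractions <= 1))
  vols <- residue_volumes_of(model, params)
  buried <- fractions < params$exposure_threshold
  res <- data.frame(chain_id = model$chain_id,
                    residue_seq = model$residue_seq,
                    residue_name = model$residue_name,
                    exposed_fraction = fractions,
                    buried = buried,
                    volume = vols)
  dom <- NULL
  if (!is.null(domains)) {
    stopifnot(inherits(domains, "domain_map"))
    dom <- vapply(domains, function(idx) sum(vols[idx][buried[idx]]), 0)
  }
  structure(list(residues = res,
                 domain_buried_volume = dom,
                 total_buried_volume = sum(vols[buried]),
                 threshold = params$exposure_threshold),
            class = "burial_report")
}

#' @export
print.burial_report <- function(x, ...) {
  cat("<burial_report> ", sum(x$residues$buried), "/",
      nrow(x$residues), " residues buried (exposure < ", x$threshold,
      "), total buried volume ", round(x$total_buried_volume, 1),
      " A^3\n", sep = "")
  if (!is.null(x$domain_buried_volume)) {
    cat("  per-domain buried volume (A^3):\n")
    print(round(x$domain_buried_volume, 1))
  }
  invisible(x)
}

#' Buried-volume statistics over a deformed ensemble
#'
#' Computes a burial report for every frame and aggregates per-domain
#' buried volumes into mean and standard deviation, both over all
#' frames and restricted to frames where the domain retains any buried
#' volume (a domain that has lost its entire core contributes zeros
#' which would otherwise mask how compact the surviving frames are).
#'
#' @param ensemble A `deformed_ensemble`.
#' @param domains A [domain_map()] on the ensemble's reference model.
#' @param params [burial_params()].
#' @return An object of class `ensemble_burial`: data frame `stats`
#'   with one row per domain (`domain`, `mean`, `sd`, `mean_nonzero`,
#'   `sd_nonzero`, `n_frames`, `n_nonzero`) plus matrix
#'   `frame_volumes` (frames x domains).
#' @export
ensemble_burial <- function(ensemble, domains,
                            params = burial_params()) {
  stopifnot(inherits(ensemble, "deformed_ensemble"),
            inherits(domains, "domain_map"))
  ref <- ensemble$reference
  radii <- residue_radii(ref, params)
  vols <- residue_volumes_of(ref, params)
  m <- dim(ensemble$frames)[1L]
  fv <- matrix(0, m, length(domains),
               dimnames = list(NULL, names(domains)))
  for (f in seq_len(m)) {
    fr <- exposed_fractions(ensemble$frames[f, , ], radii, params)
    buried <- fr < params$exposure_threshold
    fv[f, ] <- vapply(domains, function(idx) sum(vols[idx][buried[idx]]), 0)
  }
  stats_df <- data.frame(
    domain = names(domains),
    mean = colMeans(fv),
    sd = apply(fv, 2L, function(v) if (length(v) > 1L) stats::sd(v) else 0),
    mean_nonzero = apply(fv, 2L, function(v)
      if (any(v > 0)) mean(v[v > 0]) else 0),
    sd_nonzero = apply(fv, 2L, function(v)
      if (sum(v > 0) > 1L) stats::sd(v[v > 0]) else 0),
    n_frames = m,
    n_nonzero = apply(fv, 2L, function(v) sum(v > 0)),
    row.names = NULL)
  structure(list(stats = stats_df, frame_volumes = fv),
            class = "ensemble_burial")
}

#' @export
print.ensemble_burial <- function(x, ...) {
  cat("<ensemble_burial> ", nrow(x$frame_volumes), " frames\n", sep = "")
  print(x$stats, digits = 4)
  invisible(x)
}
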