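#' Specification of a mode-driven deformation
#'
#' @param mode_indices Non-empty vector of 1-based non-zero mode
#'   indices.
#' @param target_rmsd Target raw RMSD from the reference, Angstrom
#'   (> 0, capped at `sanity_cap`).
#' @param n_conformations Ensemble size (default 500).
#' @param seed RNG seed.
#' @param weighting `"inverse_lambda"` (default; coefficient standard
#'   deviation proportional to `1/sqrt(lambda_k)`, so softer modes
#'   dominate as they would thermally) or `"equal"`.
#' @param direction +1 or -1 for single-mode use.
#' @param sanity_cap Largest permissible target RMSD (default 20
#'   Angstrom; linear ENM deformations beyond this are meaningless).
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode_indices, target_rmsd,
                             n_conformations = 500L, seed = 1L,
                             weighting = c("inverse_lambda", "equal"),
                             direction = 1, sanity_cap = 20) {
  weighting <- match.arg(weighting)
  mode_indices <- as.integer(mode_indices)
  if (!length(mode_indices)) stop("mode_indices must be non-empty")
  if (target_rmsd < 0) stop("target_rmsd must be non-negative")
  if (target_rmsd > sanity_cap)
    stop("target_rmsd ", target_rmsd, " exceeds the sanity cap of ",
         sanity_cap, " Angstrom")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(mode_indices = mode_indices, target_rmsd = target_rmsd,
                 n_conformations = as.integer(n_conformations),
                 seed = as.integer(seed), weighting = weighting,
                 direction = direction),
            class = "deformation_spec")
}

new_ensemble <- function(reference, frames, coefficients, mode_indices,
                         target_rmsd, seed = NA_integer_,
                         weighting = NA_character_) {
  achieved <- apply(frames, 1L, function(f) rmsd(f, reference$xyz))
  structure(list(reference = reference, frames = frames,
                 coefficients = coefficients,
                 mode_indices = as.integer(mode_indices),
                 target_rmsd = target_rmsd, achieved_rmsd = achieved,
                 seed = seed, weighting = weighting),
            class = "deformed_ensemble")
}

#' @export
print.deformed_ensemble <- function(x, ...) {
  cat("<deformed_ensemble> ", dim(x$frames)[1L], " frame(s), N = ",
      dim(x$frames)[2L], ", modes {",
      paste(x$mode_indices, collapse = ","), "}, target RMSD ",
      x$target_rmsd, " A\n", sep = "")
  invisible(x)
}

#' Deterministic single-mode deformation at a target RMSD
#'
#' `R' = R + s * a_k` with `s = direction * target_rmsd * sqrt(N)`;
#' since the eigenvector has unit norm the achieved raw RMSD equals
#' the target exactly.
#'
#' @param modes A `mode_set`.
#' @param k Non-zero mode index.
#' @param target_rmsd Target RMSD (Angstrom).
#' @param direction +1 or -1.
#' @return A [coarse_model()] with displaced coordinates.
#' @export
deform_single_mode <- function(modes, k, target_rmsd, direction = 1) {
  stopifnot(inherits(modes, "mode_set"))
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  a <- mode_shape(modes, k)
  s <- direction * target_rmsd * sqrt(modes$n_sites)
  out <- modes$model
  out$xyz <- out$xyz + s * a
  out
}

#' Pseudo-trajectory sweeping one mode through its amplitude range
#'
#' Frames sample the single-mode displacement `s * a_k` with `s`
#' ramping linearly from `-s_max` to `+s_max` (so the middle frame of
#' an odd-length sweep is the reference itself); viewers loop the file
#' to animate the oscillation.  `s_max` corresponds to `max_rmsd`.
#'
#' @param modes A `mode_set`.
#' @param k Non-zero mode index.
#' @param max_rmsd Peak RMSD of the sweep (Angstrom).
#' @param n_frames Number of frames (>= 3).
#' @return A `deformed_ensemble`; per-frame coefficients are logged so
#'   any frame can be reconstructed as `R + c * a_k`.
#' @export
pseudo_trajectory <- function(modes, k, max_rmsd, n_frames = 11L) {
  stopifnot(inherits(modes, "mode_set"))
  if (n_frames < 3L) stop("n_frames must be at least 3")
  a <- modes$vectors[, k]
  n <- modes$n_sites
  s_max <- max_rmsd * sqrt(n)
  s <- seq(-s_max, s_max, length.out = n_frames)
  frames <- array(0, dim = c(n_frames, n, 3L))
  for (f in seq_len(n_frames))
    frames[f, , ] <- modes$model$xyz +
      s[f] * matrix(a, ncol = 3L, byrow = TRUE)
  new_ensemble(modes$model, frames,
               coefficients = matrix(s, ncol = 1L,
                                     dimnames = list(NULL, paste0("mode", k))),
               mode_indices = k, target_rmsd = max_rmsd)
}

## run code with a private, seeded RNG stream, restoring global state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Stochastic multi-mode ensemble at an exact target RMSD
#'
#' For each frame, a coefficient is drawn for every selected mode from
#' a zero-mean normal with standard deviation `w_k` (`1/sqrt(lambda_k)`
#' for `inverse_lambda` weighting, 1 for `equal`); the combined
#' displacement is then rescaled so the frame's raw RMSD from the
#' reference equals the target exactly.  Deterministic given the seed;
#' the post-rescale coefficients are logged and reproduce every frame.
#'
#' @param modes A `mode_set`.
#' @param spec A [deformation_spec()].
#' @return A `deformed_ensemble`.
#' @export
sample_ensemble <- function(modes, spec) {
  stopifnot(inherits(modes, "mode_set"),
            inherits(spec, "deformation_spec"))
  ks <- spec$mode_indices
  if (any(ks < 1L | ks > length(modes$values)))
    stop("mode index out of range")
  V <- modes$vectors[, ks, drop = FALSE]
  w <- switch(spec$weighting,
              inverse_lambda = 1 / sqrt(modes$values[ks]),
              equal = rep(1, length(ks)))
  n <- modes$n_sites
  m <- spec$n_conformations
  frames <- array(0, dim = c(m, n, 3L))
  coeffs <- matrix(0, m, length(ks),
                   dimnames = list(NULL, paste0("mode", ks)))
  with_seed(spec$seed, {
    for (f in seq_len(m)) {
      repeat {
        cf <- stats::rnorm(length(ks)) * w
        delta <- as.numeric(V %*% cf)
        nrm <- sqrt(sum(delta^2))
        if (nrm > 1e-12) break
      }
      scale <- spec$target_rmsd * sqrt(n) / nrm
      cf <- cf * scale
      frames[f, , ] <- modes$model$xyz +
        matrix(delta * scale, ncol = 3L, byrow = TRUE)
      coeffs[f, ] <- cf
    }
  })
  new_ensemble(modes$model, frames, coeffs, ks, spec$target_rmsd,
               seed = spec$seed, weighting = spec$weighting)
}

#' Progressive deformation: ensembles at increasing RMSD targets
#'
#' One independent ensemble per target, with per-step sub-seeds derived
#' deterministically from the base seed (`seed + 7919 * step_index`),
#' so any single step can be reproduced in isolation.
#'
#' @param modes A `mode_set`.
#' @param mode_indices Modes to combine.
#' @param targets Strictly increasing RMSD targets (Angstrom), e.g.
#'   `c(2, 4, 6, 8, 10, 12)`.
#' @param n_per_step Frames per target.
#' @param seed Base seed.
#' @param weighting Passed to [deformation_spec()].
#' @return A named list of `deformed_ensemble` objects (names
#'   `"rmsd_<target>"`).
#' @export
rmsd_ramp <- function(modes, mode_indices, targets, n_per_step = 100L,
                      seed = 1L, weighting = "inverse_lambda") {
  if (any(diff(targets) <= 0) || any(targets <= 0))
    stop("targets must be positive and strictly increasing")
  out <- lapply(seq_along(targets), function(s) {
    sample_ensemble(modes, deformation_spec(
      mode_indices, targets[s], n_conformations = n_per_step,
      seed = ramp_subseed(seed, s), weighting = weighting))
  })
  names(out) <- paste0("rmsd_", targets)
  out
}

ramp_subseed <- function(seed, step) {
  as.integer((as.numeric(seed) + 7919 * step) %% 2147483647)
}
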