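#' Elastic network model parameters
#'
#' The anisotropic C-alpha elastic network joins every pair of beads
#' closer than `cutoff_rc` in the reference structure by a harmonic
#' spring of uniform force constant `gamma` (energy
#' `(gamma/2) (d_ij - d_ij^0)^2` per contact).  All fluctuation and
#' stiffness outputs are therefore in gamma-normalized (relative)
#' units; absolute Angstrom^2 values would require calibrating gamma
#' against experiment.
#'
#' @param cutoff_rc Contact cutoff in Angstrom.  Default 15, the
#'   mid-range of the customary 8-20 Angstrom window; values outside
#'   that window trigger a warning.
#' @param gamma Spring force constant (arbitrary units, default 1).
#' @param n_modes Number of non-zero modes to retain, or `"all"`.
#'   Mechanical stiffness requires `"all"`.
#' @return An object of class `enm_params`.
#' @export
enm_params <- function(cutoff_rc = 15, gamma = 1, n_modes = 50L) {
  if (cutoff_rc <= 0) stop("cutoff_rc must be positive")
  if (cutoff_rc < 8 || cutoff_rc > 20)
    warning("cutoff_rc = ", cutoff_rc,
            " is outside the customary 8-20 Angstrom range")
  if (gamma <= 0) stop("gamma must be positive")
  if (!identical(n_modes, "all")) {
    n_modes <- as.integer(n_modes)
    if (is.na(n_modes) || n_modes < 1L)
      stop("n_modes must be a positive integer or \"all\"")
  }
  structure(list(cutoff_rc = cutoff_rc, gamma = gamma, n_modes = n_modes),
            class = "enm_params")
}

contact_pairs <- function(xyz, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L],
       d0 = d[idx])
}

## connected components of the contact graph (BFS on adjacency list)
graph_components <- function(n, i, j) {
  adj <- vector("list", n)
  for (k in seq_along(i)) {
    adj[[i[k]]] <- c(adj[[i[k]]], j[k])
    adj[[j[k]]] <- c(adj[[j[k]]], i[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Elastic network energy of a displaced conformation
#'
#' Harmonic network energy `sum over contacts of
#' (gamma/2) (d_ij - d_ij^0)^2`, with the contact set and equilibrium
#' distances `d_ij^0` fixed by the reference structure (fixed network
#' topology).  Zero at the reference, non-negative everywhere.
#'
#' @param reference A [coarse_model()] defining the network.
#' @param coords N x 3 displaced coordinates.
#' @param params [enm_params()].
#' @return Energy in gamma * Angstrom^2 units.
#' @export
enm_energy <- function(reference, coords, params = enm_params()) {
  stopifnot(inherits(reference, "coarse_model"))
  coords <- as_xyz(coords)
  if (!identical(dim(coords), dim(reference$xyz)))
    stop("coords shape does not match the reference model")
  cp <- contact_pairs(reference$xyz, params$cutoff_rc)
  d <- sqrt(rowSums((coords[cp$i, , drop = FALSE] -
                       coords[cp$j, , drop = FALSE])^2))
  sum(params$gamma / 2 * (d - cp$d0)^2)
}

#' Build the elastic-network Hessian
#'
#' Dense symmetric 3N x 3N second-derivative matrix of the network
#' energy at the reference structure.  For a contact (i,j) the
#' off-diagonal 3 x 3 super-element is `-gamma * e %o% e` with `e` the
#' unit inter-bead vector; diagonal super-elements make every block row
#' sum to zero (translation invariance).
#'
#' @param model A [coarse_model()].
#' @param params [enm_params()].
#' @return An object of class `enm_hessian`: list with `matrix`
#'   (3N x 3N), `model`, `params`, `n_contacts`, `n_components`.
#'   A disconnected contact graph triggers a warning reporting the
#'   component count (the eigendecomposition will then have more than
#'   6 zero modes).
#' @export
build_hessian <- function(model, params = enm_params()) {
  stopifnot(inherits(model, "coarse_model"))
  xyz <- model$xyz
  n <- nrow(xyz)
  cp <- contact_pairs(xyz, params$cutoff_rc)
  if (!length(cp$i)) stop("no contacts under cutoff ", params$cutoff_rc)
  comp <- graph_components(n, cp$i, cp$j)
  n_comp <- max(comp)
  if (n_comp > 1L)
    warning("contact graph is disconnected (", n_comp,
            " components); expect more than 6 zero modes")
  H <- matrix(0, 3L * n, 3L * n)
  g <- params$gamma
  for (k in seq_along(cp$i)) {
    i <- cp$i[k]; j <- cp$j[k]
    e <- (xyz[j, ] - xyz[i, ]) / cp$d0[k]
    blk <- g * tcrossprod(e)
    ii <- (3L * i - 2L):(3L * i)
    jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  structure(list(matrix = H, model = model, params = params,
                 n_contacts = length(cp$i), n_components = n_comp),
            class = "enm_hessian")
}

#' Diagonalize an ENM Hessian into a normal-mode set
#'
#' Eigenpairs sorted by ascending eigenvalue; modes with eigenvalue
#' below `zero_tol * max(eigenvalue)` are discarded as rigid-body
#' (zero) modes and counted.  Mode indexing everywhere in this package
#' is 1-based over the NON-ZERO modes.  A connected 3-D network must
#' yield exactly 6 zero modes; any other count triggers a structural
#' warning.  A safety assertion requires the smallest retained
#' eigenvalue to exceed the largest discarded one by at least 3 orders
#' of magnitude, otherwise the zero/non-zero split is ambiguous and an
#' error is raised.
#'
#' @param hessian An [build_hessian()] result (or a plain symmetric
#'   3N x 3N matrix).
#' @param n_modes Number of non-zero modes to retain, `"all"`, or
#'   `NULL` to take the value from the Hessian's parameters.
#' @param zero_tol Relative zero-eigenvalue threshold (default 1e-8).
#' @return An object of class `mode_set`: `values` (ascending non-zero
#'   eigenvalues), `vectors` (3N x k orthonormal columns, per-site
#'   component order x1,y1,z1,x2,...), `n_zero_modes`, `n_sites`,
#'   `complete` (TRUE if all non-zero modes retained), `params`,
#'   `model` (reference coarse model).
#' @export
compute_modes <- function(hessian, n_modes = NULL, zero_tol = 1e-8) {
  if (inherits(hessian, "enm_hessian")) {
    H <- hessian$matrix
    model <- hessian$model
    params <- hessian$params
  } else {
    H <- as.matrix(hessian)
    model <- NULL
    params <- NULL
  }
  if (max(abs(H - t(H))) > 1e-10) stop("Hessian is not symmetric")
  if (is.null(n_modes))
    n_modes <- if (is.null(params)) "all" else params$n_modes
  eg <- eigen(H, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  lam_max <- max(vals)
  if (lam_max <= 0) stop("Hessian has no positive eigenvalue")
  zero <- vals <= zero_tol * lam_max
  n_zero <- sum(zero)
  lam_zero_max <- max(abs(vals[zero]))
  lam_nz_min <- min(vals[!zero])
  if (lam_nz_min < 1e3 * max(lam_zero_max, .Machine$double.eps * lam_max))
    stop("ambiguous zero-mode separation: smallest retained eigenvalue ",
         "is within 3 orders of magnitude of the largest discarded one")
  if (n_zero != 6L)
    warning("expected 6 rigid-body zero modes, found ", n_zero,
            " (disconnected or degenerate network?)")
  nz_vals <- vals[!zero]
  nz_vecs <- vecs[, !zero, drop = FALSE]
  k_avail <- length(nz_vals)
  k <- if (identical(n_modes, "all")) k_avail else min(n_modes, k_avail)
  structure(list(values = nz_vals[seq_len(k)],
                 vectors = nz_vecs[, seq_len(k), drop = FALSE],
                 n_zero_modes = n_zero,
                 n_sites = nrow(H) / 3L,
                 complete = (k == k_avail),
                 params = params,
                 model = model),
            class = "mode_set")
}

#' Build and diagonalize an ENM in one call
#'
#' @inheritParams build_hessian
#' @inheritParams compute_modes
#' @return A `mode_set` (see [compute_modes()]).
#' @export
enm_modes <- function(model, params = enm_params(), n_modes = NULL,
                      zero_tol = 1e-8) {
  compute_modes(build_hessian(model, params), n_modes = n_modes,
                zero_tol = zero_tol)
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", length(x$values), " non-zero modes (of ",
      3L * x$n_sites - x$n_zero_modes, " internal), ", x$n_zero_modes,
      " zero modes, N = ", x$n_sites,
      if (isTRUE(x$complete)) ", complete", "\n", sep = "")
  cat("  lowest eigenvalues:",
      paste(signif(utils::head(x$values, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

## 3-vector of mode k at each site, as an N x 3 matrix
mode_shape <- function(modes, k) {
  stopifnot(inherits(modes, "mode_set"))
  if (k < 1L || k > length(modes$values))
    stop("mode index ", k, " out of range (", length(modes$values),
         " modes available)")
  matrix(modes$vectors[, k], ncol = 3L, byrow = TRUE)
}

#' Write a mode set in a plain-text NMD-style format
#'
#' Line-oriented interchange format: header lines `nsites`, then
#' `coordinates` (3N reference coordinates), then one `mode <index>
#' <eigenvalue> <3N components>` line per retained mode, whitespace
#' separated.
#'
#' @param modes A `mode_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nmd <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("nsites", modes$n_sites), con)
  if (!is.null(modes$model))
    writeLines(paste("coordinates",
                     paste(sprintf("%.3f", t(modes$model$xyz)),
                           collapse = " ")), con)
  for (k in seq_along(modes$values))
    writeLines(paste("mode", k, sprintf("%.10g", modes$values[k]),
                     paste(sprintf("%.8g", modes$vectors[, k]),
                           collapse = " ")), con)
  invisible(path)
}
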