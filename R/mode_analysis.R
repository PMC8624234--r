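#' Named domain partitions of a coarse model
#'
#' Resolves named residue-range specifications (e.g. NTD/CTD lobes)
#' into disjoint sets of bead indices.
#'
#' @param model A [coarse_model()].
#' @param ... Named arguments, each a character vector of
#'   `"chain:first-last"` range strings (or an integer vector of bead
#'   indices).
#' @return An object of class `domain_map`: a named list of sorted
#'   integer bead-index vectors.
#' @export
domain_map <- function(model, ...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !is.null(names(specs[[1L]])))
    specs <- specs[[1L]]
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("every domain must be named")
  if (anyDuplicated(names(specs))) stop("duplicate domain names")
  out <- lapply(specs, function(sp) {
    if (is.numeric(sp)) {
      idx <- sort(unique(as.integer(sp)))
      if (any(idx < 1L | idx > model$n_sites))
        stop("domain index out of range")
      return(idx)
    }
    sel <- residue_selection(sp, mode = "keep")
    hit <- rep(FALSE, model$n_sites)
    for (r in seq_len(nrow(sel$ranges))) {
      rng <- sel$ranges[r, ]
      m <- model$chain_id == rng$chain_id &
        model$residue_seq >= rng$first_seq &
        model$residue_seq <= rng$last_seq
      if (!any(m))
        stop("domain range ", rng$chain_id, ":", rng$first_seq, "-",
             rng$last_seq, " matches no residue")
      hit <- hit | m
    }
    which(hit)
  })
  all_idx <- unlist(out)
  if (anyDuplicated(all_idx)) stop("domains must be disjoint")
  structure(out, class = "domain_map")
}

#' Per-residue square fluctuations
#'
#' Thermal mean-square displacement of each bead from the lowest
#' `m_modes` non-zero modes: `f_i = sum_k (1/lambda_k) |a_k,i|^2`.
#' Values are in gamma-normalized units (relative, not absolute
#' Angstrom^2); comparisons are valid within a fixed parameterization.
#'
#' @param modes A `mode_set`.
#' @param m_modes Number of modes to sum (default 100; capped at the
#'   number available, with a warning).
#' @return Numeric vector of length N.
#' @export
square_fluctuations <- function(modes, m_modes = 100L) {
  stopifnot(inherits(modes, "mode_set"))
  k_avail <- length(modes$values)
  if (!k_avail) stop("empty mode set")
  if (m_modes > k_avail) {
    warning("only ", k_avail, " modes available; using all")
    m_modes <- k_avail
  }
  V2 <- modes$vectors[, seq_len(m_modes), drop = FALSE]^2
  n <- modes$n_sites
  site_norm2 <- V2[seq(1L, 3L * n, 3L), , drop = FALSE] +
    V2[seq(2L, 3L * n, 3L), , drop = FALSE] +
    V2[seq(3L, 3L * n, 3L), , drop = FALSE]
  as.numeric(site_norm2 %*% (1 / modes$values[seq_len(m_modes)]))
}

#' Degree of collectivity of a mode
#'
#' Entropy-based measure of how many sites participate in mode `k`:
#' with `p_i = |a_k,i|^2 / sum_j |a_k,j|^2`,
#' `kappa = exp(-sum p_i log p_i) / N`.  Ranges from `1/N` (one site
#' moves) to 1 (all sites move equally).
#'
#' @param modes A `mode_set`.
#' @param k 1-based non-zero mode index (may be a vector).
#' @return Numeric vector of collectivities in `[1/N, 1]`.
#' @export
collectivity <- function(modes, k) {
  vapply(k, function(kk) {
    a <- mode_shape(modes, kk)
    p <- rowSums(a^2)
    p <- p / sum(p)
    nz <- p > 0
    exp(-sum(p[nz] * log(p[nz]))) / modes$n_sites
  }, 0)
}

#' Effective force constant between two residues
#'
#' Mechanical stiffness felt between sites `i` and `j`: the inverse of
#' the mode-summed compliance of their inter-site distance,
#' `kappa_ij = [ sum_k (1/lambda_k) ((a_k,j - a_k,i) . e_ij)^2 ]^-1`,
#' with `e_ij` the unit inter-site vector in the reference structure.
#' Requires a complete mode set (all non-zero modes): a truncated set
#' would silently overestimate stiffness, so it is refused.
#'
#' @param modes A complete `mode_set` (computed with `n_modes = "all"`).
#' @param i,j Distinct site indices.
#' @return Stiffness in gamma units (symmetric in i, j, positive).
#' @export
effective_force_constant <- function(modes, i, j) {
  stopifnot(inherits(modes, "mode_set"))
  if (!isTRUE(modes$complete))
    stop("mechanical stiffness requires all non-zero modes ",
         "(recompute with n_modes = \"all\")")
  if (i == j) stop("i and j must differ")
  xyz <- modes$model$xyz
  e <- xyz[j, ] - xyz[i, ]
  e <- e / sqrt(sum(e^2))
  ii <- (3L * i - 2L):(3L * i)
  jj <- (3L * j - 2L):(3L * j)
  rel <- t(modes$vectors[jj, , drop = FALSE] -
             modes$vectors[ii, , drop = FALSE]) %*% e
  1 / sum(as.numeric(rel)^2 / modes$values)
}

#' Per-residue mechanical stiffness profile
#'
#' Mean of the effective force constant `kappa_ij` over all partners
#' `j != i`, computed from the Hessian pseudo-inverse assembled from
#' the complete mode set (algebraically identical to averaging
#' [effective_force_constant()] over j, but O(N^2) instead of O(N^3)).
#'
#' @param modes A complete `mode_set`.
#' @return Positive numeric vector of length N (gamma units).
#' @export
residue_stiffness <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  if (!isTRUE(modes$complete))
    stop("mechanical stiffness requires all non-zero modes ",
         "(recompute with n_modes = \"all\")")
  n <- modes$n_sites
  xyz <- modes$model$xyz
  V <- modes$vectors
  G <- V %*% (t(V) / modes$values)     # pseudo-inverse of the Hessian
  ix <- seq(1L, 3L * n, 3L)
  ## per-site 3x3 diagonal blocks of G, as an N x 9 matrix (col-major 3x3)
  Bdiag <- matrix(0, n, 9L)
  for (a in 1:3) for (b in 1:3)
    Bdiag[, (b - 1L) * 3L + a] <- G[cbind(ix + a - 1L, ix + b - 1L)]
  stiff <- numeric(n)
  for (i in seq_len(n)) {
    E <- sweep(xyz, 2L, xyz[i, ])
    d <- sqrt(rowSums(E^2)); d[i] <- 1
    E <- E / d
    EE <- cbind(E[, 1L] * E[, 1L], E[, 2L] * E[, 1L], E[, 3L] * E[, 1L],
                E[, 1L] * E[, 2L], E[, 2L] * E[, 2L], E[, 3L] * E[, 2L],
                E[, 1L] * E[, 3L], E[, 2L] * E[, 3L], E[, 3L] * E[, 3L])
    ## e' G_ii e (scalar for this i), e' G_jj e, and e' G_ij e per j
    Gii <- matrix(Bdiag[i, ], 3L, 3L)
    t_ii <- rowSums((E %*% Gii) * E)
    t_jj <- rowSums(Bdiag * EE)
    Gi <- G[(3L * i - 2L):(3L * i), , drop = FALSE]   # 3 x 3N
    Gij9 <- matrix(0, n, 9L)
    for (a in 1:3) for (b in 1:3)
      Gij9[, (b - 1L) * 3L + a] <- Gi[a, ix + b - 1L]
    t_ij <- rowSums(Gij9 * EE)
    compliance <- t_ii + t_jj - 2 * t_ij
    kappa <- 1 / compliance[-i]
    stiff[i] <- mean(kappa)
  }
  stiff
}

#' Signed per-residue components of a mode along an axis
#'
#' Projection `c_i = a_k,i . axis` of each bead's mode-`k` displacement
#' onto a (unit) axis, typically the pulling axis.  For any non-zero
#' mode of a connected network the components sum to zero (the mode is
#' orthogonal to uniform translation).
#'
#' @param modes A `mode_set`.
#' @param k Non-zero mode index.
#' @param axis 3-vector (normalized internally).
#' @return Numeric vector of length N.
#' @export
axis_components <- function(modes, k, axis = c(0, 0, 1)) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  as.numeric(mode_shape(modes, k) %*% axis)
}

#' Mean axis component of a mode within each named domain
#'
#' @inheritParams axis_components
#' @param dm A [domain_map()].
#' @return Named numeric vector, one mean per domain.
#' @export
domain_mean_axis_displacement <- function(modes, k, dm,
                                          axis = c(0, 0, 1)) {
  stopifnot(inherits(dm, "domain_map"))
  ci <- axis_components(modes, k, axis)
  vapply(dm, function(idx) mean(ci[idx]), 0)
}

#' Criteria for selecting domain-separating modes
#'
#' Codifies the screening rule: examine the first `first_k` non-zero
#' modes plus the `top_collectivity` most collective of the first
#' `of_first`; keep candidates whose two domain-mean axis components
#' have opposite signs and whose separation `|mean_A - mean_B|` is at
#' least `min_separation` times the best candidate separation.
#'
#' @param first_k Low-frequency candidate pool size (default 10).
#' @param top_collectivity How many high-collectivity modes to add
#'   (default 10).
#' @param of_first Pool from which collectivity candidates are drawn
#'   (default 50).
#' @param opposite_sign_required Require opposite-sign domain means
#'   (default TRUE).
#' @param min_separation Relative separation threshold in `[0, 1]`
#'   (default 0.25).
#' @return An object of class `mode_selection_criteria`.
#' @export
mode_selection_criteria <- function(first_k = 10L, top_collectivity = 10L,
                                    of_first = 50L,
                                    opposite_sign_required = TRUE,
                                    min_separation = 0.25) {
  stopifnot(first_k >= 1L, top_collectivity >= 1L, of_first >= 1L,
            min_separation >= 0, min_separation <= 1)
  structure(list(first_k = as.integer(first_k),
                 top_collectivity = as.integer(top_collectivity),
                 of_first = as.integer(of_first),
                 opposite_sign_required = opposite_sign_required,
                 min_separation = min_separation),
            class = "mode_selection_criteria")
}

#' Select modes that separate two domains along the pulling axis
#'
#' Identifies candidate modes that move the two domains in opposite
#' directions along the applied-force axis -- the modes expected to be
#' amplified by the pulling force -- ranked by the magnitude of the
#' domain-mean separation (ties broken by lower mode index).  The full
#' per-candidate report is always returned so the automated choice can
#' be overridden by inspection.
#'
#' @param modes A `mode_set`.
#' @param dm A two-domain [domain_map()].
#' @param axis Pulling axis (default +z).
#' @param criteria A [mode_selection_criteria()].
#' @return An object of class `mode_selection`: list with `selected`
#'   (ranked non-zero mode indices, possibly empty) and `report` (data
#'   frame with columns `mode`, `eigenvalue`, `collectivity`,
#'   `mean_<domainA>`, `mean_<domainB>`, `separation`, `opposite`,
#'   `selected`).
#' @export
select_separating_modes <- function(modes, dm, axis = c(0, 0, 1),
                                    criteria = mode_selection_criteria()) {
  stopifnot(inherits(modes, "mode_set"), inherits(dm, "domain_map"))
  if (length(dm) != 2L)
    stop("mode selection needs exactly 2 domains, got ", length(dm))
  k_avail <- length(modes$values)
  pool1 <- seq_len(min(criteria$first_k, k_avail))
  pool2_base <- seq_len(min(criteria$of_first, k_avail))
  coll <- collectivity(modes, pool2_base)
  pool2 <- pool2_base[order(-coll)][
    seq_len(min(criteria$top_collectivity, length(pool2_base)))]
  cand <- sort(union(pool1, pool2))
  means <- t(vapply(cand, function(k)
    domain_mean_axis_displacement(modes, k, dm, axis), numeric(2L)))
  sep <- abs(means[, 1L] - means[, 2L])
  opp <- means[, 1L] * means[, 2L] < 0
  pass <- if (criteria$opposite_sign_required) opp else rep(TRUE, length(cand))
  max_sep <- if (any(pass)) max(sep[pass]) else NA_real_
  sel <- pass & !is.na(max_sep) & sep >= criteria$min_separation * max_sep
  report <- data.frame(
    mode = cand,
    eigenvalue = modes$values[cand],
    collectivity = coll[match(cand, pool2_base)],
    mean_a = means[, 1L],
    mean_b = means[, 2L],
    separation = sep,
    opposite = opp,
    selected = sel)
  miss <- is.na(report$collectivity)
  if (any(miss)) report$collectivity[miss] <- collectivity(modes, cand[miss])
  names(report)[4:5] <- paste0("mean_", names(dm))
  ranked <- cand[sel][order(-sep[sel], cand[sel])]
  structure(list(selected = ranked, report = report,
                 domains = names(dm), criteria = criteria),
            class = "mode_selection")
}

#' @export
print.mode_selection <- function(x, ...) {
  cat("<mode_selection> domains ", paste(x$domains, collapse = " vs "),
      "; selected modes: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n", sep = "")
  print(x$report, digits = 4)
  invisible(x)
}
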