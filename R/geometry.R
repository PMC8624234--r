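#' Raw coordinate RMSD
#'
#' Root-mean-square deviation between two conformations of the same
#' sites, with no superposition (use [kabsch_superpose()] first if a
#' best-fit RMSD is wanted).  This is the quantity that target-RMSD
#' deformation controls.
#'
#' @param x,y N x 3 coordinate matrices (or `coarse_model` objects).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(x, y) {
  x <- as_xyz(x); y <- as_xyz(y)
  if (!identical(dim(x), dim(y)))
    stop("coordinate sets differ in shape")
  sqrt(mean(rowSums((x - y)^2)))
}

as_xyz <- function(x) {
  if (inherits(x, "coarse_model")) return(x$xyz)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an N x 3 coordinate matrix")
  storage.mode(x) <- "double"
  x
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' `mobile` onto `reference` (SVD solution with reflection correction).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3 and not
#'   collinear.
#' @return A list with `transform` (a `rigid_transform`: 3 x 3 rotation
#'   `rotation` with det +1 and length-3 `translation`, mapping
#'   `x -> rotation %*% x + translation`), `rmsd_after`, and `fitted`
#'   (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  X <- as_xyz(mobile); Y <- as_xyz(reference)
  if (!identical(dim(X), dim(Y))) stop("coordinate sets differ in shape")
  if (nrow(X) < 3L) stop("need at least 3 sites for superposition")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  sv_x <- svd(Xc)$d
  if (sv_x[2L] < 1e-8 * max(sv_x[1L], 1e-12))
    stop("degenerate (collinear) coordinates: superposition undefined")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(my - R %*% mx)
  fitted <- tcrossprod(X, R) + matrix(tr, nrow(X), 3L, byrow = TRUE)
  structure(list(
    transform = rigid_transform(R, tr),
    rmsd_after = rmsd(fitted, Y),
    fitted = fitted), class = "kabsch_fit")
}

rigid_transform <- function(rotation, translation) {
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("improper rotation (det != +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

apply_transform <- function(xyz, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  tcrossprod(as_xyz(xyz), tf$rotation) +
    matrix(tf$translation, nrow(xyz), 3L, byrow = TRUE)
}

#' Pulling geometry: tether attachment points and target axis
#'
#' In an optical-trap experiment the force acts along the line joining
#' the two tether attachment residues.  Attachments are modelled at the
#' C-alpha beads of the named residues.
#'
#' @param attach_a,attach_b Residue identifiers, either `"A:16"` strings
#'   or `list(chain_id=, residue_seq=)`.
#' @param target_axis Unit 3-vector the pulling direction is rotated
#'   onto (default +z, the convention used throughout the analyses).
#' @return An object of class `pulling_geometry`.
#' @export
pulling_geometry <- function(attach_a, attach_b,
                             target_axis = c(0, 0, 1)) {
  pa <- parse_residue_id(attach_a)
  pb <- parse_residue_id(attach_b)
  if (identical(pa, pb)) stop("attachment residues must differ")
  target_axis <- as.numeric(target_axis)
  nrm <- sqrt(sum(target_axis^2))
  if (nrm < 1e-12) stop("target_axis must be non-zero")
  structure(list(attach_a = pa, attach_b = pb,
                 target_axis = target_axis / nrm),
            class = "pulling_geometry")
}

parse_residue_id <- function(id) {
  if (is.list(id)) {
    stopifnot(all(c("chain_id", "residue_seq") %in% names(id)))
    return(list(chain_id = as.character(id$chain_id),
                residue_seq = as.integer(id$residue_seq)))
  }
  parts <- strsplit(as.character(id), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || is.na(suppressWarnings(as.integer(parts[2L]))))
    stop("malformed residue id '", id, "' (expected \"chain:resno\")")
  list(chain_id = parts[1L], residue_seq = as.integer(parts[2L]))
}

resolve_residue <- function(model, id) {
  i <- which(model$chain_id == id$chain_id &
               model$residue_seq == id$residue_seq)
  if (length(i) != 1L)
    stop("residue ", id$chain_id, ":", id$residue_seq,
         if (!length(i)) " not found in model" else " is ambiguous")
  i
}

## minimal rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  a <- crossprod_vec(u, v)
  c_ <- sum(u * v)
  if (c_ < -1 + 1e-12) {
    ## antiparallel: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- crossprod_vec(u, p); ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0),
              3L, 3L)
  diag(3) + K + K %*% K / (1 + c_)
}

crossprod_vec <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotate a model so the pulling direction lies along the target axis
#'
#' Rigidly rotates the structure so that the unit vector from attachment
#' residue A to attachment residue B coincides with the target axis
#' (exactly, not just roughly), and moves the centroid to the origin.
#' Spin about the pulling axis is left free; all internal geometry (and
#' hence the elastic network and its modes) is unchanged.
#'
#' @param model A [coarse_model()].
#' @param pull A [pulling_geometry()].
#' @return A list with `model` (the aligned [coarse_model()]) and
#'   `transform` (the `rigid_transform` that was applied).
#' @export
align_pulling_axis <- function(model, pull) {
  stopifnot(inherits(model, "coarse_model"),
            inherits(pull, "pulling_geometry"))
  ia <- resolve_residue(model, pull$attach_a)
  ib <- resolve_residue(model, pull$attach_b)
  v <- model$xyz[ib, ] - model$xyz[ia, ]
  d <- sqrt(sum(v^2))
  if (d < 1e-6)
    stop("attachment residues are coincident in space")
  R <- rotation_between(v / d, pull$target_axis)
  rotated <- tcrossprod(model$xyz, R)
  ctr <- colMeans(rotated)
  tf <- rigid_transform(R, -ctr)
  out <- model
  out$xyz <- sweep(rotated, 2L, ctr)
  list(model = out, transform = tf)
}
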