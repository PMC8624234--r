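#' Analytic two-bead dimer
#'
#' The minimal elastic network: two beads joined by one spring.  Its
#' mechanics are known in closed form (single non-zero eigenvalue
#' `2 * gamma`, five zero modes, pair stiffness `gamma`), which makes
#' it the oracle fixture for the mode machinery.
#'
#' @param d0 Bead separation in Angstrom (default 3.8, one virtual
#'   C-alpha bond).
#' @return A 2-bead [coarse_model()] along the x-axis.
#' @export
make_dimer <- function(d0 = 3.8) {
  if (d0 <= 0) stop("d0 must be positive")
  coarse_model(rbind(c(0, 0, 0), c(d0, 0, 0)),
               residue_name = c("ALA", "ALA"),
               chain_id = c("A", "A"), residue_seq = 1:2,
               source_label = sprintf("synthetic dimer d0=%g", d0))
}

#' Ideal alpha-helix C-alpha trace
#'
#' Canonical helix geometry: rise 1.5 Angstrom and rotation 100
#' degrees per residue on a 2.3 Angstrom radius, which reproduces the
#' ~3.8 Angstrom consecutive C-alpha distance.  Poly-alanine labels.
#'
#' @param n_residues Number of residues (>= 4).
#' @return A [coarse_model()].
#' @export
make_helix <- function(n_residues) {
  if (n_residues < 4L) stop("need at least 4 residues")
  i <- seq_len(n_residues) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  coarse_model(xyz, residue_name = rep("ALA", n_residues),
               chain_id = rep("A", n_residues),
               residue_seq = seq_len(n_residues),
               source_label = sprintf("synthetic helix n=%d", n_residues))
}

## rejection-sample n points uniformly in a sphere of radius r with a
## minimum pairwise distance constraint
sample_lobe <- function(n, r, min_dist = 3.4, max_tries = 20000L) {
  pts <- matrix(0, 0L, 3L)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot pack ", n, " beads at min distance ", min_dist,
           " into a sphere of radius ", r)
    p <- stats::runif(3L, -r, r)
    if (sum(p^2) > r^2) next
    if (nrow(pts) &&
        min(rowSums(sweep(pts, 2L, p)^2)) < min_dist^2) next
    pts <- rbind(pts, p)
  }
  pts
}

#' Two-lobe dumbbell with controllable packing asymmetry
#'
#' A controlled surrogate for a two-domain protein: two quasi-spherical
#' bead clusters joined by a linear linker along x, with tether
#' attachment points at the two outermost beads.  A larger packing
#' radius for one lobe at equal bead count makes that lobe looser --
#' measurably lower buried volume and stiffness -- giving a
#' known-answer system for separating-mode selection and integrity
#' ranking.
#'
#' @param n_per_lobe Beads per lobe (>= 4, default 24).
#' @param lobe_radius_a,lobe_radius_b Packing sphere radius of each
#'   lobe, Angstrom (default 8; smaller = denser).
#' @param linker_beads Beads in the connecting linker (default 3).
#' @param separation Distance between lobe centres, Angstrom (default
#'   30; must exceed the two packing radii combined).
#' @param seed RNG seed; the same seed reproduces the model exactly.
#' @param min_dist Minimum inter-bead distance, Angstrom (default 3.4).
#' @return A list with `model` ([coarse_model()]), `domains`
#'   ([domain_map()] with entries `lobeA`, `lobeB`; linker beads belong
#'   to neither), and `pulling` ([pulling_geometry()] attached at the
#'   outermost bead of each lobe).
#' @export
make_dumbbell <- function(n_per_lobe = 24L, lobe_radius_a = 8,
                          lobe_radius_b = 8, linker_beads = 3L,
                          separation = 30, seed = 1L, min_dist = 3.4) {
  if (n_per_lobe < 4L) stop("n_per_lobe must be at least 4")
  if (separation <= lobe_radius_a + lobe_radius_b)
    stop("separation must exceed the sum of the lobe radii")
  for (attempt in 0:9) {
    xyz <- with_seed(seed + 1000L * attempt, {
      a <- sweep(sample_lobe(n_per_lobe, lobe_radius_a, min_dist), 2L,
                 c(-separation / 2, 0, 0), `+`)
      b <- sweep(sample_lobe(n_per_lobe, lobe_radius_b, min_dist), 2L,
                 c(separation / 2, 0, 0), `+`)
      x0 <- -separation / 2 + lobe_radius_a
      x1 <- separation / 2 - lobe_radius_b
      lx <- seq(x0, x1, length.out = linker_beads + 2L)
      lx <- lx[-c(1L, linker_beads + 2L)]
      ## zig-zag offset off the x-axis in both y and z: an exactly
      ## collinear linker would leave lobe torsion about x as a
      ## zero-energy mechanism, and a planar one would brace it weakly
      phi <- seq_along(lx) * 2.4
      lnk <- cbind(lx, 1.5 * cos(phi), 1.5 * sin(phi))
      rbind(a, lnk, b)
    })
    ## reject constructions with near-coincident beads across groups
    if (min(stats::dist(xyz)) < 1) next
    n <- nrow(xyz)
    model <- coarse_model(
      xyz, residue_name = rep("ALA", n), chain_id = rep("A", n),
      residue_seq = seq_len(n),
      source_label = sprintf("synthetic dumbbell seed=%d", seed))
    cp <- contact_pairs(xyz, enm_params()$cutoff_rc)
    if (max(graph_components(n, cp$i, cp$j)) > 1L) next
    ia <- which.min(xyz[, 1L])
    ib <- which.max(xyz[, 1L])
    dm <- domain_map(model,
                     lobeA = seq_len(n_per_lobe),
                     lobeB = (n_per_lobe + linker_beads + 1L):n)
    pull <- pulling_geometry(
      list(chain_id = "A", residue_seq = model$residue_seq[ia]),
      list(chain_id = "A", residue_seq = model$residue_seq[ib]))
    return(list(model = model, domains = dm, pulling = pull))
  }
  stop("failed to generate a connected, non-overlapping dumbbell")
}
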