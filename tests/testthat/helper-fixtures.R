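## shared helpers for the test suite; all fixtures are generated in code

## random proper rotation matrix (QR of a Gaussian matrix, det fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## hand-assembled mode_set with prescribed eigenvalues/eigenvectors,
## for operations whose contracts are defined on arbitrary orthonormal
## mode vectors (collectivity, axis components, sampling statistics)
fake_modes <- function(values, vectors, xyz = NULL) {
  n <- nrow(vectors) / 3L
  if (is.null(xyz)) xyz <- matrix(seq_len(3L * n) * 3.8, n, 3L)
  model <- coarse_model(xyz, rep("ALA", n), rep("A", n), seq_len(n))
  structure(list(values = values, vectors = vectors,
                 n_zero_modes = 6L, n_sites = n,
                 complete = FALSE, params = NULL, model = model),
            class = "mode_set")
}

## a small bent trimer whose 1-3 pair is outside the cutoff: two
## springs in series along x (cutoff 5 excludes the 7.6 A 1-3 pair)
make_trimer <- function(d = 3.8) {
  coarse_model(rbind(c(0, 0, 0), c(d, 0, 0), c(2 * d, 0, 0)),
               rep("ALA", 3), rep("A", 3), 1:3)
}

## canonical asymmetric dumbbell used across tests: lobe B 30% looser
loose_dumbbell <- function(seed = 1L)
  make_dumbbell(lobe_radius_a = 8, lobe_radius_b = 8 * 1.3, seed = seed)

## write a small hand-crafted multi-atom PDB text file; returns path
write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, record = "ATOM", alt = " ",
                          elem = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, b, elem)
}

expect_connected_modes <- function(model, ...) {
  modes <- enm_modes(model, ...)
  expect_identical(modes$n_zero_modes, 6L)
  modes
}
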