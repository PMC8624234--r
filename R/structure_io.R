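#' Read a PDB file into a structure of atom records
#'
#' Parses a fixed-column PDB file (ATOM/HETATM, MODEL/ENDMDL honoured) into
#' an atom table plus per-model coordinates.  Alternate locations are
#' resolved by keeping the highest-occupancy conformer of each atom
#' (ties: first encountered), the standard single-conformer convention.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_structure`: a list with elements
#'   `atoms` (data frame with columns `serial`, `record`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_seq`, `insertion_code`,
#'   `occupancy`, `b_factor`, `element`), `xyz` (numeric matrix,
#'   one row per model, 3 columns per atom in `x1,y1,z1,x2,...` order)
#'   and `n_models`.
#' @seealso [extract_ca()], [write_coarse_pdb()]
#' @export
read_pdb <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path")
  if (!file.exists(path))
    stop("PDB file not found: '", path, "'")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom
  if (!any(atoms$type == "ATOM"))
    stop("no ATOM records in '", path, "'")

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)

  ## resolve altlocs: within each (chain, resno, icode, atom name) group
  ## keep the highest-occupancy record; ties go to the first encountered
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               atoms$type, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(atoms)))
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  if (length(keep) < nrow(atoms)) {
    atoms <- atoms[keep, , drop = FALSE]
    xyz <- xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
               drop = FALSE]
  }

  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  out <- data.frame(
    serial = atoms$eleno,
    record = atoms$type,
    atom_name = atoms$elety,
    residue_name = atoms$resid,
    chain_id = ifelse(is.na(atoms$chain), " ", atoms$chain),
    residue_seq = atoms$resno,
    insertion_code = ins,
    occupancy = atoms$o,
    b_factor = atoms$b,
    element = ifelse(is.na(atoms$elesy), "", atoms$elesy),
    stringsAsFactors = FALSE)
  bad <- !is.finite(xyz[1L, as.vector(rbind(seq_len(nrow(out)) * 3 - 2,
                                            seq_len(nrow(out)) * 3 - 1,
                                            seq_len(nrow(out)) * 3))])
  if (any(bad))
    stop("non-finite coordinates in '", path, "'")
  structure(list(atoms = out, xyz = xyz, n_models = nrow(xyz),
                 source = path),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", nrow(x$atoms), " atoms, ", x$n_models,
      " model(s), source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Construct a C-alpha coarse model
#'
#' One bead per residue.  This is the container on which the elastic
#' network, deformation and burial machinery operates.
#'
#' @param xyz N x 3 numeric matrix of coordinates (Angstrom).
#' @param residue_name Character vector of 3-letter residue codes.
#' @param chain_id Character vector of 1-character chain identifiers.
#' @param residue_seq Integer vector of author residue numbers.
#' @param insertion_code Character vector of insertion codes ("" if none).
#' @param source_label Free-text provenance string.
#' @return An object of class `coarse_model` with fields `xyz`,
#'   `residue_name`, `chain_id`, `residue_seq`, `insertion_code`,
#'   `source_label` and `n_sites`.
#' @export
coarse_model <- function(xyz, residue_name, chain_id, residue_seq,
                         insertion_code = rep("", nrow(xyz)),
                         source_label = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (n < 2L) stop("a coarse model needs at least 2 sites")
  if (ncol(xyz) != 3L) stop("'xyz' must be an N x 3 matrix")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  residue_name <- as.character(residue_name)
  chain_id <- as.character(chain_id)
  residue_seq <- as.integer(residue_seq)
  insertion_code <- as.character(insertion_code)
  stopifnot(length(residue_name) == n, length(chain_id) == n,
            length(residue_seq) == n, length(insertion_code) == n)
  ids <- paste(chain_id, residue_seq, insertion_code, sep = "\r")
  if (anyDuplicated(ids))
    stop("duplicate residue identifiers in coarse model")
  if (anyDuplicated(xyz, MARGIN = 1))
    stop("coincident bead coordinates in coarse model")
  structure(list(n_sites = n, xyz = xyz, residue_name = residue_name,
                 chain_id = chain_id, residue_seq = residue_seq,
                 insertion_code = insertion_code,
                 source_label = source_label),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat("<coarse_model> ", x$n_sites, " C-alpha beads, chains: ",
      paste(unique(x$chain_id), collapse = ","),
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Extract a C-alpha coarse model from a parsed structure
#'
#' Takes exactly one bead per residue possessing a CA atom, in
#' chain-then-sequence order.  Residues lacking a CA atom are skipped
#' with a warning.  HETATM records are excluded unless
#' `keep_hetatm = TRUE`, in which case HETATM residues possessing a CA
#' atom are retained as beads.
#'
#' @param structure A `pdb_structure` from [read_pdb()].
#' @param chains Optional character vector of chain identifiers to keep.
#' @param model_index Which model to take coordinates from (default 1).
#' @param keep_hetatm Retain HETATM residues that have a CA atom.
#' @return A [coarse_model()].
#' @export
extract_ca <- function(structure, chains = NULL, model_index = 1L,
                       keep_hetatm = FALSE) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (model_index < 1L || model_index > structure$n_models)
    stop("model_index ", model_index, " out of range (structure has ",
         structure$n_models, " models)")
  at <- structure$atoms
  sel <- at$record == "ATOM"
  if (keep_hetatm) sel <- sel | at$record == "HETATM"
  if (!is.null(chains)) sel <- sel & at$chain_id %in% chains
  res_key <- paste(at$chain_id, at$residue_seq, at$insertion_code,
                   sep = "\r")
  is_ca <- sel & at$atom_name == "CA"
  no_ca <- setdiff(unique(res_key[sel]), unique(res_key[is_ca]))
  if (length(no_ca))
    warning(length(no_ca), " residue(s) without a CA atom skipped")
  idx <- which(is_ca)
  if (!length(idx))
    stop("no CA atoms after filtering",
         if (!is.null(chains)) paste0(" (chains ",
                                      paste(chains, collapse = ","), ")"))
  idx <- idx[order(at$chain_id[idx], at$residue_seq[idx],
                   at$insertion_code[idx])]
  xyz <- matrix(structure$xyz[model_index,
                              as.vector(rbind(3 * idx - 2, 3 * idx - 1,
                                              3 * idx))],
                ncol = 3L, byrow = TRUE)
  coarse_model(xyz,
               residue_name = at$residue_name[idx],
               chain_id = at$chain_id[idx],
               residue_seq = at$residue_seq[idx],
               insertion_code = at$insertion_code[idx],
               source_label = paste0(structure$source, " model ",
                                     model_index))
}

#' Residue-range selection
#'
#' Inclusive residue ranges in author numbering, used for truncations
#' (e.g. removing a C-terminal tail) or sub-domain extraction.  Ranges
#' may be given as strings `"A:530-554"` (chain:first-last) or
#' `"A:159"` (single residue).
#'
#' @param ranges Character vector of `"chain:first-last"` strings, or a
#'   data frame with columns `chain_id`, `first_seq`, `last_seq`.
#' @param mode `"keep"` or `"remove"`.
#' @return An object of class `residue_selection`.
#' @export
residue_selection <- function(ranges, mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  if (is.character(ranges)) ranges <- parse_ranges(ranges)
  stopifnot(is.data.frame(ranges),
            all(c("chain_id", "first_seq", "last_seq") %in% names(ranges)))
  if (any(ranges$first_seq > ranges$last_seq))
    stop("range with first_seq > last_seq")
  structure(list(ranges = ranges, mode = mode),
            class = "residue_selection")
}

parse_ranges <- function(strings) {
  parts <- strsplit(strings, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed range '", strings[bad][1L],
                     "' (expected \"chain:first-last\")")
  chain <- vapply(parts, `[[`, "", 1L)
  span <- vapply(parts, `[[`, "", 2L)
  lims <- lapply(strsplit(span, "-", fixed = TRUE), as.integer)
  if (any(vapply(lims, function(x) any(is.na(x)) || !length(x) %in% 1:2,
                 TRUE)))
    stop("malformed residue span in range specification")
  data.frame(chain_id = chain,
             first_seq = vapply(lims, `[[`, 0L, 1L),
             last_seq = vapply(lims, function(x) x[[length(x)]], 0L),
             stringsAsFactors = FALSE)
}

#' Apply a residue-range selection to a coarse model
#'
#' @param model A [coarse_model()].
#' @param sel A [residue_selection()].  Every range must overlap the
#'   model's residue numbering; a range that selects nothing is an
#'   error, not a silent no-op.
#' @return The selected/truncated [coarse_model()], order preserved.
#' @export
apply_selection <- function(model, sel) {
  stopifnot(inherits(model, "coarse_model"),
            inherits(sel, "residue_selection"))
  hit <- rep(FALSE, model$n_sites)
  for (r in seq_len(nrow(sel$ranges))) {
    rng <- sel$ranges[r, ]
    if (!any(model$chain_id == rng$chain_id))
      stop("selection references absent chain '", rng$chain_id, "'")
    m <- model$chain_id == rng$chain_id &
      model$residue_seq >= rng$first_seq &
      model$residue_seq <= rng$last_seq
    if (!any(m))
      stop("range ", rng$chain_id, ":", rng$first_seq, "-", rng$last_seq,
           " matches no residue in the model")
    hit <- hit | m
  }
  keep <- if (sel$mode == "keep") hit else !hit
  if (sum(keep) < 2L)
    stop("selection leaves fewer than 2 beads")
  coarse_model(model$xyz[keep, , drop = FALSE],
               model$residue_name[keep], model$chain_id[keep],
               model$residue_seq[keep], model$insertion_code[keep],
               source_label = model$source_label)
}

#' Write a coarse model or deformed ensemble as a PDB file
#'
#' One CA ATOM line per bead; a [deformed_ensemble] is written as a
#' MODEL/ENDMDL multi-model trajectory.  Round-trips through
#' [read_pdb()] + [extract_ca()] to the 3-decimal coordinate precision
#' of the format.
#'
#' @param x A [coarse_model()] or a [sample_ensemble()] /
#'   [pseudo_trajectory()] result.
#' @param path Output file path.
#' @param b_factor Optional per-bead numeric vector written to the
#'   B-factor column (e.g. buried flags); default 0.
#' @return `path`, invisibly.
#' @export
write_coarse_pdb <- function(x, path, b_factor = NULL) {
  if (inherits(x, "deformed_ensemble")) {
    ref <- x$reference
    frames <- x$frames
  } else if (inherits(x, "coarse_model")) {
    ref <- x
    frames <- array(x$xyz, dim = c(1L, nrow(x$xyz), 3L))
  } else stop("cannot write object of class ", class(x)[1L])
  n <- ref$n_sites
  if (is.null(b_factor)) b_factor <- rep(0, n)
  stopifnot(length(b_factor) == n)
  multi <- dim(frames)[1L] > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(dim(frames)[1L])) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), ref$residue_name,
      substr(paste0(ref$chain_id, " "), 1, 1), ref$residue_seq,
      substr(paste0(ref$insertion_code, " "), 1, 1),
      frames[m, , 1L], frames[m, , 2L], frames[m, , 3L],
      1, b_factor)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a CA-only PDB back into a coarse model
#'
#' Convenience wrapper: [read_pdb()] followed by [extract_ca()].
#' @inheritParams extract_ca
#' @param path PDB file path.
#' @return A [coarse_model()].
#' @export
read_coarse_pdb <- function(path, chains = NULL, model_index = 1L) {
  extract_ca(read_pdb(path), chains = chains, model_index = model_index)
}
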