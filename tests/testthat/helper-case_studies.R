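## Case-study structures (T4 lysozyme wild-type/CP13, DnaK NBD/SBD,
## glucocorticoid-receptor LBD).  These are real PDB entries that are
## not redistributed with the package; scripts/fetch_structures.R
## materializes C-alpha extracts under inst/extdata/pdb/ for users
## with network access.  The analyses below run whenever the files
## exist and error otherwise.

case_study_model <- function(id, chains = "A") {
  path <- system.file("extdata", "pdb", paste0(id, "_ca.pdb"),
                      package = "fsnma")
  if (!nzchar(path) || !file.exists(path))
    stop("case-study structure ", id, " is not available: run ",
         "scripts/fetch_structures.R (requires network access) and ",
         "reinstall the package", call. = FALSE)
  read_coarse_pdb(path, chains = chains)
}

## T4 lysozyme: tethered at residues 16 and 159; NTD/CTD split with
## the N-terminal helix A (1-12) counted with the CTD
t4l_domains <- function()
  list(NTD = "A:13-65", CTD = c("A:1-12", "A:66-164"))
t4l_pulling <- function() pulling_geometry("A:16", "A:159")

## DnaK nucleotide-binding domain: residues 1-392 construct, "tailless"
## removes the C-terminal 23 residues; lobe I / lobe II partition at
## the customary 1-185 / 186-383 boundary
nbd_extract <- function(model, tailless = TRUE) {
  last <- max(model$residue_seq[model$residue_seq <= 392])
  m <- apply_selection(model, residue_selection(
    sprintf("A:%d-%d", last + 1L, max(model$residue_seq)), "remove"))
  if (tailless)
    m <- apply_selection(m, residue_selection(
      sprintf("A:%d-%d", last - 22L, last), "remove"))
  m
}
nbd_domains <- function() list(lobeI = "A:1-185", lobeII = "A:186-383")
nbd_pulling <- function(model)
  pulling_geometry(sprintf("A:%d", min(model$residue_seq)),
                   sprintf("A:%d", max(model$residue_seq)))

## DnaK substrate-binding domain: beta 393-507, alpha 508-603
sbd_extract <- function(model, part = c("both", "beta", "alpha")) {
  part <- match.arg(part)
  rng <- switch(part, both = "A:393-603", beta = "A:393-507",
                alpha = "A:508-603")
  apply_selection(model, residue_selection(rng, "keep"))
}

## GCR ligand-binding domain segments (author numbering of 1M2Z);
## the hyper-mobile first 8 N-terminal residues are excluded
gcr_segments <- function()
  list(NT1 = c(530L, 554L), NT2 = c(555L, 582L),
       CT2 = c(735L, 767L), CT1 = c(768L, 777L))

seg_mean <- function(values, model, lo, hi)
  mean(values[model$residue_seq >= lo & model$residue_seq <= hi])
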