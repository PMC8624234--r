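#!/usr/bin/env Rscript
## Download the case-study PDB entries from RCSB and store compact
## C-alpha extracts under inst/extdata/pdb/, where the case-study
## tests expect them.  Requires network access; re-install the
## package afterwards so system.file() can find the files.
##
##   Rscript scripts/fetch_structures.R

suppressPackageStartupMessages(library(fsnma))

entries <- list(
  `2lzm` = "A",   # T4 lysozyme wild-type
  `2o4w` = "A",   # T4 lysozyme circular permutant CP13
  `2kho` = "A",   # DnaK, ADP/substrate state (NMR)
  `4b9q` = "A",   # DnaK, ATP state (crystal)
  `1m2z` = "A")   # glucocorticoid receptor LBD + dexamethasone

dest_dir <- file.path("inst", "extdata", "pdb")
dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)

for (id in names(entries)) {
  dest <- file.path(dest_dir, paste0(id, "_ca.pdb"))
  if (file.exists(dest)) { cat(id, "already present\n"); next }
  raw <- tempfile(fileext = ".pdb")
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  download.file(url, raw, quiet = TRUE)
  model <- extract_ca(read_pdb(raw), chains = entries[[id]])
  write_coarse_pdb(model, dest)
  cat(id, ": ", model$n_sites, " C-alpha beads -> ", dest, "\n", sep = "")
}
cat("done; re-install the package to expose the files via system.file()\n")
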