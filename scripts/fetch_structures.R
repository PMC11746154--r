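#!/usr/bin/env Rscript
# Downloads the deposited structures analysed by the real-structure
# acceptance checks into structures/ at the repository root (network
# required; the package itself never fetches anything).
#
# Usage: Rscript scripts/fetch_structures.R [dest_dir]

args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args)) args[1] else "structures"
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

accessions <- c("8uru", "8urq", "2zbk", "2q2e", "1d3y")
for (acc in accessions) {
  out <- file.path(dest, paste0(acc, ".cif"))
  if (file.exists(out)) {
    cat(acc, "already cached\n")
    next
  }
  url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(acc))
  ok <- tryCatch({
    utils::download.file(url, out, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    unlink(out)
    cat("FAILED:", acc, "(", url, ")\n")
  } else cat("fetched", acc, "\n")
}

cat("\nNote: the Topo VI-templated dimer check additionally needs the",
    "curated Spo11/Top6A residue-pair table at",
    file.path(dest, "spo11_top6a_mapping.tsv"),
    "(TSV columns: part, complex_chain, complex_resno, template_resno,",
    "elety); see ?build_topo6_templated_dimer.\n")
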