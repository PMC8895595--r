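#!/usr/bin/env Rscript
# One-time, network-requiring helper: fetch the UniProt sequences of the
# packaged candidate manifest and store them as a plain-text FASTA fixture
# used by the optional accession-dependent checks.
#
#   Rscript scripts/fetch_table1.R [out.fasta]
#
# Default output: inst/extdata/table1_sequences.fasta (re-install the
# package afterwards so system.file() can see it). The library itself never
# touches the network.

suppressMessages(library(depositcomp))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else
  file.path("inst", "extdata", "table1_sequences.fasta")

manifest <- load_table1_manifest()
records <- list()
for (i in seq_len(nrow(manifest))) {
  acc <- manifest$accession[i]
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc)
  message("fetching ", acc, " ...")
  lines <- tryCatch(readLines(url, warn = FALSE),
                    error = function(e) stop("fetch failed for ", acc, ": ",
                                             conditionMessage(e)))
  seq <- paste(lines[-1], collapse = "")
  records[[acc]] <- protein_record(acc, seq,
                                   description = manifest$description[i])
}
write_fasta(records, out)
message("wrote ", length(records), " sequences to ", out)
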