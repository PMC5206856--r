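#!/usr/bin/env Rscript
# Apply the three-criteria filter (stability rank, hydrophobic->charged
# replacement, oligomer-contact breaking at positions 6/15) to the
# printed ranked mutants and, when available, to this package's own
# landscape-derived ranking.

suppressPackageStartupMessages(library(httscan))
dir.create("results", showWarnings = FALSE)

crit <- selection_criteria()
report <- select_candidates(table1(), crit)
write_selection_report(report, "results/selection_table1.tsv")

hydro <- report$id[report$flag_hydrophobic_replacement]
cat("hydrophobic->charged replacements:", paste(hydro, collapse = " "), "\n")
winners <- report$id[report$passes_all]
cat("combinations passing all three criteria:",
    paste(winners, collapse = " "), "\n")
m16 <- report[report$id == "M16", ]
cat("M16 (L4K E12K K15E): hydrophobic", m16$flag_hydrophobic_replacement,
    "| contact-break", m16$flag_contact_break,
    "| passes all", m16$passes_all, "\n")

if (file.exists("results/top20_3point.tsv")) {
  ranked <- read.delim("results/top20_3point.tsv")
  own <- select_candidates(ranked, crit)
  write_selection_report(own, "results/selection_own_landscape.tsv")
  cat("own-landscape candidates passing all criteria:",
      sum(own$passes_all), "of", nrow(own), "\n")
}
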