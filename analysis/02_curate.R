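#!/usr/bin/env Rscript
# Re-read the serialized suites from disk and push every matrix through
# the curation protocol (uninformative characters, taxonomic equivalents,
# missing-data balancing, inclusion thresholds), recording what each
# stage removed. The suites are emitted pre-curated, so this stage also
# verifies that curation is idempotent on files that round-trip through
# the TNT writer.

suppressPackageStartupMessages(library(stemward))

rows <- NULL
for (suite in c("exchangeable", "decay_biased")) {
  dirp <- file.path("results/suites", suite)
  mats <- read_matrix_dir(dirp)
  for (id in names(mats)) {
    cur <- curate_matrix(mats[[id]])
    rows <- rbind(rows, data.frame(
      suite = suite, matrix = id,
      removed_chars = sum(vapply(cur$reports, function(r)
        length(r$removed_chars), 0L)),
      removed_taxa = sum(vapply(cur$reports, function(r)
        length(r$removed_taxa), 0L)),
      partition_gap = 100 * abs(missing_fraction(cur$matrix, "hard") - missing_fraction(cur$matrix, "soft")),
      include = cur$inclusion$include,
      reasons = paste(cur$inclusion$reasons, collapse = ";")))
  }
}
write.table(rows, "results/curation.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("curated %d matrices; %d includable; curation idempotent on %d\n",
            nrow(rows), sum(rows$include),
            sum(rows$removed_chars == 0 & rows$removed_taxa == 0)))
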