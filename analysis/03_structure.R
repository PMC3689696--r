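#!/usr/bin/env Rscript
# Secondary-structure context of the variable sites: stem/loop roles under
# the bundled hairpin model, wobble/compensatory/disruptive classification,
# compensatory typing of every clone and consensus record, and intact-pair
# counts for the diagnostic stem positions. Also folds the two hairpin
# windows of each clone with the base-pair maximizer and exports
# dot-bracket strings. Writes results/03_structure/.

suppressPackageStartupMessages(library(ribohet))
out <- "results/03_structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- reconstruct_fixture_alignment(include_consensus = TRUE)
grouping <- fixture_grouping()
clones <- names(grouping)
caln <- rd_alignment(aln$seqs[clones], 1L)
sites <- profile_variable_sites(caln, grouping)

eff <- structural_effects(fixture_pair_table(), sites, caln)
write.table(eff, file.path(out, "structure_effects.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("structural effects of the variable sites:\n")
print(table(eff$effect))

ct <- compensatory_type_table(aln, consensus_ids = c("AJ745110", "AJ745108",
                                                     "AF360542"))
write.table(ct, file.path(out, "compensatory_types.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("compensatory types (VR1 / VR2) per clone:\n")
print(table(ct$region, ct$type_label))

pi <- clone_pairing_integrity(caln)
write.table(data.frame(clone = names(pi), intact_pairs = pi),
            file.path(out, "pairing_integrity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("intact diagnostic pairs per clone: min %d of 4, median %g\n",
            min(pi), median(pi)))

# fold the two hairpin windows of each clone and export dot-brackets
windows <- data.frame(label = c("D1_hairpin", "D2_hairpin"),
                      start = c(88L, 378L), end = c(174L, 454L))
db_lines <- character(0)
for (w in seq_len(nrow(windows))) {
  for (id in clones) {
    seq <- substr(caln$seqs[[id]], windows$start[w], windows$end[w])
    seq <- gsub("-", "", seq)
    pt <- fold_maxpair(seq, offset = windows$start[w])
    db_lines <- c(db_lines,
                  sprintf(">%s %s", id, windows$label[w]),
                  seq, write_dot_bracket(pt))
  }
}
writeLines(db_lines, file.path(out, "hairpin_folds.db"))
cat(sprintf("wrote %d folded hairpin windows\n", 2L * length(clones)))
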