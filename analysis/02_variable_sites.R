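#!/usr/bin/env Rscript
# Variable-site profiling of the reconstructed 18-clone D1/D2 alignment:
# per-site state sets by species, substitution spectra, variable-region
# detection, reconciliation of the ambiguity-coded database consensus
# sequences, and pairwise clone differences.
# Writes results/02_variable_sites/.

suppressPackageStartupMessages(library(ribohet))
out <- "results/02_variable_sites"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- reconstruct_fixture_alignment(include_consensus = TRUE)
grouping <- fixture_grouping()
clones <- names(grouping)
caln <- rd_alignment(aln$seqs[clones], 1L)
write_clustal(caln, file.path(out, "clones.aln"))

sites <- profile_variable_sites(caln, grouping)
write.table(sites, file.path(out, "variable_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d variable sites among %d clones\n", nrow(sites),
            length(clones)))

spectra <- lapply(setNames(attr(sites, "groups"), attr(sites, "groups")),
                  function(g) substitution_spectrum(sites, g))
jsonlite::write_json(lapply(spectra, unclass),
                     file.path(out, "spectrum.json"), auto_unbox = TRUE,
                     digits = NA)
for (g in names(spectra)) {
  s <- spectra[[g]]
  cat(sprintf(
    "  %s: %d variable sites; transitions %d%% of ts+tv sites; T-C %d%% of transitions\n",
    g, s$n_variable_sites, s$pct_transitions, s$pct_TC_among_transitions))
}

regions <- detect_variable_regions(sites)
write.table(regions, file.path(out, "regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
vr <- fixture_vr_windows()
for (i in seq_len(nrow(vr)))
  cat(sprintf("  %s (%d-%d): %d sites\n", vr$label[i], vr$start[i],
              vr$end[i],
              length(sites_in_window(sites, vr$start[i], vr$end[i]))))

# sequence-logo count matrices for the two variable regions
for (i in seq_len(nrow(vr))) {
  pfm <- position_frequency_matrix(caln, vr$start[i], vr$end[i])
  write.table(cbind(char = rownames(pfm), as.data.frame(pfm)),
              file.path(out, paste0("pfm_", vr$label[i], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# ambiguity reconciliation of the three database consensus records
checks <- list()
for (db in c("AJ745110", "AJ745108", "AF360542")) {
  grp <- if (db == "AF360542") "fructicola" else "andauensis"
  pool <- clones[grouping[clones] == grp]
  psites <- profile_variable_sites(rd_alignment(caln$seqs[pool], 1L),
                                   grouping[pool])
  chk <- check_ambiguity_consistency(aln$seqs[db], psites, caln,
                                     clone_ids = pool)
  checks[[db]] <- cbind(consensus_id = db, chk)
  amb <- chk[grepl("/", chk$expansion), ]
  cat(sprintf("  %s: %d ambiguous symbols, %d consistent\n", db, nrow(amb),
              sum(amb$verdict == "consistent")))
}
write.table(do.call(rbind, checks), file.path(out, "ambiguity_checks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pw <- pairwise_differences(caln)
write.table(cbind(id = rownames(pw$subst), as.data.frame(pw$subst)),
            file.path(out, "pairwise.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("max pairwise substitutions %d (%.1f%% of %d nt); identical pairs: %s\n",
            pw$max_subst, pw$max_pct, n_columns(caln),
            paste(apply(pw$identical_pairs, 1, paste, collapse = "/"),
                  collapse = ", ")))
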