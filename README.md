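# ribohet

Analysis of intragenomic heterogeneity in rDNA repeat arrays, built around
the cloned D1/D2 domains (26S rRNA gene) of yeasts whose repeats are *not*
homogenized by concerted evolution. Given an alignment of cloned repeat
sequences from one or more strains, the package answers, in order:

- **Where is the variation?** Per-column state sets by strain and pooled
  (`profile_variable_sites`), clustered variable regions
  (`detect_variable_regions`), and per-region sequence-logo count matrices.
- **What kind of variation?** A per-site substitution spectrum
  (`substitution_spectrum`): transition fraction among dimorphic sites and
  the T–C share among transitions, the signature of wobble-tolerant
  variation.
- **Do the database ambiguity codes make sense?** Reconciliation of
  IUPAC-coded consensus entries against the clone pool
  (`check_ambiguity_consistency`): a symbol such as R at a site where the
  clones alternate A/G is *consistent* — heterogeneity, not sequencing
  error.
- **Is the variation structurally neutral?** Variable sites mapped into
  hairpin stem/loop context (`map_site_context`) and classified
  (`classify_structural_effect`) as wobble-neutral (every state pairs with
  the partner under A:U/G:C/G:U), compensatory (both partners variable with
  a pairing-restoring combination, e.g. the site pairs 103–159, 389–443,
  391–441), or disruptive; plus exact compensatory-type lookups
  (`assign_compensatory_type`) and intact-pair counts
  (`pairing_integrity`). Structures come from a built-in base-pair
  maximization folder (`fold_maxpair`, Nussinov-style with G:C=3, A:U=2,
  G:U=1) or imported dot-bracket strings.
- **Is the history tree-like?** p/F84/K3ST distances (`distance_matrix`),
  neighbor joining with bootstrap supports (`neighbor_joining`,
  `bootstrap_support`), and the pairwise homoplasy (Phi) recombination
  test (`phi_permutation_test`): Φ = mean incompatibility (four-gamete /
  partition-intersection) over informative-site pairs within a window *w*,
  with a permutation null on site positions and add-one p-value
  p = (1 + #{Φ\* ≤ Φ}) / (1 + N).

A seeded repeat-array simulator (`sim_config`, `evolve_array`) provides
ground truth for all of it: duplication-driven spread of a master repeat,
hot-spotted transition-biased substitution with compensatory co-mutation,
optional recombination and gene conversion, event-log replay, clone
sampling and IUPAC consensus emission.

## Worked example

The package ships machine-readable encodings of the published
variable-position tables for the *Metschnikowia andauensis* /
*M. fructicola* type strains and reconstructs from them a deterministic
18-clone alignment (`reconstruct_fixture_alignment`; a synthetic stand-in
realizing the tabulated per-site state sets, not the deposited
sequences). Running the whole pipeline on it:

```r
library(ribohet)
aln <- reconstruct_fixture_alignment(include_consensus = TRUE)
grouping <- fixture_grouping()
consensus <- aln$seqs[c("AJ745110", "AJ745108", "AF360542")]
attr(consensus, "groups") <- c(AJ745110 = "andauensis",
                               AJ745108 = "andauensis",
                               AF360542 = "fructicola")
report <- run_all(aln, grouping, consensus = consensus,
                  bootstrap_replicates = 100, phi_permutations = 1000,
                  seed = 42)
report
#> rd_report: 18 records, 35 variable sites (VR1=9, VR2=16)
#>   andauensis: 24 variable sites, ts 79%, T-C among ts 74%
#>   fructicola: 31 variable sites, ts 82%, T-C among ts 65%
#>   Phi = 0.5765, p = 0.9091
```

Reading it: the 18 clones vary at 35 sites, 9 of which fall in the fixed
window VR1 (positions 154–172) and 16 in VR2 (432–452) — both the 3′
back-folding strands of hairpin stems. Transitions dominate (79% and 82%
of dimorphic sites per strain), and most transitions are T–C (74% / 65%),
exactly the class a stem G partner neutralizes by wobble pairing. Every
ambiguous symbol of the three database consensus records reconciles as
consistent with the clone pools (`report$ambiguity`), and every clone
keeps at least 2 of its 4 diagnostic stem pairs intact
(`report$pairing_integrity`). The Phi p-value on this *reconstructed*
alignment is not informative about the real repeat arrays — the fixture
fixes per-site state sets, not the deposited haplotype mosaic (see below).

## Analysis workflow

Numbered drivers under `analysis/` run the full study end to end and write
tables under `results/` (each is a thin narrative wrapper over the package
functions):

```sh
Rscript analysis/01_simulate_array.R     # ground-truthed simulated arrays
Rscript analysis/02_variable_sites.R     # sites, spectra, regions, ambiguity
Rscript analysis/03_structure.R          # stem/loop effects, compensatory types
Rscript analysis/04_phylogeny.R          # F84/K3ST distances, NJ + bootstrap
Rscript analysis/05_recombination.R      # Phi test, clonal vs recombinant
```

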