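---
title: "Profiling intragenomic rDNA heterogeneity with ribohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling intragenomic rDNA heterogeneity with ribohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribohet)
```

## The problem

The tandem rDNA repeats of a genome are normally kept sequence-identical by
concerted evolution (unequal crossover, gene conversion). When
homogenization is inefficient, a single strain carries a pool of diverged
repeat variants, and the D1/D2 domain of the 26S rRNA gene — the standard
yeast barcode — stops being a single sequence. Cloned repeats from such a
strain differ at dozens of sites, the database "consensus" accumulates IUPAC
ambiguity codes, and phylogenetic trees built from the repeats carry almost
no support because their history is reticulate rather than tree-like.

ribohet packages the full desk analysis of such a clone set: where the
heterogeneous sites are and how they cluster; what kinds of substitutions
they carry; whether the ambiguity codes of database consensus records are
explained by the clone pool; how the variants sit in the hairpin secondary
structure of the rRNA (and why so many are structurally neutral); what the
distance phylogeny looks like; and whether site-compatibility patterns show
recombination. A seeded simulator of repeat-array evolution generates
arrays with known ground truth so that every stage is testable without
external data.

## Coordinates and data model

An alignment (`rd_alignment`) is a set of equal-length upper-case IUPAC
sequences plus an `offset`: the position of column 1 in the convention used
throughout — sites numbered from the first base behind the forward
amplification primer. All reports use these positions, never raw column
indices; `trim_overhangs()` keeps the convention intact when database
entries longer than the amplicon are clipped. T and U are one state
everywhere; `.` gaps normalize to `-`.

`align_center_star()` is a deliberately small aligner for near-identical
repeats (center sequence by minimum summed edit distance, ties to input
order; pairwise Needleman–Wunsch with linear gaps; merged gap pattern).
Cloned repeats of one array differ by a few percent at most, which is the
regime where center-star merging is safe. For anything more diverged, or to
replicate an existing analysis, supply a pre-made alignment — the pipeline
accepts one directly and skips alignment. The Clustal parameter set used in
any published alignment is rarely recoverable, so the pre-aligned path is
the recommended replication route.

## Variable sites and the substitution spectrum

`profile_variable_sites()` records, for every non-invariant column, the
state set per group (species/strain) and pooled. Pooled site classes are
`dimorphic` (exactly two non-gap states, no gap), `multistate` (three or
more bases), and `indel_involved` (a gap plus at most two bases), with gap
involvement also kept as an orthogonal flag.

The spectrum rule matters. `substitution_spectrum()` counts per SITE, not
per inferred event (the clone genealogy is unknown, so event counts would
be model-dependent): gaps are removed first, and a site whose residual
state set has exactly two bases enters the transition/transversion
denominator — even when a gap was present. A site like A/T/− is therefore
a transversion site with an indel flag, while T/− carries no substitution
at all. Sites with three or more bases are counted separately as
multistate and excluded from the ts/tv denominator. On the bundled
reconstruction of the published tables this rule reproduces all four
printed percentages (79% and 82% transitions; 74% and 65% T–C among
transitions); the stricter "gap-free sites only" variant does not (it
yields 85% for the second strain), which is why the gap-removal rule is
the package's definition. Reported percentages are rounded to the nearest
integer, half away from zero; exact rationals are kept alongside.

Single-clone outlier states (the kind a sequencing error would produce)
are not filtered: they are part of the observed state sets, and filtering
would change the printed counts. Downstream consumers can drop them by
thresholding the per-state counts in `position_frequency_matrix()` output.

`detect_variable_regions()` clusters variable positions into maximal runs
with spacing ≤ `max_gap` (default 5) and reports runs of at least
`min_sites` (default 3). The canonical regions used in all reports are
nevertheless the fixed windows VR1 = 154–172 and VR2 = 432–452
(`fixture_vr_windows()`), which hold 9 and 16 variable sites: the fixed
windows pin down the published counts, while detected runs are
supplementary (the gap-5 rule happily merges position 428 into the VR2
run, and position 103 — compensatory partner of 159 but 50 nt upstream —
is deliberately outside VR1).

`check_ambiguity_consistency()` reconciles an ambiguity-coded consensus
against the clone pool: a symbol is `consistent` when the clone bases at
that position are a subset of its expansion and at least two bases occur,
`inconsistent` on any base outside the expansion, `uninformative` when the
clones do not actually vary there. Unambiguous consensus characters at
variable sites are reported as uninformative with a note.

## Hairpin structure and the neutrality of the variation

Both variable regions sit in the 3′, back-folding strands of hairpin
stems. Because G:U wobble pairs are about as stable as canonical pairs, a
C↔T change opposite a stem G leaves the helix intact; coordinated changes
at paired positions (compensatory substitutions) do the same.

`fold_maxpair()` is a Nussinov-style dynamic program maximizing summed
pair scores (G:C = 3, A:U = 2, G:U = 1; hairpin loops ≥ 3). It is a
topology-level simplification of free-energy folding: stem/loop membership
is what the analysis consumes, stacking energetics are not modelled.
Traceback is deterministic (pairing preferred over bifurcation, smallest
split first). Folding is meant for extracted hairpin windows, mirroring an
analysis in which all segments not involved in the stems are removed;
whole-domain folding of a ~500-nt repeat will find spurious long-range
pairs. Even on windows, score maximization occasionally trades a true A:U
pair for a higher-scoring alternative offered by the loop sequence —
on simulated masters the designed stems are recovered at ~97% per pair,
not 100% — so externally predicted structures can be imported as
dot-bracket strings (`parse_dot_bracket()`) whenever fidelity matters.

The bundled hairpin model (`fixture_pair_table()`) places two D1 helices
and three nested D2 helices such that the three diagnostic variable-site
pairs (103–159, 389–443, 391–441, plus the invariant 390–442) are
base-paired and position 415 falls in a loop. The exact windows behind the
published structure figures are not recoverable; this model is the
package's calibration, shipped as data rather than hard-coded, and
replaceable by any imported dot-bracket.

`classify_structural_effect()` labels each variable stem site:
`wobble_neutral` when every observed state pairs (canonically or G:U) with
every partner state; `compensatory` when the partner is itself variable
and at least one joint combination restores pairing; `disruptive`
otherwise on the back-fold strand; `forward_strand_variant` for a 5′-strand
site with an invariant partner that is not wobble-neutral. Unpaired sites
are `loop_variant` (role `loop` inside a hairpin, `unpaired_other`
elsewhere). A gap among the site or partner states — the deletion at
position 440 is the real case — yields `indeterminate` rather than a
guess. On the reconstructed clone set the modal class among stem variants
is wobble-neutral (17 of 35 sites), with 6 compensatory sites: the
structural argument for why this much heterogeneity persists.

Compensatory typing (`assign_compensatory_type()`) is an exact lookup
against the published catalogs — VR1 types I–IV from the (103, 159) pair,
plus the consensus-only type V (R or N at 103), and VR2 types I–VI from
the 389-390-391 / 443-442-441 triplets. Unknown combinations are `novel`,
never force-fitted. `pairing_integrity()` counts intact diagnostic pairs
under the A:U/G:C/G:U rule; every catalogued clone keeps at least 2 of its
4 diagnostic pairs intact.

## Distances, trees, supports

`distance_matrix()` offers p, F84 (empirical base frequencies) and K3ST
(Kimura three-substitution-types) distances with pairwise deletion of
gapped sites by default — the study data have only two indel columns, so
the choice is immaterial there, but it is switchable. The K3ST correction
is computed in-package because its three log terms must be checked for
saturation individually: a library call that takes the log of their
product lets two negative terms cancel and silently returns a finite
distance for saturated pairs. Saturation is an error naming the pair, not
an infinite entry. `neighbor_joining()` clamps negative branch estimates
to zero with a warning. `bootstrap_support()` resamples columns against
the canonical column order (so supports are record-order invariant at a
fixed seed), builds one NJ tree per replicate, and maps the percentage of
replicates containing each full-data bipartition onto the tree. Replicates
that saturate are skipped, warned about, and removed from the denominator.

The published tree for this kind of data has very low supports; the
package treats NJ correctness (exact recovery of additive matrices,
order invariance) as the test surface and never asserts a topology for
the clone set.

## The Phi recombination test

Parsimony-informative sites (≥ 2 states each in ≥ 2 records, gaps as
missing) are tested pairwise for compatibility: the four-gamete test for
biallelic pairs, acyclicity of the partition-intersection graph for
multistate ones (normalized to a 0/1 verdict rather than extra-step
counts). Φ is the mean incompatibility over informative-site pairs within
`w` positions of each other (default 100, the cited implementation's
convention). Under recombination, nearby sites share genealogies while
distant ones do not, so the observed Φ is LOW relative to the same
incompatibility matrix with site positions permuted; the permutation null
(positions shuffled uniformly; the matrix itself is position-free and
computed once) with the add-one p-value
p = (1 + #{Φ_perm ≤ Φ_obs}) / (1 + N) is exact at desk scale and avoids
p = 0. A clonal alignment with no homoplasy gives Φ = 0 and p = 1.

Calibration, by simulation with uniform site rates (positions are then
exchangeable under the clonal null, and mutation hot-spots cannot
masquerade as signal), uses two designs. Size: 300-nt clonal repeats at
2×10⁻³ substitutions per site per generation over 40 generations — dense
enough in recurrent mutation that the permutation distribution is not
massed at Φ = 0 (with sparse homoplasy the test is intrinsically
conservative, a known property of homoplasy-based recombination tests);
the type-I error over 200 such arrays sits inside the central 95%
binomial band around 0.05. Power: 600-nt recombinant repeats (two
expected crossovers per generation, same mutation rate) — several
window-widths long, so nearby and distant informative-site pairs
actually contrast; rejection over 50 such arrays is ≥ 80% at 1000
permutations (measured ~95%). At 300 nt the window covers a third of the
repeat and power saturates near 78% regardless of rates, which is why
the power design uses the longer repeat. The permutation p-value is
reported alone — no normal approximation is implemented, so there is no
moment formula to mis-state.

## The repeat-array simulator

`evolve_array()` starts from `n_repeats` copies of a seeded master whose
stem blocks are reverse-complementary (with a configurable G:T wobble
fraction) and applies, per generation, in a fixed documented order:
duplications (a repeat overwritten by a copy of another — the turnover
analog of concerted evolution), substitutions (Poisson count placed
proportionally to site rates; the 3′ stem strands are rate-elevated by
`hot_multiplier` so variation concentrates in the two variable regions;
transitions drawn with probability `ts_bias`, C↔T weight further
multiplied by `tc_opposite_g_bias` opposite a partner G; a
pairing-breaking stem substitution is accompanied by the Watson–Crick
restoring partner change with probability `comp_comutation_p`),
recombination (suffix swap at a uniform breakpoint), gene conversion
(geometric tract copied between repeats), and per-site majority
homogenization. One global RNG stream per run makes paired-seed
comparisons meaningful; every event is logged and `replay_events()`
reproduces the array byte for byte, which is also the strongest internal
consistency check the tests lean on.

Defaults emulate the study conditions: 499-nt repeats, 20-repeat array,
two hairpins with the diagnostic-pair geometry, per-site baseline rate
10⁻⁴ per generation with a 25× hot-spot multiplier over 100 generations
(clone pools diverged up to a few percent, concentrated in the VR
windows), ts_bias 0.8, tc_opposite_g_bias 3, comp_comutation_p 0.5, no
recombination or conversion unless switched on, and clone samples of 7
and 11 mirroring a two-strain cloning design. Length variation is limited
to whole-tract conversion and single-site deletions; there are no
length-changing internal duplications, which keeps the alignment trivial
and the ground truth exact. The event model is a caricature: no
selection, no rDNA-array spatial structure, no PCR or sequencing error.
Passing tests on simulated arrays therefore validate the arithmetic of
the pipeline and the direction of its inferences, not the biology of any
real array.

`emit_consensus_with_ambiguity()` produces the minimal IUPAC cover per
column (gap columns emit a gap and are flagged); reconciling that
consensus against its own repeat pool is consistent by construction, and
the tests verify the implementation honors the construction.
`truth_evaluation()` closes the loop: detected variable sites against
truly segregating ones, modal structural-effect class against the
generative bias, and the Phi verdict against the generative
recombination rate.

## The reconstructed clone set

`reconstruct_fixture_alignment()` builds a deterministic synthetic
18-clone, 499-column alignment realizing exactly the published per-group
state sets at the 35 tabulated positions. Clone states at the six
diagnostic positions come straight from the compensatory-type catalogs;
the remaining per-clone assignments are fixed, documented choices made so
that (a) every per-group state set is realized, (b) exactly the two
published clone pairs are sequence-identical, and (c) no other pair
collides. The invariant background is a repeating pattern overwritten at
structurally constrained positions so the bundled hairpin model is
self-consistent (wobble-site partners are G, A/G-site partners are T,
invariant stem pairs are complementary).

What the fixture shows and does not show: per-site quantities (site
counts, spectra, region counts, ambiguity verdicts, compensatory types,
intact-pair counts) are exact reproductions of the published tables.
Clone-by-clone quantities that depend on the real haplotype structure —
the pairwise substitution maxima of 18 and 25, the tree, and the Phi
verdict on the real repeats — are NOT reproduced by the fixture and
require the deposited sequences (see the README on reproducing the
results); the fixture's maximum pairwise difference (29) and its
non-significant Phi are properties of the documented assignment, not of
the study data.

## Problem sizes and numerical choices

The test suite validates the folder against brute-force enumeration on
200 random sequences of length ≤ 14; NJ against 100 random additive
matrices (4–12 taxa); pair compatibility against exhaustive tree search
on 6 taxa (105 topologies); Phi size on 200 clonal and power on 50
recombinant simulated arrays; consensus reconciliation on 20 arrays; and
spectrum recovery on 100 arrays of 18 clones, whose mean estimated
transition percentage must fall within ±10 points of the generative 80%.
The acceptance script re-derives the headline quantities at slightly
smaller simulation counts. Ties in the folder and the aligner break
deterministically as documented above; all stochastic stages require an
explicit seed and refuse to run without one.
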