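fixture <- reconstruct_fixture_alignment()
grouping <- fixture_grouping()
sites <- profile_variable_sites(fixture, grouping)

test_that("substitution classification removes gaps first", {
  expect_identical(classify_substitution(c("A", "G"))$class, "transition")
  expect_identical(classify_substitution(c("C", "T"))$class, "transition")
  expect_identical(classify_substitution(c("A", "C"))$class, "transversion")
  expect_identical(classify_substitution(c("T", "C", "A"))$class, "multistate")
  expect_identical(classify_substitution("A")$class, "not_variable")
  # gap-involved sites classify on the residual base set, flag the indel
  atgap <- classify_substitution(c("A", "T", "-"))
  expect_identical(atgap$class, "transversion")
  expect_true(atgap$indel)
  tgap <- classify_substitution(c("T", "-"))
  expect_identical(tgap$class, "indel")
  expect_true(tgap$indel)
  expect_identical(classify_substitution(c("U", "C"))$class, "transition")
})

test_that("variable-site profile matches the tabulated state sets", {
  expect_identical(nrow(sites), 35L)
  tabs <- rbind(fixture_table_d1(), fixture_table_d2())
  expect_setequal(sites$position, tabs$position)
  # per-group state sets reproduce the tables exactly (order-normalized)
  norm <- function(s) paste(sort(strsplit(s, "/", fixed = TRUE)[[1]]),
                            collapse = "/")
  for (i in seq_len(nrow(tabs))) {
    row <- sites[sites$position == tabs$position[i], ]
    expect_identical(norm(row$states_andauensis), norm(tabs$andauensis[i]),
                     info = paste("position", tabs$position[i]))
    expect_identical(norm(row$states_fructicola), norm(tabs$fructicola[i]),
                     info = paste("position", tabs$position[i]))
  }
  # site 103: both groups alternate A/G, dimorphic pooled
  s103 <- sites[sites$position == 103, ]
  expect_identical(s103$site_class, "dimorphic")
  expect_identical(s103$class_andauensis, "transition")
})

test_that("profile is invariant under record order permutation", {
  set.seed(7)
  perm <- sample(names(fixture$seqs))
  aln2 <- rd_alignment(fixture$seqs[perm], fixture$offset)
  sites2 <- profile_variable_sites(aln2, grouping)
  expect_identical(sites$position, sites2$position)
  expect_identical(sites$pooled_states, sites2$pooled_states)
  expect_identical(sites$states_andauensis, sites2$states_andauensis)
})

test_that("site classes partition variable sites with indel orthogonal", {
  expect_true(all(sites$site_class %in%
                  c("dimorphic", "multistate", "indel_involved")))
  # spectrum class counts sum to the per-group variable-site count
  for (g in c("andauensis", "fructicola")) {
    sp <- substitution_spectrum(sites, g)
    n_not_var <- sum(vapply(strsplit(sites[[paste0("states_", g)]], "/"),
                            function(s) length(unique(s)) < 2, logical(1)))
    n_indel_only <- sum(vapply(strsplit(sites[[paste0("states_", g)]], "/"),
      function(s) {
        cl <- classify_substitution(s)
        cl$class == "indel"
      }, logical(1)))
    expect_identical(sp$n_transition_sites + sp$n_transversion_sites +
                     sp$n_multistate_sites + n_indel_only,
                     sp$n_variable_sites)
  }
})

test_that("substitution spectra reproduce the published percentages", {
  and <- substitution_spectrum(sites, "andauensis")
  fru <- substitution_spectrum(sites, "fructicola")
  expect_identical(and$pct_transitions, 79)
  expect_identical(fru$pct_transitions, 82)
  expect_identical(and$pct_TC_among_transitions, 74)
  expect_identical(fru$pct_TC_among_transitions, 65)
  expect_identical(and$n_variable_sites, 24L)
  expect_identical(fru$n_variable_sites, 31L)
})

test_that("degenerate spectra report undefined percentages, not zero", {
  aln <- rd_alignment(c(a = "AAAT", b = "AAA-"), offset = 1L)
  s <- profile_variable_sites(aln, c(a = "g", b = "g"))
  sp <- substitution_spectrum(s, "g")
  expect_true(is.na(sp$pct_transitions))
  # a single A/G site gives 100% transitions but 0% T-C among them
  aln2 <- rd_alignment(c(a = "AAAA", b = "AAAG"), offset = 1L)
  sp2 <- substitution_spectrum(profile_variable_sites(aln2, c(a = "g", b = "g")), "g")
  expect_identical(sp2$pct_transitions, 100)
  expect_identical(sp2$pct_TC_among_transitions, 0)
})

test_that("variable-region detection clusters runs by spacing", {
  vr <- detect_variable_regions(
    c(154L, 159L, 160L, 161L, 164L, 168L, 169L, 170L, 172L), max_gap = 5)
  expect_identical(nrow(vr), 1L)
  expect_identical(vr$start, 154L)
  expect_identical(vr$end, 172L)
  expect_identical(vr$n_sites, 9L)
  expect_identical(nrow(detect_variable_regions(integer(0))), 0L)
  # far-apart singletons are suppressed by min_sites
  expect_identical(nrow(detect_variable_regions(c(1L, 10L), max_gap = 5)), 0L)
  # canonical fixed windows on the fixture
  expect_identical(length(sites_in_window(sites, 154, 172)), 9L)
  expect_identical(length(sites_in_window(sites, 432, 452)), 16L)
})

test_that("ambiguity reconciliation verdicts follow the IUPAC expansions", {
  withcons <- reconstruct_fixture_alignment(include_consensus = TRUE)
  and_ids <- names(grouping)[grouping == "andauensis"]
  and_sites <- profile_variable_sites(
    rd_alignment(fixture$seqs[and_ids], 1L), grouping[and_ids])
  chk <- check_ambiguity_consistency(withcons$seqs["AJ745110"], and_sites,
                                     fixture, clone_ids = and_ids)
  amb <- chk[grepl("/", chk$expansion), ]
  expect_identical(nrow(amb), 7L)
  expect_true(all(amb$verdict == "consistent"))
  expect_identical(amb$symbol[amb$position == 103], "R")

  # a wrong symbol is flagged: Y over an A/G site
  cons <- fixture$seqs[["a77"]]
  substr(cons, 103, 103) <- "Y"
  chk2 <- check_ambiguity_consistency(stats::setNames(cons, "bad"),
                                      and_sites, fixture,
                                      clone_ids = and_ids)
  expect_identical(chk2$verdict[chk2$position == 103], "inconsistent")

  # N is consistent wherever >= 2 states are observed
  cons2 <- fixture$seqs[["a77"]]
  substr(cons2, 168, 168) <- "N"
  chk3 <- check_ambiguity_consistency(stats::setNames(cons2, "n"),
                                      and_sites, fixture,
                                      clone_ids = and_ids)
  expect_identical(chk3$verdict[chk3$position == 168], "consistent")
  expect_error(check_ambiguity_consistency(c(x = "ACGT"), and_sites, fixture),
               "length")
})

test_that("position frequency matrix conserves record counts", {
  pfm <- position_frequency_matrix(fixture, 154, 172)
  expect_identical(ncol(pfm), 19L)
  expect_true(all(colSums(pfm) == length(fixture$seqs)))
  # the 9 variable columns of VR1 have >= 2 nonzero characters
  varcols <- as.character(sites_in_window(sites, 154, 172))
  expect_true(all(colSums(pfm[, varcols] > 0) >= 2))
  # invariant columns have exactly one
  invcols <- setdiff(colnames(pfm), varcols)
  expect_true(all(colSums(pfm[, invcols] > 0) == 1))
})

test_that("pairwise differences are a symmetric pseudo-metric with the expected identical pairs", {
  pw <- pairwise_differences(fixture)
  expect_true(isSymmetric(pw$subst))
  expect_true(all(diag(pw$subst) == 0))
  tot <- pw$subst + pw$indel
  ids <- rownames(tot)
  # triangle inequality on a sample of triples
  set.seed(1)
  for (rep in 1:50) {
    t3 <- sample(ids, 3)
    expect_lte(tot[t3[1], t3[3]], tot[t3[1], t3[2]] + tot[t3[2], t3[3]])
  }
  got <- apply(pw$identical_pairs, 1, function(r) paste(sort(r), collapse = "+"))
  expect_setequal(got, c("aa20+ab24", "f39b2+fb6"))
  # constructed check: two records differing at exactly 3 columns
  aln <- rd_alignment(c(a = "ACGTACGT", b = "ACGAACTA"))
  expect_identical(pairwise_differences(aln)$subst["a", "b"], 3L)
})
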