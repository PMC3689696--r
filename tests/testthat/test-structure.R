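test_that("maximum-pairing fold matches the known optimum on a canonical hairpin", {
  pt <- fold_maxpair("GGGAAAACCC")
  expect_identical(pair_list(pt), cbind(i = 1:3, j = c(10L, 9L, 8L)))
  expect_identical(pair_list(fold_maxpair("AAAA")), cbind(i = integer(0),
                                                          j = integer(0)))
  # G:U wobble is allowed
  gu <- fold_maxpair("GGGAAAATTT")
  expect_identical(nrow(pair_list(gu)), 3L)
  expect_error(fold_maxpair("ACGX"), "must be over")
})

test_that("fold score equals the brute-force enumeration optimum on random sequences", {
  set.seed(42)
  n_cases <- 60
  for (case in seq_len(n_cases)) {
    n <- sample(5:14, 1)
    chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    pt <- fold_maxpair(paste(chars, collapse = ""))
    expect_valid_structure(pt, chars)
    expect_identical(pair_table_score(pt, chars),
                     brute_fold_score(chars))
  }
})

test_that("dot-bracket parsing and writing are mutually inverse", {
  pt <- parse_dot_bracket("((...))")
  expect_identical(pair_list(pt), cbind(i = 1:2, j = c(7L, 6L)))
  expect_identical(sum(parse_dot_bracket(".......")$partner), 0L)
  expect_error(parse_dot_bracket("(()"), "unbalanced")
  expect_error(parse_dot_bracket("())"), "position 3")
  expect_error(parse_dot_bracket("(x)"), "illegal")
  set.seed(11)
  for (case in 1:20) {
    n <- sample(8:16, 1)
    chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    pt <- fold_maxpair(paste(chars, collapse = ""))
    s <- write_dot_bracket(pt)
    expect_identical(parse_dot_bracket(s)$partner, pt$partner)
  }
})

test_that("site context assigns strand roles and loop membership", {
  # hairpin (1,10),(2,9),(3,8) over a 10-nt window
  pt <- ribohet:::new_pair_table(c(10L, 9L, 8L, 0L, 0L, 0L, 0L, 3L, 2L, 1L))
  aln <- rd_alignment(c(a = "GGGAAAACCC", b = "GGGATAACCC"))
  sites <- profile_variable_sites(aln, c(a = "g", b = "g"))
  # variable site 5 sits in the loop
  ctx <- map_site_context(pt, sites, aln)
  expect_identical(ctx$role[ctx$position == 5], "loop")
  aln2 <- rd_alignment(c(a = "GGGAAAACCC", b = "GGGAAAACTC"))
  s2 <- profile_variable_sites(aln2, c(a = "g", b = "g"))
  ctx2 <- map_site_context(pt, s2, aln2)
  expect_identical(ctx2$role[ctx2$position == 9], "stem_backfold")
  expect_identical(ctx2$partner_position[ctx2$position == 9], 2L)
})

test_that("structural effects: wobble, compensatory, disruptive", {
  mkctx <- function(role, partner_position = NA_integer_,
                    partner_states = NA_character_, partner_variable = NA)
    data.frame(position = 1L, role = role,
               partner_position = partner_position,
               partner_states = partner_states,
               partner_variable = partner_variable)
  # C/T opposite a stable G is neutral via the wobble pair
  eff <- classify_structural_effect(c("C", "T"),
           mkctx("stem_backfold", 2L, "G", FALSE))
  expect_identical(eff$effect, "wobble_neutral")
  # both partners variable with a pairing-restoring combination
  eff2 <- classify_structural_effect(c("A", "G"),
            mkctx("stem_forward", 159L, "T/C", TRUE))
  expect_identical(eff2$effect, "compensatory")
  # A/C opposite a stable G cannot pair for A
  eff3 <- classify_structural_effect(c("A", "C"),
            mkctx("stem_backfold", 2L, "G", FALSE))
  expect_identical(eff3$effect, "disruptive")
  expect_identical(classify_structural_effect(c("T", "C"),
                     mkctx("loop"))$effect, "loop_variant")
  # gap-bearing stem sites are indeterminate
  eff4 <- classify_structural_effect(c("A", "T", "-"),
            mkctx("stem_backfold", 2L, "T", FALSE))
  expect_identical(eff4$effect, "indeterminate")
})

test_that("G->U replacement opposite an all-G strand never breaks wobble neutrality", {
  # monotone property of the G:U rule: on a stem whose 5' strand is all G,
  # any mix of C and T on the 3' strand stays wobble-neutral
  set.seed(3)
  for (case in 1:25) {
    k <- sample(2:6, 1)
    states <- unique(sample(c("C", "T"), k, replace = TRUE))
    ctx <- data.frame(position = 1L, role = "stem_backfold",
                      partner_position = 2L, partner_states = "G",
                      partner_variable = FALSE)
    expect_identical(classify_structural_effect(states, ctx)$effect,
                     "wobble_neutral")
  }
})

test_that("fixture structural effects place the diagnostic pairs as compensatory", {
  aln <- reconstruct_fixture_alignment()
  sites <- profile_variable_sites(aln, fixture_grouping())
  eff <- structural_effects(fixture_pair_table(), sites, aln)
  comp <- eff$position[eff$effect == "compensatory"]
  expect_true(all(c(103L, 159L, 389L, 391L, 441L, 443L) %in% comp))
  # wobble neutralization is the modal effect among stem variants
  stem <- eff[grepl("stem", eff$role), ]
  expect_identical(names(which.max(table(stem$effect))), "wobble_neutral")
  # position 415 falls in the hairpin loop
  expect_identical(eff$effect[eff$position == 415], "loop_variant")
  expect_identical(eff$role[eff$position == 415], "loop")
  # the gap-bearing site 440 is indeterminate
  expect_identical(eff$effect[eff$position == 440], "indeterminate")
})

test_that("compensatory type lookup reproduces the published catalogs", {
  aln <- reconstruct_fixture_alignment(include_consensus = TRUE)
  cons <- c("AJ745110", "AJ745108", "AF360542")
  ct <- compensatory_type_table(aln, consensus_ids = cons)
  membership <- fixture_compensatory_membership()
  for (region in c("VR1", "VR2")) {
    cat_tab <- membership[[region]]
    for (r in seq_len(nrow(cat_tab))) {
      members <- c(strsplit(cat_tab$clones[r], ",")[[1]],
                   strsplit(cat_tab$database[r], ",")[[1]])
      members <- members[nzchar(members)]
      for (m in members) {
        got <- ct$type_label[ct$clone_id == m & ct$region == region]
        expect_identical(got, cat_tab$type[r],
                         info = paste(region, "type", cat_tab$type[r], m))
      }
    }
  }
  # unknown combinations are 'novel'; clones never match the consensus-only
  # VR1 type V
  expect_identical(assign_compensatory_type(c("T", "G"), "VR1")$type_label,
                   "novel")
  expect_identical(assign_compensatory_type(c("R", "T"), "VR1",
                                            is_consensus = FALSE)$type_label,
                   "novel")
  expect_identical(assign_compensatory_type(c("R", "T"), "VR1",
                                            is_consensus = TRUE)$type_label,
                   "V")
  expect_error(assign_compensatory_type(c("-", "T"), "VR1"), "gap")
})

test_that("pairing integrity counts intact diagnostic pairs", {
  # VR2 catalog rows: I = 3 intact A:U; V = 3 (G:C, A:U, G:C); II = 2
  # (A.C broken at the first pair); IV = 1 (two A.C)
  mk <- function(t5, t3) assign_compensatory_type(
    c(strsplit(t5, "")[[1]], strsplit(t3, "")[[1]]), "VR2")
  expect_identical(pairing_integrity(mk("AAA", "TTT")), 3L)
  expect_identical(pairing_integrity(mk("GAG", "CTC")), 3L)
  expect_identical(pairing_integrity(mk("AAA", "CTT")), 2L)
  expect_identical(pairing_integrity(mk("AAA", "CTC")), 1L)
  # VR1: G:U wobble keeps type II paired
  expect_identical(pairing_integrity(
    assign_compensatory_type(c("G", "T"), "VR1")), 1L)
  expect_identical(pairing_integrity(
    assign_compensatory_type(c("A", "C"), "VR1")), 0L)
  # every fixture clone keeps at least 2 of the 4 diagnostic pairs intact
  aln <- reconstruct_fixture_alignment()
  expect_true(all(clone_pairing_integrity(aln) >= 2))
})
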