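# Independent oracles used across the suite. These deliberately use
# different algorithms (plain recursion, closed forms, exhaustive tree
# search) than the package implementations they check.

# Maximum pair score over all nested structures of chars[i..j] by direct
# recursion on the fate of position i (unpaired, or paired with each k).
# No memoization: an enumeration, not a reimplementation of the DP.
brute_fold_score <- function(chars, min_loop = 3L,
                             scores = c(GC = 3, AU = 2, GU = 1)) {
  pairsc <- function(a, b) {
    key <- paste0(min(a, b), max(a, b))
    switch(key, AU = scores[["AU"]], CG = scores[["GC"]],
           GU = scores[["GU"]], -Inf)
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      sc <- pairsc(chars[i], chars[k])
      if (is.finite(sc))
        best <- max(best, sc + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  rec(1, length(chars))
}

# score of a pair table under the fold scoring (validity checked separately)
pair_table_score <- function(pt, chars,
                             scores = c(GC = 3, AU = 2, GU = 1)) {
  pl <- pair_list(pt)
  if (nrow(pl) == 0) return(0)
  sum(vapply(seq_len(nrow(pl)), function(r) {
    key <- paste0(min(chars[pl[r, 1]], chars[pl[r, 2]]),
                  max(chars[pl[r, 1]], chars[pl[r, 2]]))
    switch(key, AU = scores[["AU"]], CG = scores[["GC"]],
           GU = scores[["GU"]], -Inf)
  }, numeric(1)))
}

# validity of a pair table: reciprocity, nestedness, min-loop, allowed pairs
expect_valid_structure <- function(pt, chars, min_loop = 3L) {
  partner <- pt$partner
  for (i in seq_along(partner)) {
    if (partner[i] > 0) {
      expect_identical(partner[partner[i]], i)
      expect_true(abs(partner[i] - i) > min_loop)
    }
  }
  pl <- pair_list(pt)
  if (nrow(pl) >= 2) {
    for (a in 1:(nrow(pl) - 1)) for (b in (a + 1):nrow(pl)) {
      i <- pl[a, 1]; j <- pl[a, 2]; k <- pl[b, 1]; l <- pl[b, 2]
      crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
      expect_false(crossing)
    }
  }
  if (nrow(pl) > 0)
    expect_true(all(vapply(seq_len(nrow(pl)), function(r)
      can_pair(chars[pl[r, 1]], chars[pl[r, 2]]), logical(1))))
}

# K3ST distance from first principles: classify each differing site pair
k3st_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  q_pairs <- c("AT", "TA", "GC", "CG")   # alpha transversions
  r_pairs <- c("AC", "CA", "GT", "TG")   # beta transversions
  key <- paste0(a, b)
  P <- sum(key %in% ts_pairs) / n
  Q <- sum(key %in% q_pairs) / n
  R <- sum(key %in% r_pairs) / n
  -0.25 * (log(1 - 2 * P - 2 * Q) + log(1 - 2 * P - 2 * R) +
           log(1 - 2 * Q - 2 * R))
}

# F84 distance closed form with base frequencies estimated from both
# sequences pooled
f84_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  freq <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * n)
  pA <- freq[["A"]]; pC <- freq[["C"]]; pG <- freq[["G"]]; pT <- freq[["T"]]
  pR <- pA + pG; pY <- pC + pT
  key <- paste0(a, b)
  P <- sum(key %in% c("AG", "GA", "CT", "TC")) / n
  Q <- sum(a != b) / n - P
  A <- pC * pT / pY + pA * pG / pR
  B <- pC * pT + pA * pG
  C <- pR * pY
  -2 * A * log(1 - P / (2 * A) - (A - B) * Q / (2 * A * C)) +
    2 * (A - B - C) * log(1 - Q / (2 * C))
}

# Perfect-phylogeny oracle: two columns are compatible iff some unrooted
# tree lets both evolve without homoplasy (per-column parsimony score =
# number of states - 1). Exhaustive search over all topologies (phangorn).
compat_oracle <- function(col_a, col_b) {
  keep <- !is.na(col_a) & !is.na(col_b)
  a <- col_a[keep]; b <- col_b[keep]
  n <- length(a)
  taxa <- paste0("t", seq_len(n))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  da <- phangorn::phyDat(matrix(a, ncol = 1, dimnames = list(taxa, NULL)),
                         type = "USER", levels = c("A", "C", "G", "T"))
  db <- phangorn::phyDat(matrix(b, ncol = 1, dimnames = list(taxa, NULL)),
                         type = "USER", levels = c("A", "C", "G", "T"))
  ka <- length(unique(a)) - 1L
  kb <- length(unique(b)) - 1L
  for (t_i in seq_along(trees)) {
    tr <- trees[[t_i]]  # [[ restores tip labels on a compressed multiPhylo
    if (phangorn::parsimony(tr, da) == ka &&
        phangorn::parsimony(tr, db) == kb) return(TRUE)
  }
  FALSE
}

# clonal / recombinant simulation used by the Phi calibration tests, with
# uniform site rates so informative-site positions are exchangeable under
# the clonal null. The size (type-I) design uses 300-nt repeats, dense
# enough in homoplasy that the permutation distribution is not massed at
# zero; the power design uses 600-nt repeats, several window-widths long,
# so nearby and distant informative-site pairs contrast under
# recombination.
phi_sim_alignment <- function(seed, rec_rate = 0, repeat_length = 300L) {
  cfg <- sim_config(
    repeat_length = repeat_length, n_repeats = 12L,
    hairpin_spec = data.frame(pos5 = c(40:47, 150:157),
                              pos3 = c(100:93, 220:213), helix = "H"),
    mu = 2e-3, hot_multiplier = 1, ts_bias = 0.8,
    tc_opposite_g_bias = 1, comp_comutation_p = 0,
    rec_rate = rec_rate, dup_rate = 1, n_generations = 40L, seed = seed)
  arr <- evolve_array(cfg)
  rd_alignment(sample_clones(arr, 12, seed = seed + 1))
}
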