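# column characters with gaps (and ambiguity codes) as NA
column_chars <- function(m, j) {
  col <- m[, j]
  col[!col %in% c("A", "C", "G", "T", "U")] <- NA
  col[col == "U"] <- "T"
  col
}

#' Parsimony-informative sites
#'
#' Columns with at least two states each carried by at least two records;
#' gaps and ambiguity codes are treated as missing.
#'
#' @param aln An [rd_alignment()].
#' @param ids Record subset.
#' @return Integer vector of reference positions.
#' @export
informative_sites <- function(aln, ids = names(aln$seqs)) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  keep <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(column_chars(m, j))
    sum(tab >= 2) >= 2
  }, logical(1))
  column_position(aln, which(keep))
}

# integer codes for a column: A=1 C=2 G=3 T=4, anything else NA
encode_column <- function(col) {
  col <- toupper(col)
  col[col == "U"] <- "T"
  match(col, c("A", "C", "G", "T"))
}

# union-find acyclicity check of the partition-intersection (state) graph,
# on integer-coded state vectors with NAs already removed
states_graph_acyclic_int <- function(ai, bi) {
  edges <- unique(ai * 8L + bi)
  ea <- edges %/% 8L
  eb <- edges %% 8L
  na_states <- unique(ea)
  nb_states <- unique(eb)
  n_nodes <- length(na_states) + length(nb_states)
  if (length(edges) > n_nodes - 1L) return(FALSE)
  ia <- match(ea, na_states)
  ib <- length(na_states) + match(eb, nb_states)
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_along(edges)) {
    ra <- find(ia[k])
    rb <- find(ib[k])
    if (ra == rb) return(FALSE)  # edge closes a cycle
    parent[ra] <- rb
  }
  TRUE
}

states_graph_acyclic <- function(a, b) {
  ai <- encode_column(a); bi <- encode_column(b)
  keep <- !is.na(ai) & !is.na(bi)
  states_graph_acyclic_int(ai[keep], bi[keep])
}

#' Compatibility of two alignment columns
#'
#' Two sites are compatible when they can both evolve without homoplasy on a
#' single tree. For two biallelic sites this is the four-gamete test (all
#' four joint states present -> incompatible); the multistate generalization
#' used here is acyclicity of the partition-intersection graph (states of the
#' two columns as nodes, observed joint states as edges). Records missing at
#' either site are dropped pairwise; fewer than two shared records makes the
#' pair trivially compatible (flagged).
#'
#' @param col_a,col_b Character vectors of states (gaps/ambiguity as NA or
#'   `-`).
#' @return List: `compatible` (logical), `flagged` (too little overlap).
#' @export
pair_compatibility <- function(col_a, col_b) {
  ai <- encode_column(col_a); bi <- encode_column(col_b)
  keep <- !is.na(ai) & !is.na(bi)
  if (sum(keep) < 2)
    return(list(compatible = TRUE, flagged = TRUE))
  ai <- ai[keep]; bi <- bi[keep]
  # fast four-gamete path for a pair of biallelic sites
  if (length(unique(ai)) <= 2 && length(unique(bi)) <= 2) {
    compatible <- length(unique(ai * 8L + bi)) < 4L
  } else {
    compatible <- states_graph_acyclic_int(ai, bi)
  }
  list(compatible = compatible, flagged = FALSE)
}

#' Incompatibility matrix over informative sites
#'
#' @param aln An [rd_alignment()].
#' @param ids Record subset.
#' @return List: `positions` (reference coordinates) and `incompat` (symmetric
#'   0/1 matrix, zero diagonal).
#' @export
compatibility_matrix <- function(aln, ids = names(aln$seqs)) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  pos <- informative_sites(aln, ids)
  cols <- position_column(aln, pos)
  k <- length(cols)
  inc <- matrix(0, k, k)
  if (k >= 2) {
    cc <- lapply(cols, function(j) encode_column(m[, j]))
    nstates <- vapply(cc, function(x) length(unique(x[!is.na(x)])),
                      integer(1))
    for (i in 1:(k - 1)) {
      ai0 <- cc[[i]]
      for (j in (i + 1):k) {
        bi0 <- cc[[j]]
        keep <- !is.na(ai0) & !is.na(bi0)
        if (sum(keep) < 2) next  # trivially compatible
        ai <- ai0[keep]; bi <- bi0[keep]
        compatible <- if (nstates[i] <= 2 && nstates[j] <= 2)
          length(unique(ai * 8L + bi)) < 4L
        else states_graph_acyclic_int(ai, bi)
        if (!compatible) inc[i, j] <- inc[j, i] <- 1
      }
    }
  }
  list(positions = pos, incompat = inc)
}

phi_from_matrix <- function(positions, incompat, w) {
  k <- length(positions)
  if (k < 2) stop("fewer than two informative sites")
  D <- abs(outer(positions, positions, "-"))
  sel <- upper.tri(D) & D <= w & D > 0
  if (!any(sel)) stop("no informative-site pairs within window w = ", w)
  mean(incompat[sel])
}

#' Pairwise homoplasy statistic (Phi)
#'
#' Mean incompatibility over unordered pairs of parsimony-informative sites
#' whose positions differ by at most `w` (window measured in alignment
#' positions). 0 = every nearby pair compatible (tree-like signal);
#' 1 = every nearby pair incompatible.
#'
#' @param aln An [rd_alignment()].
#' @param w Window width in positions (default 100).
#' @param ids Record subset.
#' @return Numeric statistic in `[0, 1]`.
#' @export
phi_statistic <- function(aln, w = 100L, ids = names(aln$seqs)) {
  cm <- compatibility_matrix(aln, ids)
  phi_from_matrix(cm$positions, cm$incompat, w)
}

#' Permutation test for recombination based on Phi
#'
#' Recombination makes nearby sites share genealogies while distant sites do
#' not, so under recombination the observed mean incompatibility of nearby
#' informative-site pairs is LOW relative to the same sites at permuted
#' positions. The null permutes the positions of the informative columns
#' uniformly (the incompatibility matrix itself is position-free and is
#' computed once); the add-one p-value is
#' `p = (1 + #\{Phi_perm <= Phi_obs\}) / (1 + n_permutations)`.
#'
#' @param aln An [rd_alignment()].
#' @param w Window width in positions.
#' @param n_permutations At least 99.
#' @param seed Mandatory RNG seed.
#' @param ids Record subset.
#' @return List of class `rd_phi_result`: `statistic`, `w`, `n_informative`,
#'   `n_permutations`, `p_value`, `seed`.
#' @export
phi_permutation_test <- function(aln, w = 100L, n_permutations = 1000L, seed,
                                 ids = names(aln$seqs)) {
  if (missing(seed)) stop("seed is mandatory for phi_permutation_test")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 99) stop("use at least 99 permutations")
  cm <- compatibility_matrix(aln, ids)
  obs <- phi_from_matrix(cm$positions, cm$incompat, w)
  k <- length(cm$positions)
  ut <- which(upper.tri(cm$incompat))
  ii <- ((ut - 1L) %% k) + 1L
  jj <- ((ut - 1L) %/% k) + 1L
  incvec <- cm$incompat[ut]
  set.seed(seed)
  eps <- 1e-12
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    pp <- cm$positions[sample.int(k)]
    sel <- abs(pp[ii] - pp[jj]) <= w
    stat <- mean(incvec[sel])   # some pairs always qualify: k >= 2 checked
    if (stat <= obs + eps) hits <- hits + 1L
  }
  structure(list(statistic = obs, w = as.integer(w), n_informative = k,
                 n_permutations = n_permutations,
                 p_value = (1 + hits) / (1 + n_permutations),
                 seed = seed),
            class = "rd_phi_result")
}

#' @export
print.rd_phi_result <- function(x, ...) {
  cat(sprintf("Phi = %.4f (window %d, %d informative sites), p = %.4g [%d permutations]\n",
              x$statistic, x$w, x$n_informative, x$p_value,
              x$n_permutations))
  invisible(x)
}
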