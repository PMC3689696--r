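as_dnabin <- function(aln, ids = names(aln$seqs)) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  ape::as.DNAbin(tolower(m))
}

# K3ST (Kimura three-substitution-types) distances computed directly from
# the three change-class proportions. Kept in-package (rather than relying
# on a library call) because the three correction terms must be checked for
# saturation individually: taking log(w1 * w2 * w3) lets negative terms
# cancel and silently returns a finite distance for saturated pairs.
k3st_distances <- function(aln, ids, pairwise_deletion = TRUE) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  code <- matrix(match(ifelse(m == "U", "T", m), c("A", "C", "G", "T")),
                 nrow = nrow(m), dimnames = dimnames(m))
  if (!pairwise_deletion) {
    keep <- colSums(is.na(code)) == 0
    code <- code[, keep, drop = FALSE]
  }
  k <- length(ids)
  dm <- matrix(0, k, k, dimnames = list(ids, ids))
  ts_class <- c("13", "31", "24", "42")          # A<->G, C<->T
  q_class <- c("14", "41", "23", "32")           # A<->T, G<->C
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- code[i, ]; b <- code[j, ]
    keep <- !is.na(a) & !is.na(b)
    n <- sum(keep)
    if (n == 0) stop("no shared sites for pair ", ids[i], " - ", ids[j])
    key <- paste0(a[keep], b[keep])
    diff <- a[keep] != b[keep]
    P <- sum(key %in% ts_class) / n
    Q <- sum(key %in% q_class) / n
    R <- (sum(diff) - P * n - Q * n) / n
    w <- c(1 - 2 * P - 2 * Q, 1 - 2 * P - 2 * R, 1 - 2 * Q - 2 * R)
    if (any(w <= 0))
      dm[i, j] <- dm[j, i] <- NaN
    else
      dm[i, j] <- dm[j, i] <- -0.25 * sum(log(w))
  }
  dm
}

#' Pairwise evolutionary distances
#'
#' Distances under the p (raw proportion), F84 (empirical base frequencies,
#' transition/transversion correction) or K3ST model (Kimura's
#' three-substitution-types: transitions P, A<->T/G<->C transversions Q,
#' A<->C/G<->T transversions R, with
#' d = -1/4 [ln(1-2P-2Q) + ln(1-2P-2R) + ln(1-2Q-2R)]).
#' Sites with a gap in either member of a pair are excluded for that pair
#' (pairwise deletion) by default. Saturated pairs (non-finite corrected
#' distance) raise an error naming the pair rather than returning infinity.
#'
#' @param aln An [rd_alignment()].
#' @param model `"p"`, `"F84"` or `"K3ST"`.
#' @param pairwise_deletion Drop gapped sites per pair (default) instead of
#'   per alignment.
#' @param ids Record subset.
#' @return List of class `rd_distance_matrix`: `labels`, `d` (symmetric
#'   matrix), `model`.
#' @export
distance_matrix <- function(aln, model = c("F84", "p", "K3ST"),
                            pairwise_deletion = TRUE,
                            ids = names(aln$seqs)) {
  model <- match.arg(model)
  if (length(ids) < 2) stop("need at least two records")
  if (model == "K3ST") {
    dm <- k3st_distances(aln, ids, pairwise_deletion)
  } else {
    bin <- as_dnabin(aln, ids)
    ape_model <- c(p = "raw", F84 = "F84")[model]
    d <- ape::dist.dna(bin, model = ape_model,
                       pairwise.deletion = pairwise_deletion)
    dm <- as.matrix(d)
  }
  bad <- which(!is.finite(dm) | is.na(dm), arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0)
    stop(sprintf("distance saturation (model %s) for pair %s - %s", model,
                 ids[bad[1, 1]], ids[bad[1, 2]]))
  structure(list(labels = ids, d = dm, model = model),
            class = "rd_distance_matrix")
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining on a distance matrix. Negative
#' branch-length estimates are clamped to zero with a warning.
#'
#' @param dm An `rd_distance_matrix` (or a symmetric matrix / `dist`).
#' @return An [ape::phylo] unrooted tree.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "rd_distance_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Alignment columns are resampled with replacement per replicate (indices
#' drawn against the canonical column order, so supports are invariant to
#' record order at a fixed seed), an NJ tree is built per replicate, and the
#' percentage of replicates containing each bipartition of the full-data tree
#' is attached as node labels (majority-rule-style support mapping).
#' Replicates whose distance matrix saturates are skipped with a warning and
#' excluded from the denominator.
#'
#' @param aln An [rd_alignment()].
#' @param model Distance model, see [distance_matrix()].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Mandatory RNG seed.
#' @param ids Record subset.
#' @return List: `tree` (full-data NJ tree with `node.label` percentages),
#'   `n_replicates` requested, `n_effective` used.
#' @export
bootstrap_support <- function(aln, model = "F84", replicates = 100L, seed,
                              ids = names(aln$seqs)) {
  if (missing(seed)) stop("seed is mandatory for bootstrap_support")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  full <- neighbor_joining(distance_matrix(aln, model, ids = ids))
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  L <- ncol(m)
  set.seed(seed)
  trees <- list()
  skipped <- 0L
  for (b in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_aln <- rd_alignment(apply(m[, idx, drop = FALSE], 1, paste,
                                  collapse = ""), offset = 1L)
    t <- tryCatch(suppressWarnings(
                    neighbor_joining(distance_matrix(rep_aln, model))),
                  error = function(e) NULL)
    if (is.null(t)) skipped <- skipped + 1L else
      trees[[length(trees) + 1L]] <- t
  }
  if (skipped > 0)
    warning(skipped, " bootstrap replicate(s) skipped due to saturation")
  if (length(trees) == 0) stop("all bootstrap replicates saturated")
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round(100 * counts / length(trees))
  list(tree = full, n_replicates = replicates,
       n_effective = length(trees))
}

#' Root a tree on an outgroup
#'
#' @param tree An `ape::phylo`.
#' @param outgroup_id Leaf label to root on.
#' @return Rooted tree (outgroup a child of the root).
#' @export
outgroup_root <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup not among tree leaves: ", outgroup_id)
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Write a distance matrix as Phylip square format
#' @param dm `rd_distance_matrix`.
#' @param path Output file.
#' @export
write_phylip_distances <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$labels)), con)
  for (i in seq_along(dm$labels)) {
    writeLines(paste0(sprintf("%-10s", substr(dm$labels[i], 1, 10)),
                      paste(sprintf("%.6f", dm$d[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}
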