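test_that("p distance equals the mismatch proportion", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "G"), collapse = "")
  dm <- distance_matrix(rd_alignment(c(a = s1, b = s2)), model = "p")
  expect_equal(dm$d["a", "b"], 0.01)
  # identical sequences are at distance zero under every model
  s3 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  for (mod in c("p", "F84", "K3ST")) {
    dm0 <- distance_matrix(rd_alignment(c(a = s3, b = s3)), model = mod)
    expect_equal(dm0$d["a", "b"], 0)
  }
})

test_that("K3ST distance matches the closed form", {
  # crafted 300-nt pair with P = 0.05, Q = R = 0:
  # d = -1/4 * (2 ln(0.9) + ln(1))
  base <- rep(c("A", "C", "G", "T"), 75)
  other <- base
  other[seq_len(15)] <- c(A = "G", C = "T", G = "A", T = "C")[base[seq_len(15)]]
  aln <- rd_alignment(c(a = paste(base, collapse = ""),
                        b = paste(other, collapse = "")))
  dm <- distance_matrix(aln, model = "K3ST")
  expect_equal(dm$d["a", "b"], -0.25 * 2 * log(0.9), tolerance = 1e-10)
  expect_equal(dm$d["a", "b"], k3st_oracle(aln$seqs[["a"]], aln$seqs[["b"]]),
               tolerance = 1e-10)
  # random pairs agree with the oracle
  set.seed(5)
  for (case in 1:10) {
    s1 <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    s2 <- s1
    flip <- sample(400, 30)
    s2[flip] <- sapply(s1[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1))
    a2 <- rd_alignment(c(x = paste(s1, collapse = ""),
                         y = paste(s2, collapse = "")))
    expect_equal(distance_matrix(a2, model = "K3ST")$d["x", "y"],
                 k3st_oracle(a2$seqs[["x"]], a2$seqs[["y"]]),
                 tolerance = 1e-9)
  }
})

test_that("F84 distance matches the closed form with empirical frequencies", {
  set.seed(9)
  for (case in 1:10) {
    s1 <- sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                 prob = c(0.3, 0.2, 0.3, 0.2))
    s2 <- s1
    flip <- sample(500, 40)
    s2[flip] <- sapply(s1[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1,
             prob = rep(1, 3)))
    a2 <- rd_alignment(c(x = paste(s1, collapse = ""),
                         y = paste(s2, collapse = "")))
    expect_equal(distance_matrix(a2, model = "F84")$d["x", "y"],
                 f84_oracle(a2$seqs[["x"]], a2$seqs[["y"]]),
                 tolerance = 1e-6)
  }
})

test_that("distance models agree to first order at low divergence", {
  set.seed(21)
  s1 <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  s2 <- s1
  flip <- sample(1000, 8)  # 0.8% divergence
  s2[flip] <- sapply(s1[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1))
  aln <- rd_alignment(c(x = paste(s1, collapse = ""),
                        y = paste(s2, collapse = "")))
  d <- sapply(c("p", "F84", "K3ST"), function(m)
    distance_matrix(aln, model = m)$d["x", "y"])
  expect_true(all(abs(d / d[["p"]] - 1) < 0.05))
})

test_that("saturation raises an error naming the pair", {
  s1 <- paste(rep(c("A", "C"), 50), collapse = "")
  s2 <- paste(rep(c("G", "T"), 50), collapse = "")
  expect_error(distance_matrix(rd_alignment(c(p1 = s1, p2 = s2)),
                               model = "K3ST"), "saturation.*p1.*p2")
})

test_that("gapped sites are excluded pairwise", {
  aln <- rd_alignment(c(a = "ACGTACGTAC", b = "ACGTACGT--",
                        c = "ACGAACGTAC"))
  dm <- distance_matrix(aln, model = "p")
  expect_equal(dm$d["a", "b"], 0)          # 8 shared sites, no difference
  expect_equal(dm$d["a", "c"], 0.1)        # 1 of 10
  expect_equal(dm$d["b", "c"], 1 / 8)      # 1 of 8 shared
})

test_that("neighbor joining exactly recovers additive matrices", {
  set.seed(77)
  for (case in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
    D <- cophenetic(tr)
    nj <- neighbor_joining(D[sort(rownames(D)), sort(rownames(D))])
    expect_equal(ape::dist.topo(ape::unroot(tr), nj),
                 structure(0L, .Dim = NULL), ignore_attr = TRUE)
    expect_equal(cophenetic(nj)[rownames(D), rownames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("three-taxon NJ solves the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # pendant lengths: a = (3+4-5)/2 = 1, b = (3+5-4)/2 = 2, c = (4+5-3)/2 = 3
  got <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(got, c(a = 1, b = 2, c = 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is invariant under label order permutation", {
  set.seed(13)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  D <- cophenetic(tr)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), structure(0L), ignore_attr = TRUE)
})

test_that("negative NJ branch estimates are clamped with a warning", {
  D <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 10,
                1, 1, 0, 1,
                10, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- neighbor_joining(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports a clean split and is seed-deterministic", {
  # every column is one of two patterns supporting the same bipartition
  colA <- c(a = "A", b = "A", c = "G", d = "G")
  colB <- c(a = "C", b = "C", c = "T", d = "T")
  m <- cbind(matrix(rep(colA, 30), nrow = 4),
             matrix(rep(colB, 30), nrow = 4))
  rownames(m) <- names(colA)
  aln <- rd_alignment(apply(m, 1, paste, collapse = ""))
  bs <- bootstrap_support(aln, model = "p", replicates = 50, seed = 42)
  expect_identical(bs$n_effective, 50L)
  # the single internal edge carries 100% support
  expect_true(any(bs$tree$node.label == 100))
  bs2 <- bootstrap_support(aln, model = "p", replicates = 50, seed = 42)
  expect_identical(bs$tree$node.label, bs2$tree$node.label)
  expect_error(bootstrap_support(aln, model = "p", replicates = 10),
               "seed is mandatory")
})

test_that("outgroup rooting places the outgroup at the root and unroots back", {
  set.seed(2)
  tr <- ape::rtree(6, rooted = FALSE)
  rooted <- outgroup_root(tr, "t1")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 ape::Ntip(rooted) + 1L, 2]
  expect_true(which(rooted$tip.label == "t1") %in% root_children)
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr),
               structure(0L), ignore_attr = TRUE)
  expect_error(outgroup_root(tr, "nope"), "not among")
})
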