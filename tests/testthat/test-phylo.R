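# K2P distances, neighbor-joining, bootstrap supports.

test_that("K2P closed form matches hand-computed values", {
  # identical sequences
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # L=20, 2 transitions, 1 transversion: P=0.1, Q=0.05 -> 0.1701812
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c(rep("A", 17), "G", "G", "C"), collapse = "")
  cnt <- k2p_pair_counts(a, b)
  expect_equal(cnt$L, 20L)
  expect_equal(cnt$P, 0.1)
  expect_equal(cnt$Q, 0.05)
  d <- k2p_distance(a, b)
  expect_equal(d, -0.5 * log(0.75) - 0.25 * log(0.9))
  expect_equal(round(d, 5), 0.17018)
  # symmetry
  expect_equal(k2p_distance(b, a), d)
})

test_that("saturation raises a classed error", {
  # P=0.5, Q=0 -> log of a non-positive number
  a <- paste(rep(c("A", "C"), 10), collapse = "")
  b <- paste(rep(c("G", "C"), 10), collapse = "")
  expect_error(k2p_distance(a, b), class = "pks_saturation_error")
  # all-gap overlap
  expect_error(k2p_pair_counts("AC--", "--GT"), class = "pks_value_error")
})

test_that("pairwise deletion uses per-pair gap-free columns", {
  aln <- c(x = "ACGTAC-TAC", y = "ACGTACGT-C", z = "ACTTACGTAG")
  # x vs z: only x's gap column (pos 7) is dropped -> 9 compared sites
  cnt <- k2p_pair_counts(aln[["x"]], aln[["z"]])
  expect_equal(cnt$L, 9L)
  d_pw <- k2p_matrix(aln, "pairwise")
  d_cd <- k2p_matrix(aln, "complete")
  expect_true(isSymmetric(d_pw))
  expect_equal(diag(d_pw), c(x = 0, y = 0, z = 0))
  # complete deletion removes the union of gap columns for every pair
  expect_false(identical(d_pw[1, 3], d_cd[1, 3]))
})

test_that("K2P matrix agrees with the ape reference implementation", {
  aln <- simulate_k2p_alignment(
    "((A:0.08,B:0.05):0.04,(C:0.06,D:0.07):0.03,E:0.1);", 800, kappa = 2, seed = 5)
  mine <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(strsplit(tolower(aln), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
})

test_that("NJ handles 2 and 3 taxa with closed-form branch lengths", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sum(t2$edge.length), 0.3)

  d3 <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  pat <- cophenetic(t3)
  # three-point formulas reproduce the input exactly
  expect_equal(pat[rownames(d3), colnames(d3)], d3, tolerance = 1e-9)
})

test_that("NJ exactly recovers additive 4-taxon matrices (least-squares oracle)", {
  set.seed(17)
  for (rep in 1:20) {
    # random generating quartet: ((A,B),(C,D)) with random positive branches
    bl <- runif(5, 0.05, 0.4)  # a, b, c, d, internal
    taxa <- c("A", "B", "C", "D")
    d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    d["A", "B"] <- d["B", "A"] <- bl[1] + bl[2]
    d["C", "D"] <- d["D", "C"] <- bl[3] + bl[4]
    for (i in 1:2) for (j in 3:4)
      d[i, j] <- d[j, i] <- bl[i] + bl[j] + bl[5]

    tree <- nj_tree(d)
    # topology from the all-3-topology least-squares oracle
    fit <- oracle_quartet(d)
    expect_equal(fit$rss, 0, tolerance = 1e-12)
    expect_equal(tree_bipartitions(tree), fit$sig)
    # additive matrix -> exact patristic recovery (hence exact branch lengths)
    expect_equal(cophenetic(tree)[taxa, taxa], d, tolerance = 1e-8)
  }
})

test_that("NJ agrees with ape::nj topology on random matrices and validates input", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- gen$edge.length * 0.15  # keep distances unsaturated
    aln <- simulate_k2p_alignment(gen, 600, kappa = 2, seed = rep)
    d <- k2p_matrix(aln)
    expect_equal(ape::dist.topo(ape::unroot(nj_tree(d)), ape::unroot(ape::nj(d))), 0,
                 ignore_attr = TRUE)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(bad), class = "pks_validation_error")
  expect_error(nj_tree(matrix(0, 1, 1)), class = "pks_validation_error")
})

test_that("negative NJ branches are clamped with raw values preserved", {
  # strongly non-additive triple: the three-point formula goes negative for b
  taxa <- c("a", "b", "c")
  d <- matrix(c(0, .01, .5,
                .01, 0, .1,
                .5, .1, 0), 3, dimnames = list(taxa, taxa))
  tree <- nj_tree(d)
  expect_true(all(tree$edge.length >= 0))
  raw <- unlist(attr(tree, "raw_lengths"))
  expect_true(any(raw < 0))
  # total tree length is conserved by the clamp redistribution
  expect_equal(sum(tree$edge.length), sum(pmax(raw, 0)) + sum(raw[raw < 0]),
               tolerance = 1e-9)
})

test_that("NJ recovers the generating quartet for simulated K2P data", {
  newick <- "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);"
  want <- tree_bipartitions(ape::read.tree(text = newick))
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    aln <- simulate_k2p_alignment(newick, 1000, kappa = 2, seed = 1000 + s)
    got <- tree_bipartitions(nj_tree(k2p_matrix(aln)))
    if (identical(got, want)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("simulated K2P distances are consistent (within 3 SE at L = 10000)", {
  aln <- simulate_k2p_alignment("(A:0.1,B:0.1);", 10000, kappa = 2, seed = 99)
  cnt <- k2p_pair_counts(aln[["A"]], aln[["B"]])
  d <- k2p_distance(aln[["A"]], aln[["B"]])
  se <- k2p_stderr(cnt$P, cnt$Q, cnt$L)
  expect_lt(abs(d - 0.2), 3 * se)
})

test_that("kappa = 0.5 gives the unbiased 1/3 transition fraction", {
  aln <- simulate_k2p_alignment("(A:0.01,B:0.01);", 200000, kappa = 0.5, seed = 8)
  cnt <- k2p_pair_counts(aln[["A"]], aln[["B"]])
  frac_ts <- cnt$P / (cnt$P + cnt$Q)
  expect_lt(abs(frac_ts - 1 / 3), 0.05)
  # zero-length branches -> identical sequences
  aln0 <- simulate_k2p_alignment("(A:0,B:0);", 100, seed = 3)
  expect_equal(aln0[["A"]], aln0[["B"]])
  expect_equal(k2p_distance(aln0[["A"]], aln0[["B"]]), 0)
})

test_that("bootstrap: seeded reproducibility, valid ranges, default 1000", {
  expect_equal(eval(formals(bootstrap_support)$n_replicates), 1000L)
  aln <- simulate_k2p_alignment(
    "((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06,E:0.15);", 600, kappa = 2, seed = 4)
  t1 <- bootstrap_support(aln, n_replicates = 100, seed = 42)
  t2 <- bootstrap_support(aln, n_replicates = 100, seed = 42)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
  s <- attr(t1, "supports")
  expect_true(all(s >= 0 & s <= 100))
  # supports annotate exactly the full-data tree's bipartitions
  expect_setequal(names(s), tree_bipartitions(nj_tree(k2p_matrix(aln))))
  # different seed: same bipartitions, supports within stochastic range
  t3 <- bootstrap_support(aln, n_replicates = 200, seed = 7)
  expect_setequal(names(attr(t3, "supports")), names(s))
})

test_that("strong signal yields 100% supports and newick export carries them", {
  aln <- simulate_k2p_alignment(
    "((A:0.12,B:0.12):0.15,(C:0.12,D:0.12):0.15);", 3000, kappa = 2, seed = 11)
  tree <- bootstrap_support(aln, n_replicates = 100, seed = 13)
  expect_true(all(attr(tree, "supports") == 100))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  nwk <- readLines(path)
  expect_match(nwk, "100")
  expect_s3_class(ape::read.tree(path), "phylo")
})
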