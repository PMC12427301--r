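test_that("p_distance counts differing comparable sites, pairwise-deleting
          gaps and N", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)   # 3 comparable sites
  expect_equal(p_distance("ACNT", "AAGT"), 1 / 3)
  expect_error(p_distance("ACG", "ACGT"), "length")
  expect_warning(d0 <- p_distance("----", "AAAA"), "comparable")
  expect_equal(d0, 0)
})

test_that("p-distance matrices are symmetric, zero-diagonal, in [0, 1]", {
  set.seed(2)
  cfg <- sim_config(seed = 2, n_sites = 200, subst_rate = 0.1,
                    tree = "((a,b),(c,(d,e)));")
  dm <- p_distance_matrix(simulate_alignment_jc(cfg))
  expect_true(isSymmetric(unname(dm$mat)))
  expect_true(all(diag(dm$mat) == 0))
  expect_true(all(dm$mat >= 0 & dm$mat <= 1))
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  mat <- matrix(c(0, 0.3, 0.4,
                  0.3, 0, 0.5,
                  0.4, 0.5, 0), 3, dimnames = list(letters[1:3],
                                                   letters[1:3]))
  tr <- nj_tree(mat)
  # l_a = (d_ab + d_ac - d_bc) / 2, etc.
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0.1)
  expect_equal(bl[["b"]], 0.2)
  expect_equal(bl[["c"]], 0.3)
  expect_error(nj_tree(mat[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the generating topology from additive distances", {
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    D <- stats::cophenetic(true)
    got <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(true), got), 0)
    # and the recovered branch lengths reproduce the metric
    expect_equal(stats::cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("four-taxon NJ picks the topology satisfying the four-point
          condition", {
  # build an additive matrix by hand for split ab|cd
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ab <- 0.02; cd <- 0.03; inner <- 0.1
  pend <- c(a = 0.01, b = 0.01, c = 0.015, d = 0.015)
  d["a", "b"] <- d["b", "a"] <- pend["a"] + pend["b"]
  d["c", "d"] <- d["d", "c"] <- pend["c"] + pend["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- pend[x] + pend[y] + inner
  }
  tr <- nj_tree(d)
  split_ab <- karyevol:::tree_splits(tr)
  expect_true("b,c,d" %in% split_ab || "c,d" %in% split_ab)
})

test_that("negative NJ branch lengths are clamped with a warning", {
  mat <- matrix(c(0, 1, 1, 10,
                  1, 0, 1, 10,
                  1, 1, 0, 1,
                  10, 10, 1, 0), 4,
                dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(mat), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic per seed, bounded, and
          saturate on unambiguous alignments", {
  aln <- new_alignment(
    c("a", "b", "c", "d"),
    c(strrep("A", 40), strrep("A", 40), strrep("C", 40), strrep("C", 40)))
  # two identical pairs: every replicate tree contains the ab|cd split
  aln$mat[1, 1:10] <- "G"; aln$mat[2, 1:10] <- "G"
  tr <- bootstrap_support(aln, replicates = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  t1 <- bootstrap_support(tiny_alignment(), replicates = 30, seed = 9)
  t2 <- bootstrap_support(tiny_alignment(), replicates = 30, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("bootstrap support grows with sequence length", {
  tr <- read_tree(text =
    "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05,(e:0.05,f:0.05):0.05);")
  mean_support <- function(n_sites, seed) {
    cfg <- sim_config(seed = seed, n_sites = n_sites, tree = tr)
    aln <- simulate_alignment_jc(cfg)
    bt <- bootstrap_support(aln, replicates = 60, seed = seed)
    mean(suppressWarnings(as.numeric(bt$node.label)), na.rm = TRUE)
  }
  short <- mean(vapply(1:3, function(s) mean_support(50, s), 0))
  long <- mean(vapply(1:3, function(s) mean_support(500, s), 0))
  expect_gt(long, short)
})

test_that("alignments round-trip through FASTA and reject bad input", {
  aln <- tiny_alignment()
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$mat, aln$mat, ignore_attr = TRUE)
  expect_error(new_alignment(c("a", "a"), c("AC", "AC")), "duplicate")
  expect_error(new_alignment(c("a", "b"), c("AC", "ACG")), "aligned")
  expect_error(new_alignment("a", "AXC"), "symbol")
})
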