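dm <- function(vals, labs) {
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[upper.tri(m)] <- vals
  m + t(m)
}

test_that("UPGMA solves the small hand-computed cases", {
  d2 <- dm(0.4, c("A", "B"))
  t2 <- upgma(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  d3 <- dm(c(0.2, 0.6, 0.6), c("A", "B", "C"))  # AB=0.2, AC=BC=0.6
  t3 <- upgma(d3)
  expect_true(clade_support(t3, c("A", "B"))$present)
  depths <- ape::node.depth.edgelength(t3)
  heights <- max(depths) - depths
  expect_equal(sort(unique(round(heights[-(1:3)], 9))), c(0.1, 0.3))
})

test_that("UPGMA exactly recovers ultrametric inputs from the simulator", {
  for (seed in c(7, 19, 53)) {
    tr <- simulate_tree(10, 0.6, seed)
    d <- ape::cophenetic.phylo(tr)
    rec <- upgma(d[sort(rownames(d)), sort(rownames(d))])
    d_rec <- ape::cophenetic.phylo(rec)
    expect_equal(d_rec[rownames(d), colnames(d)], d, tolerance = 1e-12)
    expect_setequal(
      unname(vapply(tree_clades(rec), paste, "", collapse = "|")),
      unname(vapply(tree_clades(tr), paste, "", collapse = "|")))
  }
})

test_that("UPGMA output is ultrametric even for arbitrary distances", {
  set.seed(441)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    vals <- runif(n * (n - 1) / 2, 0.05, 1)
    tr <- upgma(dm(vals, paste0("t", seq_len(n))))
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  }
})

test_that("UPGMA merge heights agree with average-linkage hclust", {
  set.seed(442)
  vals <- runif(15, 0.1, 1)  # 6 taxa, generic distances (no ties)
  d <- dm(vals, paste0("t", 1:6))
  mine <- upgma(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  depths <- ape::node.depth.edgelength(mine)
  my_heights <- sort(round(max(depths) - depths, 10))
  expect_equal(tail(my_heights, 5), sort(round(hc$height / 2, 10)))
})

test_that("single-label input gives a single-tip tree", {
  tr <- upgma(matrix(0, 1, 1, dimnames = list("only", "only")))
  expect_s3_class(tr, "phylo")
  expect_equal(tr$tip.label, "only")
})

test_that("bootstrap is deterministic per seed and bounded in [0, 100]", {
  tr <- simulate_tree(7, 0.4, 451)
  aln <- evolve_proteins(tr, 120, 452)
  b1 <- bootstrap_support(aln, replicates = 30, seed = 9)
  b2 <- bootstrap_support(aln, replicates = 30, seed = 9)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  sup <- attr(b1, "support")
  expect_true(all(is.na(sup) | (sup >= 0 & sup <= 100)))
  expect_true(is.na(sup[as.character(length(aln$label) + 1L)]))
  b3 <- bootstrap_support(aln, replicates = 30, seed = 10)
  expect_s3_class(b3, "phylo")  # different seed still runs; values may move
})

test_that("a universally supported split gets support exactly 100", {
  aln <- protein_alignment(paste0("t", 1:4),
                           c(strrep("A", 40), strrep("A", 40),
                             strrep("C", 40), strrep("C", 40)))
  bt <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 2))
  expect_equal(clade_support(bt, c("t1", "t2"))$support, 100)
  expect_equal(clade_support(bt, c("t3", "t4"))$support, 100)
})

test_that("clade queries behave on cherries, the root, and non-clades", {
  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  expect_true(clade_support(cat4, c("a", "b"))$present)
  expect_false(clade_support(cat4, c("b", "c"))$present)
  root <- clade_support(cat4, c("a", "b", "c", "d"))
  expect_true(root$present)
  expect_true(is.na(root$support))
  expect_error(clade_support(cat4, c("a", "zz")), "unknown tip")
})

test_that("trees round-trip through Newick with supports intact", {
  tr <- simulate_tree(6, 0.5, 461)
  aln <- evolve_proteins(tr, 100, 462)
  bt <- bootstrap_support(aln, replicates = 20, seed = 5)
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(bt, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, bt$tip.label)
  expect_equal(sort(ape::cophenetic.phylo(back)[bt$tip.label, bt$tip.label]),
               sort(ape::cophenetic.phylo(bt)), tolerance = 1e-9)
  expect_setequal(stats::na.omit(as.numeric(back$node.label)),
                  stats::na.omit(attr(bt, "support")))
})
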