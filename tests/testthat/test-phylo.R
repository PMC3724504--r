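test_that("JC distance matches its closed form and ape's implementation", {
  # identical sequences
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(unname(jc_distance(aln)[1, 2]), 0)

  # p = 0.1 -> d = -(3/4) log(1 - 4/3 * 0.1) = 0.107326
  pr <- pair_with_p(200, 20, seed = 4)
  expect_equal(unname(jc_distance(pr, model = "p")[1, 2]), 0.1)
  expect_equal(unname(jc_distance(pr)[1, 2]), 0.107326, tolerance = 1e-5)

  # cross-check against ape's JC69 on a random low-divergence alignment
  sim <- run_simulation(sim_params(n_cycles = 400, n_descendants = 4,
                                   seq_length = 600, seed = 8))
  ours <- jc_distance(sim$sequences)
  apes <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    do.call(rbind, strsplit(tolower(sim$sequences), ""))),
    model = "JC69", pairwise.deletion = TRUE))
  expect_equal(ours, apes[rownames(ours), colnames(ours)], tolerance = 1e-10)
})

test_that("gap-only overlap and saturation are errors, not silent values", {
  expect_error(jc_distance(c(x = "AC--", y = "--AC")), "no comparable columns")
  sat <- c(x = strrep("A", 100), y = paste0(strrep("C", 80), strrep("A", 20)))
  expect_error(jc_distance(sat), "saturated")
  expect_equal(unname(jc_distance(sat, model = "p")[1, 2]), 0.8)
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-built additive matrix from ((A:1,B:2):1,(C:3,D:4):1)
  dm <- matrix(c(0, 3, 6, 7,
                 3, 0, 7, 8,
                 6, 7, 0, 7,
                 7, 8, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  ref <- ape::unroot(ape::read.tree(text = "((A:1,B:2):2,(C:3,D:4):0);"))
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)

  # random additive trees up to 8 taxa: topology and path lengths recovered
  set.seed(10)
  for (n in c(4, 5, 6, 8)) {
    gen <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    dm2 <- ape::cophenetic.phylo(gen)
    est <- nj_tree(dm2)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), est)), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm2), colnames(dm2)],
                 dm2, tolerance = 1e-8)
  }
})

test_that("degenerate taxon counts use the closed-form decompositions", {
  # 2 taxa: the single edge carries the full distance
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- nj_tree(dm2)
  expect_equal(sum(tr2$edge.length), 0.4)

  # 3 taxa: three-point decomposition, e.g. branch to A = (dAB + dAC - dBC)/2
  dm3 <- matrix(c(0, 0.2, 0.35,
                  0.2, 0, 0.30,
                  0.35, 0.30, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(dm3)
  lens <- tr3$edge.length[match(1:3, tr3$edge[, 2])]
  expect_equal(lens[tr3$tip.label == "A"], (0.2 + 0.35 - 0.30) / 2)
  expect_equal(lens[tr3$tip.label == "B"], (0.2 + 0.30 - 0.35) / 2)
  expect_equal(lens[tr3$tip.label == "C"], (0.35 + 0.30 - 0.2) / 2)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("a homoplasy-free clade signal earns 100% bootstrap support", {
  set.seed(21)
  L <- 400
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  flip <- function(s, idx) {
    for (i in idx) s[i] <- setdiff(c("A", "C", "G", "T"), s[i])[1]
    paste(s, collapse = "")
  }
  # taxa a..d: a few private substitutions each; e, f share 50 private ones
  sites <- sample(L, 4 * 5 + 50 + 2 * 5)
  blocks <- split(sites, rep(1:7, c(5, 5, 5, 5, 50, 5, 5)))
  ef_core <- flip(base, blocks[[5]])
  aln <- c(a = flip(base, blocks[[1]]), b = flip(base, blocks[[2]]),
           c = flip(base, blocks[[3]]), d = flip(base, blocks[[4]]),
           e = flip(str_chars(ef_core), blocks[[6]]),
           f = flip(str_chars(ef_core), blocks[[7]]))
  tr <- bootstrap_tree(aln, n_reps = 100, seed = 1)
  expect_equal(bipartition_support(tr, c("e", "f")), 100)
  expect_true(all(na.omit(as.numeric(tr$node.label)) >= 0))
  expect_true(all(na.omit(as.numeric(tr$node.label)) <= 100))

  # reproducibility from the seed
  tr2 <- bootstrap_tree(aln, n_reps = 100, seed = 1)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  # annotation does not change the point-estimate topology
  point <- nj_tree(jc_distance(aln))
  expect_equal(as.numeric(ape::dist.topo(point, tr)), 0)

  expect_error(bootstrap_tree(aln, n_reps = 0), "positive")
})

test_that("an invariant alignment yields undefined supports", {
  aln <- c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
           c = strrep("ACGT", 30), d = strrep("ACGT", 30))
  expect_warning(tr <- bootstrap_tree(aln, n_reps = 10, seed = 1),
                 "no variable sites")
  expect_true(all(is.na(tr$node.label)))
  expect_true(isTRUE(attr(tr, "degenerate")))
  expect_error(mean_bootstrap_value(tr), "undefined")
})

test_that("mean bootstrap value averages all internal-edge supports", {
  tr <- ape::read.tree(text = "((a,b),(c,d),(e,(f,g)));")
  tr$node.label <- c(NA, 62, 88, 100, 50)  # basal node carries no split
  expect_equal(mean_bootstrap_value(tr), 75)
  tr$node.label <- c(NA, 100, 50, NA, NA)
  expect_equal(mean_bootstrap_value(tr), 75)
  tr$node.label <- c(NA, 100, NA, NA, NA)
  expect_equal(mean_bootstrap_value(tr), 100)
  tr$node.label <- NULL
  expect_error(mean_bootstrap_value(tr), "no support")
})

test_that("tree shape metrics separate star-like from balanced trees", {
  star <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0,E:1);")
  m <- tree_shape_metrics(star)
  expect_equal(m$mean_internal, 0)
  expect_true(is.infinite(m$ratio))

  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mb <- tree_shape_metrics(bal)
  expect_equal(mb$ratio, 1)
  expect_equal(mb$n_terminal, 4)
  expect_equal(mb$n_internal, 2)
})

test_that("supported trees round-trip through Newick", {
  sim <- run_simulation(sim_params(n_cycles = 500, n_descendants = 4,
                                   seq_length = 400, seed = 6))
  tr <- bootstrap_tree(sim$sequences, n_reps = 20, seed = 6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, names(sim$sequences))
  expect_equal(mean_bootstrap_value(back), mean_bootstrap_value(tr))
})
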