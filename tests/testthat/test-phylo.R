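## presence matrix -> BinaryMatrix, tips A, B, C, ...
bmFromSets <- function(sets, samples) {
  pres <- t(vapply(sets, function(s) samples %in% s, logical(length(samples))))
  colnames(pres) <- samples
  buildMatrix(pres)
}

## independent oracle: minimum parsimony by exhaustive enumeration with
## phangorn's Fitch implementation
phangornMin <- function(bm) {
  pd <- phangorn::phyDat(t(bm@mat[rep(seq_len(nrow(bm@mat)), bm@weights), ,
                                  drop = FALSE]),
                         type = "USER", levels = c(0, 1))
  trees <- phangorn::allTrees(ncol(bm@mat), tip.label = colnames(bm@mat))
  min(phangorn::parsimony(trees, pd))
}

test_that("matrix construction collapses duplicate patterns with weights", {
  samples <- c("A", "B", "C", "D")
  sets <- list(c("A", "B", "C", "D"), c("A", "B"), c("C", "D"), "A", "C",
               c("A", "B"))   # duplicate of pattern 2
  bm <- bmFromSets(sets, samples)
  expect_equal(nrow(bm@mat), 5L)
  expect_equal(sum(bm@weights), 6L)
  pat <- apply(bm@mat[, samples], 1, paste, collapse = "")
  expect_equal(bm@weights[pat == "1100"], 2L)
  ## outgroup column appended as all-zero
  expect_true(all(bm@mat[, "Normal"] == 0))
  ## brute-force hash check
  set.seed(71)
  pres <- matrix(runif(48) < 0.5, 12, 4,
                 dimnames = list(NULL, samples))
  pres[rowSums(pres) == 0, 1] <- TRUE
  bm2 <- buildMatrix(pres)
  expect_equal(sum(bm2@weights), 12L)
  expect_equal(nrow(bm2@mat),
               length(unique(apply(pres, 1, paste, collapse = ""))))
  expect_error(buildMatrix(pres[, 1:2]), "3 samples")
})

test_that("Fitch scoring matches hand enumeration and the phangorn oracle", {
  samples <- c("A", "B", "C", "D")
  bm_all <- bmFromSets(list(samples), samples)
  t1 <- ape::read.tree(text = "((A,B),(C,D),Normal);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),Normal);")
  expect_equal(fitchScore(t1, bm_all), 1L)
  expect_equal(fitchScore(t2, bm_all), 1L)
  bm_ab <- bmFromSets(list(c("A", "B")), samples)
  expect_equal(fitchScore(t1, bm_ab), 1L)
  expect_equal(fitchScore(t2, bm_ab), 2L)
  expect_error(fitchScore(ape::read.tree(text = "(A,B,X);"), bm_ab),
               "do not match")
  ## random 5-sample matrices against phangorn
  set.seed(72)
  samples5 <- LETTERS[1:5]
  for (i in 1:10) {
    pres <- matrix(runif(40) < 0.5, 8, 5, dimnames = list(NULL, samples5))
    pres[rowSums(pres) == 0, 1] <- TRUE
    bm <- buildMatrix(pres)
    pd <- phangorn::phyDat(t(bm@mat[rep(seq_len(nrow(bm@mat)), bm@weights), ,
                                    drop = FALSE]),
                           type = "USER", levels = c(0, 1))
    tr <- ape::rtree(6, rooted = FALSE,
                     tip.label = sample(colnames(bm@mat)))
    expect_equal(fitchScore(tr, bm),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("branch and bound finds the perfect phylogeny and resists conflict", {
  samples <- c("A", "B", "C", "D")
  sets <- list(c("A", "B", "C", "D"), c("A", "B"), c("C", "D"), "A", "C")
  bm <- bmFromSets(sets, samples)
  trees <- maxParsimony(bm)
  expect_length(trees, 1L)
  expect_equal(parsimonyScore(trees[[1]]), 5L)
  expect_equal(trees[[1]]@newick, "((A,B),(C,D),Normal);")
  ## one conflicting character: score 5 + 2, same optimal topology
  bm2 <- bmFromSets(c(sets, list(c("B", "C"))), samples)
  trees2 <- maxParsimony(bm2)
  expect_equal(parsimonyScore(trees2[[1]]), 7L)
  expect_true("((A,B),(C,D),Normal);" %in%
                vapply(trees2, function(x) x@newick, ""))
  ## identical samples: every topology co-optimal at the same score
  bm3 <- bmFromSets(list(samples, samples, samples), samples)
  trees3 <- maxParsimony(bm3)
  expect_length(trees3, 15L)   # unrooted binary topologies on 5 taxa
  expect_true(all(vapply(trees3, parsimonyScore, integer(1)) == 3L))
})

test_that("branch and bound equals exhaustive enumeration on random matrices", {
  set.seed(73)
  for (i in 1:20) {
    ns <- sample(4:6, 1)
    pres <- matrix(runif(8 * ns) < 0.5, 8, ns,
                   dimnames = list(NULL, LETTERS[seq_len(ns)]))
    pres[rowSums(pres) == 0, 1] <- TRUE
    bm <- buildMatrix(pres)
    trees <- maxParsimony(bm)
    expect_equal(parsimonyScore(trees[[1]]), phangornMin(bm))
  }
})

test_that("parsimony score is invariant to sample order and weighting", {
  set.seed(74)
  pres <- matrix(runif(40) < 0.5, 10, 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  pres[rowSums(pres) == 0, 1] <- TRUE
  s1 <- parsimonyScore(maxParsimony(buildMatrix(pres))[[1]])
  s2 <- parsimonyScore(maxParsimony(buildMatrix(pres[, c(3, 1, 4, 2)]))[[1]])
  s3 <- parsimonyScore(maxParsimony(buildMatrix(pres[rep(1:10, 2), ]))[[1]])
  expect_equal(s1, s2)
  expect_equal(s3, 2L * s1)
})

test_that("clones cluster together on trees from simulated tumors", {
  cfg <- simConfig(n_regions = 6, n_clonal = 20, depth_mean = 300,
                   purity = 0.9, mu_eff = 0,
                   tree_splits = list(
                     list(parent = "C0", fraction = 0.6, regions = 1:3,
                          n_private = 10),
                     list(parent = "C0", fraction = 0.6, regions = 4:6,
                          n_private = 10)),
                   seed = 75)
  vt <- recoverVariants(applyFilters(simulateTumor(cfg)))
  trees <- maxParsimony(buildMatrix(vt))
  bm <- buildMatrix(vt)
  ## no homoplasy: optimal score equals the summed pattern weight
  expect_equal(parsimonyScore(trees[[1]]), sum(bm@weights))
  ## R1-R3 form one clade: the newick groups them on one side
  nw <- trees[[1]]@newick
  phy <- ape::read.tree(text = nw)
  split <- ape::prop.part(phy)
  tips <- phy$tip.label
  has123 <- any(vapply(split, function(p)
    setequal(tips[p], c("R1", "R2", "R3")) ||
      setequal(tips[p], c("R4", "R5", "R6", "Normal")), logical(1)))
  expect_true(has123)
})

test_that("newick output is canonical and round trips", {
  ## a 3-sample star (the unique unresolved topology on 4 taxa) is written
  ## with sorted tips and the outgroup last
  samples <- c("C", "A", "B")
  bm <- bmFromSets(list(c("A", "B", "C")), samples)
  star <- clonescape:::.sampleTree(cbind(5L, 1:4), bm)
  expect_equal(star@newick, "(A,B,C,Normal);")
  expect_equal(parsimonyScore(star), 1L)
  ## all three binary resolutions are co-optimal for a single shared variant
  trees <- maxParsimony(bm)
  expect_length(trees, 3L)
  f <- tempfile(fileext = ".nwk")
  writeNewick(trees[[1]], f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c(samples, "Normal"))
  ## branch-assigned variant counts sum to the parsimony score
  samples4 <- c("A", "B", "C", "D")
  bm4 <- bmFromSets(list(samples4, c("A", "B"), "D"), samples4)
  tr4 <- maxParsimony(bm4)[[1]]
  expect_equal(sum(tr4@branch_mutations), parsimonyScore(tr4))
  phy4 <- ape::read.tree({writeNewick(tr4, f); f})
  expect_equal(sum(phy4$edge.length), parsimonyScore(tr4))
})

test_that("CCF ordering constraints encode dominance and sibling rules", {
  ccf <- rbind(X = c(1.0, 1.0), Y = c(0.6, 0.2), Z = c(0.3, 0.5))
  res <- ccfOrderCheck(ccf, epsilon = 0.1)
  anc <- res$ancestry
  get <- function(a, d) anc$admissible[anc$ancestor == a & anc$descendant == d]
  expect_true(get("X", "Y"))
  expect_false(get("Y", "X"))
  ## crossing CCFs: neither Y over Z nor Z over Y
  expect_false(get("Y", "Z"))
  expect_false(get("Z", "Y"))
  ## but they fit as siblings under X: 0.9 <= 1.1 and 0.7 <= 1.1
  sib <- res$siblings
  expect_true(sib$admissible[sib$x == "Y" & sib$y == "Z" & sib$parent == "X"])
  expect_error(ccfOrderCheck(ccf[1, , drop = FALSE]), "2 clusters")
  ## exact simulated fractions reproduce the generating clone relations
  cfg <- simConfig(n_regions = 4, tree_splits = list(
    list(parent = "C0", fraction = 0.5, regions = 1:2, n_private = 3),
    list(parent = "C1", fraction = 0.3, regions = 1L, n_private = 3)),
    mu_eff = 0, seed = 76)
  tree <- simulateTree(cfg)
  res2 <- ccfOrderCheck(tree@fractions, epsilon = 0)
  a2 <- res2$ancestry
  g2 <- function(a, d) a2$admissible[a2$ancestor == a & a2$descendant == d]
  expect_true(g2("C0", "C1"))
  expect_true(g2("C1", "C2"))
  expect_false(g2("C2", "C1"))
})
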