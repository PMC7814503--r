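test_that("pcaStructure separates diverged subpopulations and behaves under duplication", {
  cfg <- simConfig(nAccessions = 80, nSnps = 200, divergence = 0.4,
                   missingRate = 0, seed = 2)
  sim <- simulatePanel(cfg)
  st <- pcaStructure(sim$genotypes, 2)
  sub <- sim$phenotypes@meta$subpop
  pc1 <- pcScores(st)[, 1]
  # PC1 separates the two subpopulations perfectly at high divergence
  expect_true(max(pc1[sub == 1]) < min(pc1[sub == 2]) ||
                max(pc1[sub == 2]) < min(pc1[sub == 1]))
  # duplicating every accession leaves variance fractions unchanged
  d <- dosages(sim$genotypes)
  dup <- makePanel(cbind(d, d), chrom = snpInfo(sim$genotypes)$chrom,
                   pos = snpInfo(sim$genotypes)$pos,
                   accessions = paste0("a", seq_len(2 * ncol(d))))
  expect_equal(varianceExplained(pcaStructure(dup, 2)),
               varianceExplained(st), tolerance = 1e-8)
  # full decomposition accounts for all variance
  small <- sim$genotypes[1:50, 1:10]
  stF <- pcaStructure(small, nPcs = 9)
  expect_equal(sum(varianceExplained(stF)), 1, tolerance = 1e-8)
  # scores orthogonal
  G <- crossprod(pcScores(st))
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # constant matrix errors
  expect_error(pcaStructure(makePanel(matrix(1, 3, 4))), "constant|variance")
})

test_that("kinshipMatrix is a PSD Gram matrix with sensible structure", {
  cfg <- simConfig(nAccessions = 60, nSnps = 300, divergence = 0,
                   missingRate = 0, seed = 6)
  sim <- simulatePanel(cfg)
  K <- kinshipMatrix(sim$genotypes)
  expect_true(isSymmetric(unname(K), tol = 1e-10))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # unstructured panel: mean off-diagonal near 0, diagonal near 1
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
  expect_lt(abs(mean(diag(K)) - 1), 0.2)
  # identical accessions give equal rows and the maximal off-diagonal entry
  d <- dosages(sim$genotypes)
  d2 <- cbind(d, dup = d[, 1])
  colnames(d2) <- c(colnames(d), "dup")
  K2 <- kinshipMatrix(makePanel(d2, chrom = snpInfo(sim$genotypes)$chrom,
                                pos = snpInfo(sim$genotypes)$pos))
  off <- K2; diag(off) <- -Inf
  expect_equal(sort(unname(which(off == max(off), arr.ind = TRUE)[1, ])),
               sort(c(1L, ncol(K2))), ignore_attr = TRUE)
  expect_equal(unname(K2[1, -c(1, ncol(K2))]), unname(K2[ncol(K2), -c(1, ncol(K2))]),
               tolerance = 1e-10)
})

test_that("njTree reproduces additive matrices exactly and handles twins", {
  # 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(D3)
  co <- ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(co), unname(D3), tolerance = 1e-10)
  # 4-taxon additive matrix from a known tree: path lengths recovered exactly
  ref <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0);")
  D4 <- ape::cophenetic.phylo(ref)
  t4 <- njTree(D4)
  expect_equal(ape::cophenetic.phylo(t4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-10)
  # duplicated taxa become siblings with zero-length pendant edges
  D5 <- D4
  D5 <- cbind(rbind(D5, E = D5["A", ]), E = c(D5["A", ], 0))
  t5 <- njTree(D5)
  expect_lt(ape::cophenetic.phylo(t5)["A", "E"], 1e-10)
  expect_error(njTree(matrix(c(0, NaN, NaN, 0), 2)), "NaN|3 taxa")
})

test_that("ibsDistance matches the allele-sharing definition on a hand example", {
  d <- matrix(c(0, 2, 1,
                2, 2, 1,
                0, NA, 1), nrow = 3, byrow = FALSE)
  colnames(d) <- c("x", "y", "z")
  gm <- makePanel(d)
  D <- ibsDistance(gm)
  # x vs y: |0-2| + |2-2| + |1-1| over 3 SNPs -> 2 / (2*3)
  expect_equal(D["x", "y"], 2 / 6)
  # x vs z: SNP2 missing in z -> pairwise complete over SNPs 1 and 3
  expect_equal(D["x", "z"], (0 + 0) / (2 * 2))
  expect_equal(diag(D), c(x = 0, y = 0, z = 0))
})
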