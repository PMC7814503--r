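test_that("lm scan agrees with a brute-force regression oracle to 1e-10", {
  # 6-accession worked example: dosages (0,0,1,1,2,2)
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.0, 0.8, 2.1, 1.9, 3.2, 2.9)
  gm <- makePanel(rbind(g))
  sc <- scanResults(scanEnvironment(gm, y, model = "lm"))
  or <- olsOracle(cbind(1, g), y)
  expect_equal(sc$beta, or$beta, tolerance = 1e-10)
  expect_equal(sc$se, or$se, tolerance = 1e-10)
  expect_equal(sc$p, or$p, tolerance = 1e-10)
  # parameterised random small instances, with PCs as covariates
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    g <- sample(0:2, n, replace = TRUE)
    if (var(g) == 0) next
    pcs <- matrix(rnorm(2 * n), n, 2)
    y <- rnorm(n)
    sc <- scanResults(scanEnvironment(makePanel(rbind(g)), y, pcs = pcs,
                                      model = "lm"))
    or <- olsOracle(cbind(1, pcs, g), y)
    expect_equal(sc$beta, or$beta, tolerance = 1e-10)
    expect_equal(sc$p, or$p, tolerance = 1e-10)
  }
})

test_that("perfect fit hits the p-value floor and skip reasons are recorded", {
  g <- c(0, 0, 1, 1, 2, 2, 0, 1)
  gm <- makePanel(rbind(g, rep(0, 8), c(0, 1, NA, NA, NA, NA, NA, NA)))
  sc <- scanResults(scanEnvironment(gm, as.numeric(g), model = "lm"))
  expect_equal(sc$beta[1], 1, tolerance = 1e-12)
  expect_equal(sc$p[1], 1e-300)
  expect_equal(sc$skipped[2], "monomorphic")
  expect_equal(sc$skipped[3], "too few accessions")
  expect_error(scanEnvironment(gm, rep(1, 8), model = "lm"), "constant")
})

test_that("type-I error is calibrated under the null (10,000 SNP tests)", {
  set.seed(77)
  n <- 100
  d <- matrix(sample(0:2, 10000 * n, replace = TRUE), nrow = 10000)
  gm <- makePanel(d, chrom = rep(c("1H", "2H"), each = 5000),
                  pos = rep(seq_len(5000) * 100L, 2))
  y <- rnorm(n)           # independent of every genotype
  sc <- scanResults(scanEnvironment(gm, y, model = "lm"))
  frac <- mean(sc$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("REML variance-ratio fit recovers truth and is scale equivariant", {
  set.seed(55)
  n <- 300
  # structured kinship from a simulated panel
  sim <- simulatePanel(simConfig(nAccessions = n, nSnps = 400, seed = 19))
  K <- kinshipMatrix(sim$genotypes)
  X <- cbind(rep(1, n))
  # sigma2_g = 0: estimate collapses to the lower boundary
  y0 <- rnorm(n)
  f0 <- suppressWarnings(fitNullMlm(y0, X, K))
  expect_lte(f0@lambda, 0.01)
  # sigma2_g / sigma2_e = 1: estimate lands in a sane band (5 seeds)
  eK <- eigen(K, symmetric = TRUE)
  ok <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    u <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * rnorm(n))
    y <- drop(u) + rnorm(n)
    f <- fitNullMlm(y, X, K)
    if (f@lambda >= 0.5 && f@lambda <= 2.0) ok <- ok + 1
  }
  expect_gte(ok, 4)
  # doubling y leaves lambda unchanged
  y <- drop(eK$vectors %*% (sqrt(pmax(eK$values, 0)) * rnorm(n))) + rnorm(n)
  f1 <- fitNullMlm(y, X, K)
  f2 <- fitNullMlm(2 * y, X, K)
  expect_equal(f1@lambda, f2@lambda, tolerance = 1e-6)
  expect_error(fitNullMlm(y, X, -K), "positive semi-definite")
})

test_that("mixed model degenerates to OLS under identity kinship", {
  set.seed(61)
  n <- 60
  d <- matrix(sample(0:2, 40 * n, replace = TRUE), nrow = 40)
  gm <- makePanel(d)
  y <- rnorm(n) + 0.8 * d[5, ]
  pcs <- matrix(rnorm(2 * n), n, 2)
  lmRes <- scanResults(scanEnvironment(gm, y, pcs = pcs, model = "lm"))
  nf <- suppressWarnings(fitNullMlm(y, cbind(1, pcs), diag(n)))
  mlmRes <- scanResults(scanEnvironment(gm, y, pcs = pcs, model = "mlm",
                                        nullFit = nf))
  expect_equal(mlmRes$p, lmRes$p, tolerance = 1e-8)
  expect_equal(mlmRes$beta, lmRes$beta, tolerance = 1e-8)
})

test_that("scanAll excludes unusable environments and is order equivariant", {
  sim <- simulatePanel(simConfig(nAccessions = 80, nSnps = 60, blockSize = 5,
                                 seed = 23))
  ws <- wsMatrix(sim$phenotypes)
  ws[, "UK-15"] <- 50                       # constant: non-differential site
  ws[seq_len(60), "ES-15"] <- NA            # only 20 phenotypes left
  ph <- PhenotypePanel(accessionIds(sim$phenotypes), ws)
  scans <- scanAll(sim$genotypes, ph, model = "lm", minN = 30)
  expect_equal(length(scans), 8L)
  excl <- attr(scans, "excluded")
  expect_setequal(names(excl), c("UK-15", "ES-15"))
  expect_match(excl[["UK-15"]], "constant")
  # permuting environment order permutes output only
  ph2 <- PhenotypePanel(accessionIds(sim$phenotypes), ws[, rev(colnames(ws))])
  scans2 <- scanAll(sim$genotypes, ph2, model = "lm", minN = 30)
  expect_setequal(names(scans2), names(scans))
  expect_equal(scanResults(scans2[["MN-14"]])$p, scanResults(scans[["MN-14"]])$p)
})

test_that("a strong QTL is the minimum-p marker in nearly every active environment", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- simConfig(nAccessions = 500, nSnps = 120, blockSize = 5,
                     residSd = rep(10, 10),
                     wsQtls = list(qtlSpec(8, c("MN-14", "MN-15", "OH-14",
                                                "OH-15", "AB-14", "AB-15",
                                                "DE-14", "ID-15", "UK-15",
                                                "ES-15"))),
                     seed = 200 + s)
    sim <- simulatePanel(cfg)
    qtl <- truthQtls(sim$truth)$snp_id
    scans <- scanAll(sim$genotypes, sim$phenotypes, model = "lm")
    for (sc in scans) {
      r <- scanResults(sc)
      total <- total + 1
      if (r$snp_id[which.min(r$p)] == qtl) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
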