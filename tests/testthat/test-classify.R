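test_that("vernalization classes follow the DTF thresholds and partition the range", {
  expect_equal(classifyVernalization(c(73, 130, 89)),
               c("insensitive", "sensitive", "intermediate"))
  expect_equal(classifyVernalization(NA), "unclassified")
  # every integer day in [1, censor] maps to exactly one class
  cl <- classifyVernalization(1:154)
  expect_true(all(cl %in% c("insensitive", "intermediate", "sensitive")))
  expect_equal(sum(cl == "insensitive"), 73L)
  expect_equal(sum(cl == "intermediate"), 129L - 74L + 1L)
  expect_equal(sum(cl == "sensitive"), 154L - 130L + 1L)
  expect_error(classifyVernalization(80, insensitiveMax = 140), "insensitiveMax")
})

test_that("VRN-H2 status matches its truth table over all flag combinations", {
  combos <- expand.grid(ha = c(TRUE, FALSE), hb = c(TRUE, FALSE),
                        hc = c(TRUE, FALSE))
  st <- callVrnH2(combos$ha, combos$hb, combos$hc)
  nPresent <- rowSums(combos)
  expect_equal(st[nPresent == 3], "intact")
  expect_equal(st[nPresent == 0], "complete_deletion")
  expect_true(all(st[nPresent %in% 1:2] == "partial_deletion"))
  expect_equal(callVrnH2(NA, TRUE, FALSE), "missing")
  # worked examples: all three ZCCT genes deleted vs Ha+Hb deleted
  expect_equal(callVrnH2(FALSE, FALSE, FALSE), "complete_deletion")
  expect_equal(callVrnH2(FALSE, FALSE, TRUE), "partial_deletion")
})

test_that("growth-habit decision table reproduces the worked accessions", {
  # 06OR-20: complete deletion + intact intron 1 + truncated HvFT3 + DTF 73
  expect_equal(classifyFacultative("truncated_HvFT3", "intact_intron1",
                                   "complete_deletion",
                                   classifyVernalization(73)),
               "facultative")
  # NB09433: intact ZCCT complex, DTF 135
  expect_equal(classifyFacultative("intact_HvFT3", "intact_intron1", "intact",
                                   classifyVernalization(135)),
               "winter")
  expect_equal(classifyFacultative("missing", "missing", "missing",
                                   "unclassified"),
               "unclassified")
  # insensitive but lacking a facultative key -> spring_like
  expect_equal(classifyFacultative("intact_HvFT3", "intact_intron1",
                                   "complete_deletion", "insensitive"),
               "spring_like")
})

test_that("top-fraction selection uses floor sizing and deterministic ties", {
  # constructed table with distinct means
  ws <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 95), ncol = 1)
  ph <- PhenotypePanel(paste0("g", 1:10), ws)
  top <- selectTopFraction(ph, frac = 0.2)
  expect_equal(top$accession, c("g10", "g9"))
  expect_warning(none <- selectTopFraction(PhenotypePanel(paste0("h", 1:19),
                                                          matrix(1:19, ncol = 1)),
                                           frac = 0.05),
                 "zero")
  expect_equal(nrow(none), 0L)
  expect_error(selectTopFraction(ph, frac = 1.5), "frac")
  # ties broken by accession id, ascending
  tie <- PhenotypePanel(c("b", "a", "c"), matrix(c(5, 5, 1), ncol = 1))
  expect_equal(selectTopFraction(tie, frac = 2 / 3)$accession, c("a", "b"))
  # 882 accessions at 5% give 44
  big <- PhenotypePanel(sprintf("x%03d", 1:882),
                        matrix(runif(882, 0, 100), ncol = 1))
  expect_equal(nrow(selectTopFraction(big, 0.05)), 44L)
})

test_that("clade summaries reproduce the printed top-5% table means", {
  t1 <- table1Fixture()
  membership <- setNames(as.character(t1$clade), t1$accession)
  values <- setNames(t1$avg_ws, t1$accession)
  cs <- cladeSummary(membership, values)
  expect_equal(cs$clades$mean_ws[match(as.character(1:7), cs$clades$clade)],
               c(61, 59, 58, 60, 62, 65, 59))
  expect_equal(cs$grandMean, 60)
  # single-member clade is its own value
  one <- cladeSummary(c(z = "solo"), c(z = 42))
  expect_equal(one$clades$mean_ws, 42)
  # half-up integer rounding (banker's rounding would give 2)
  expect_equal(cladeSummary(c(u = "c", v = "c"), c(u = 2, v = 3))$clades$mean_ws, 3)
})

test_that("augmented-design adjustment is exact on additive block shifts", {
  checks <- list(primary = "Alba", secondary = c("Maja", "FullPint"))
  base <- data.frame(entry = c("Alba", "Maja", "FullPint", "e1", "e2"),
                     value = c(46, 47, 19, 60, 30))
  shifts <- c(5, 0, -5)
  layout <- do.call(rbind, lapply(1:3, function(b) {
    d <- base; d$block <- b; d$value <- d$value + shifts[b]; d
  }))
  adj <- adjustAugmented(layout, checks, method = "primary")
  entries <- adj$adjusted[!adj$adjusted$entry %in% c("Alba", "Maja", "FullPint"), ]
  expect_equal(entries$adjusted, rep(c(60, 30), 3))
  expect_gt(adj$relativeEfficiency, 1)
  # identical blocks: zero adjustment, RE = 1
  flat <- do.call(rbind, lapply(1:3, function(b) { d <- base; d$block <- b; d }))
  adjF <- adjustAugmented(flat, checks, method = "primary")
  expect_equal(adjF$adjusted$adjusted, adjF$adjusted$value)
  expect_equal(adjF$relativeEfficiency, 1)
  # method = none is the identity
  adjN <- adjustAugmented(layout, checks, method = "none")
  expect_equal(adjN$adjusted$adjusted, layout$value)
  expect_equal(adjN$relativeEfficiency, 1)
  # secondary-check regression also recovers additive shifts
  adjS <- adjustAugmented(layout, checks, method = "secondary")
  entriesS <- adjS$adjusted[adjS$adjusted$entry %in% c("e1", "e2"), ]
  expect_equal(entriesS$adjusted, rep(c(60, 30), 3))
  # a block missing its primary check errors
  broken <- layout[!(layout$block == 2 & layout$entry == "Alba"), ]
  expect_error(adjustAugmented(broken, checks, method = "primary"),
               "primary check")
})

test_that("candidateGenes reports overlaps and windowed neighbours in distance order", {
  # toy annotation built at offsets {0, 100k, 259k, 400k} from the SNP
  snpPos <- 31685164L
  ann <- data.frame(
    gene_id = c("G_inside", "G_100k", "G_259k", "G_400k"),
    chrom = "1H",
    start = c(snpPos - 5000L, snpPos + 100000L, snpPos + 259000L, snpPos + 400000L),
    end = c(snpPos + 5000L, snpPos + 110000L, snpPos + 269000L, snpPos + 410000L))
  snps <- data.frame(snp_id = "SCRI_peak", chrom = "1H", pos = snpPos)
  res <- candidateGenes(snps, ann, windowBp = 300000)
  expect_equal(res$gene_id, c("G_inside", "G_100k", "G_259k"))
  expect_equal(res$distance, c(0, 100000, 259000))
  # gene starting exactly window + 1 beyond the SNP is excluded
  edge <- data.frame(gene_id = "G_edge", chrom = "1H",
                     start = snpPos + 300001L, end = snpPos + 310000L)
  resE <- candidateGenes(snps, edge, windowBp = 300000)
  expect_equal(nrow(resE), 0L)
  # at exactly the window bound it is included
  resB <- candidateGenes(snps, transform(edge, start = snpPos + 300000L),
                         windowBp = 300000)
  expect_equal(resB$distance, 300000)
  # unplaced SNPs are skipped with a reason
  resU <- candidateGenes(data.frame(snp_id = "u1", chrom = "1H", pos = NA),
                         ann, windowBp = 300000)
  expect_equal(nrow(resU), 0L)
  expect_match(attr(resU, "skipped")[["u1"]], "unplaced")
})

test_that("classifying the genotyped top accessions reproduces the printed pattern", {
  t3 <- table3Fixture()
  vern <- classifyVernalization(t3$dtf)
  habit <- classifyFacultative(t3$ppd_h2, t3$vrn_h1, t3$vrn_h2, vern)
  # the facultative ideotype: complete VRN-H2 deletion, intact intron 1,
  # truncated HvFT3, no vernalization requirement
  expect_equal(sort(t3$accession[habit == "facultative"]),
               c("06OR-20", "GRETE"))
  expect_true(all(t3$vrn_h1 == "intact_intron1"))  # whole top set carries it
  # VRN-H2 deletions confer insensitive or intermediate sensitivity
  expect_true(all(vern[t3$vrn_h2 == "complete_deletion"] %in%
                    c("insensitive", "intermediate")))
  # the two partial deletions in the winter group
  expect_setequal(t3$accession[t3$vrn_h2 == "partial_deletion" &
                                 vern == "sensitive"], c("JET", "DIADEM"))
})
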