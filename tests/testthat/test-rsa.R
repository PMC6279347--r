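test_that("exemplar aggregation averages trials and flags missingness", {
  # 2 trials of one combination in run 1, none of another
  design <- data.frame(trial_id = 1:3, run = c(1L, 1L, 2L),
                       condition = "current", category = c(1L, 1L, 2L),
                       exemplar = 1L, target_present = TRUE, n_trs = 2L)
  pat <- array(seq_len(3 * 2 * 4), c(3, 2, 4))
  ds <- methods::new("PatternDataset", patterns = pat, trialInfo = design,
                     subjectId = "s", chanceLevel = 1 / 2,
                     provenance = list())
  ep <- exemplarPatterns(ds, tr = 1)
  i11 <- which(ep$labels$category == 1 & ep$labels$exemplar == 1)
  expect_equal(ep$patterns[i11, , 1],
               colMeans(rbind(pat[1, 1, ], pat[2, 1, ])))
  # category 2 absent from run 1, present (single trial) in run 2
  i21 <- which(ep$labels$category == 2 & ep$labels$exemplar == 1)
  expect_true(all(is.na(ep$patterns[i21, , 1])))
  expect_equal(ep$patterns[i21, , 2], pat[3, 1, ])
})

test_that("a 12-trial two-condition run covers half of the 24 combinations", {
  ds <- invertedDataset("exp1", nVoxels = 10, seed = 2)
  ep <- exemplarPatterns(ds, tr = 5)
  expect_equal(nrow(ep$labels), 24L)
  perRun <- apply(ep$patterns[, 1, ], 2, function(col) sum(!is.na(col)))
  expect_true(all(perRun == 12L))
})

test_that("RDM cells hit the analytic endpoints and match a ties oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(mvdecode:::.rdmCell(x, x * 3 + 1, "one_minus_rho"), 0)
  expect_equal(mvdecode:::.rdmCell(x, -x, "one_minus_rho"), 2)
  # ties: brute-force average-rank Spearman
  a <- c(1, 2, 2, 3, 5)
  b <- c(2, 2, 4, 4, 1)
  expect_equal(mvdecode:::.rdmCell(a, b, "one_minus_rho"),
               1 - oracleSpearman(a, b))
  expect_equal(cor(a, b, method = "spearman"), oracleSpearman(a, b))
})

test_that("the two-condition RDM is 24 x 24, symmetric, zero-diagonal", {
  ds <- invertedDataset("exp1", nVoxels = 25, seed = 3)
  rdm <- computeRdm(ds, trs = defaultIntervals("exp1")$delay)
  d <- dissimilarity(rdm)
  expect_equal(dim(d), c(24L, 24L))
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 24))
  expect_true(all(d[upper.tri(d)] >= 0 & d[upper.tri(d)] <= 2))
  expect_equal(nrow(rdmLabels(rdm)), 24L)
})

test_that("rank transform spaces unique values evenly and respects ties", {
  lab <- data.frame(category = rep(1:2, each = 2), exemplar = 1:2,
                    relevance = "current")
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(1, 2, 3, 4, 5, 6) / 10
  d <- d + t(d)
  rdm <- methods::new("RDM", d = d, labels = lab, scope = "toy",
                      nRunsAveraged = matrix(1, 4, 4),
                      scale = "one_minus_rho")
  rt <- rankTransform(rdm)
  expect_equal(sort(dissimilarity(rt)[upper.tri(d)]), (0:5) / 5)
  # monotone transform invariance
  rdm2 <- rdm; rdm2@d <- sqrt(d)
  expect_equal(dissimilarity(rankTransform(rdm2)), dissimilarity(rt))
  # idempotence up to scaling
  expect_equal(dissimilarity(rankTransform(rt)), dissimilarity(rt))
  # ties get equal transformed values; all-equal collapses to 0.5
  d3 <- matrix(0.4, 4, 4); diag(d3) <- 0
  rdm3 <- methods::new("RDM", d = d3, labels = lab, scope = "toy",
                       nRunsAveraged = matrix(1, 4, 4),
                       scale = "one_minus_rho")
  expect_true(all(dissimilarity(rankTransform(rdm3))[upper.tri(d3)] == 0.5))
})

test_that("classical MDS recovers a planar configuration up to rigid motion", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(dist(pts))
  coords <- classicalMds(d, k = 2)
  expect_equal(sort(as.numeric(dist(coords))), sort(as.numeric(dist(pts))),
               tolerance = 1e-8)
  # all-zero dissimilarities -> coincident points
  expect_true(all(classicalMds(matrix(0, 3, 3), k = 2) == 0))
  expect_error(classicalMds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # k above the positive-eigenvalue count warns and reduces
  expect_warning(classicalMds(d, k = 3), "positive eigenvalue")
})

test_that("same/different contrast has the documented cell structure", {
  ds <- invertedDataset("exp1", nVoxels = 25, seed = 4)
  rdm <- computeRdm(ds, trs = 5)
  ct <- sameVsDiffContrast(rdm, c("current", "prospective"), scale = "raw")
  expect_equal(ct$nSameCells, 48L)   # 3 blocks x 4 x 4 exemplar pairs
  expect_equal(ct$nDiffCells, 96L)   # 6 off-blocks x 16
  expect_equal(ct$difference, ct$sameCategoryMean - ct$diffCategoryMean)
  # swapping the roles flips nothing (cells are cross-relevance either way),
  # but relabelling same<->different is antisymmetric by construction
  ct2 <- sameVsDiffContrast(rdm, c("prospective", "current"), scale = "raw")
  expect_equal(ct2$difference, ct$difference)
  expect_error(sameVsDiffContrast(rdm, c("current", "missing")), "absent")
  expect_error(sameVsDiffContrast(rdm, c("current", "current")), "distinct")
})

test_that("an all-equal RDM gives zero contrast difference", {
  lab <- expand.grid(exemplar = 1:2, category = 1:3,
                     relevance = c("current", "prospective"),
                     stringsAsFactors = FALSE)[, c("category", "exemplar",
                                                   "relevance")]
  d <- matrix(0.8, 12, 12); diag(d) <- 0
  rdm <- methods::new("RDM", d = d, labels = lab, scope = "toy",
                      nRunsAveraged = matrix(1, 12, 12),
                      scale = "one_minus_rho")
  ct <- sameVsDiffContrast(rdm, c("current", "prospective"), scale = "raw")
  expect_equal(ct$difference, 0)
})

test_that("fisher scaling transforms the underlying rho before averaging", {
  lab <- data.frame(category = c(1, 1, 2, 2),
                    exemplar = c(1, 1, 1, 1),
                    relevance = rep(c("current", "prospective"), 2))
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(0.5, 0.4, 0.9, 1.2, 0.6, 0.3)
  d <- d + t(d)
  rdm <- methods::new("RDM", d = d, labels = lab, scope = "toy",
                      nRunsAveraged = matrix(1, 4, 4),
                      scale = "one_minus_rho")
  ct <- sameVsDiffContrast(rdm, c("current", "prospective"),
                           scale = "fisher")
  sameCells <- c(d[1, 2], d[3, 4])       # same-category cross-relevance
  diffCells <- c(d[1, 4], d[2, 3])
  expect_equal(ct$sameCategoryMean, mean(-atanh(1 - sameCells)))
  expect_equal(ct$diffCategoryMean, mean(-atanh(1 - diffCells)))
})
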