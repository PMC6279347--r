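test_that("generalization matrix diagonal reproduces the timecourse", {
  ds <- strongSignalDataset("exp1", nVoxels = 8, noiseSd = 1.2, seed = 4)
  sub <- c(4, 8)
  scheme <- decodingScheme("current")
  gm <- crossTemporalMatrix(ds, scheme, trs = sub)
  tc <- decodeTimecourse(ds, scheme, trs = sub)
  expect_equal(diag(accuracy(gm)), accuracy(tc)[sub],
               ignore_attr = TRUE)
  expect_equal(dim(accuracy(gm)), c(2L, 2L))
})

test_that("time-constant high-SNR signal generalizes across all TRs", {
  ds <- strongSignalDataset("exp1", nVoxels = 10, noiseSd = 0.01, seed = 6)
  gm <- crossTemporalMatrix(ds, decodingScheme("current"), trs = c(2, 9, 14))
  expect_true(all(accuracy(gm) == 1))
})

test_that("a planted block is recovered as one significant cluster", {
  set.seed(5)
  n <- 12
  mats <- lapply(1:n, function(i) {
    m <- matrix(rnorm(100, mean = 1 / 3, sd = 0.05), 10, 10)
    m[4:6, 4:6] <- m[4:6, 4:6] + 0.3
    m
  })
  res <- clusterPermutation2d(mats, chance = 1 / 3, tail = "positive",
                              nPerm = 1000, seed = 3)
  sig <- Filter(function(cl) cl$significant, clusters(res))
  expect_equal(length(sig), 1L)
  cells <- sig[[1]]$cells
  # the planted 3x3 block is fully contained; at most a couple of adjacent
  # noise cells may join it
  expect_true(all(paste(rep(4:6, each = 3), rep(4:6, 3)) %in%
                    paste(cells[, 1], cells[, 2])))
  expect_lte(nrow(cells), 12L)
  expect_true(all(vapply(clusters(res), function(cl) cl$p, numeric(1)) > 0))
})

test_that("exhaustive enumeration matches an independent sign-flip oracle", {
  set.seed(11)
  n <- 5
  mats <- lapply(1:n, function(i) matrix(rnorm(16, 0.4, 0.15), 4, 4))
  res <- clusterPermutation2d(mats, chance = 1 / 3, tail = "positive",
                              nPerm = 10000, seed = 1)
  expect_true(res@exhaustive)
  expect_equal(res@nPerm, 32)
  # oracle: enumerate all 2^5 assignments by hand
  D <- t(sapply(mats, function(m) as.numeric(m) - 1 / 3))
  thr <- qt(0.95, n - 1)
  tOf <- function(Dm) {
    mu <- colMeans(Dm); v <- apply(Dm, 2, var)
    mu / sqrt(v / n)
  }
  nullMax <- sapply(0:31, function(code) {
    signs <- ifelse(bitwAnd(code, 2^(0:4)) > 0, -1, 1)
    oracleMaxMass(matrix(tOf(D * signs), 4, 4), thr)
  })
  for (cl in clusters(res)) {
    expect_equal(cl$p, mean(nullMax >= cl$mass))
  }
  # Monte-Carlo with forced sampling agrees closely but not by construction
  resMc <- clusterPermutation2d(mats, chance = 1 / 3, tail = "positive",
                                nPerm = 4000, seed = 2, exact = FALSE)
  expect_false(resMc@exhaustive)
  for (i in seq_along(clusters(res)))
    expect_lt(abs(clusters(resMc)[[i]]$p - clusters(res)[[i]]$p), 0.05)
})

test_that("permutation p-values use the +1 guard and inputs are validated", {
  set.seed(2)
  mats <- lapply(1:6, function(i) matrix(rnorm(9, 0.5, 0.1), 3, 3))
  res <- clusterPermutation2d(mats, chance = 1 / 3, nPerm = 50, seed = 1,
                              exact = FALSE, tail = "positive")
  ps <- vapply(clusters(res), function(cl) cl$p, numeric(1))
  expect_true(all(ps >= 1 / 51))
  expect_error(clusterPermutation2d(mats, 1 / 3, nPerm = 0), "nPerm")
  expect_error(clusterPermutation2d(mats[1], 1 / 3), "subjects")
  expect_error(clusterPermutation2d(list(matrix(0, 2, 2), matrix(0, 3, 3)),
                                    1 / 3), "congruent")
})

test_that("zero-variance cells are excluded with a warning", {
  set.seed(3)
  mats <- lapply(1:6, function(i) {
    m <- matrix(rnorm(9, 0.5, 0.1), 3, 3)
    m[1, 1] <- 1 / 3    # identical across subjects
    m
  })
  expect_warning(
    res <- clusterPermutation2d(mats, 1 / 3, tail = "positive", nPerm = 64),
    "zero-variance")
  expect_true(is.na(res@tMap[1, 1]))
})

test_that("negative effects surface as negative-tail clusters (two-sided)", {
  set.seed(7)
  mats <- lapply(1:10, function(i) {
    m <- matrix(rnorm(64, 1 / 3, 0.04), 8, 8)
    m[6:8, 2:4] <- m[6:8, 2:4] - 0.25
    m
  })
  res <- clusterPermutation2d(mats, 1 / 3, tail = "two.sided", nPerm = 1024)
  sig <- Filter(function(cl) cl$significant, clusters(res))
  expect_true(any(vapply(sig, function(cl) cl$tail == "negative",
                         logical(1))))
  negCl <- sig[[which(vapply(sig, function(cl) cl$tail, character(1)) ==
                        "negative")[1]]]
  expect_lt(negCl$mass, 0)
})
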