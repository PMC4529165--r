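test_that("compute2C follows the internal-standard ratio and is homogeneous", {
  expect_equal(compute2C(500, 500, 2.5), 2.5)
  expect_equal(compute2C(243.4, 500, 2.5), 1.217)
  expect_error(compute2C(0, 500), "positive")
  expect_error(compute2C(500, -1), "positive")
  withr::with_seed(5, {
    for (r in 1:20) {
      m <- runif(1, 100, 900); s <- runif(1, 100, 900); c <- runif(1, 0.1, 10)
      expect_equal(compute2C(m * c, s * c), compute2C(m, s))
    }
  })
})

test_that("pg-to-Mbp conversion matches the 978 Mbp/pg constant", {
  expect_equal(pgToMbp(1), 978)
  expect_equal(pgToMbp(2) / 2, 978)
  expect_equal(pgToMbp(0.6085), 595.113)
  expect_equal(monoploidMbp(1.217), 595L)  # 1Cx = 0.6085 pg
  expect_equal(monoploidMbp(1.772), 867L)  # rounds half-up from 866.5
  expect_equal(pgToMbp(c(1, 2)), c(978, 1956))
  expect_error(pgToMbp(-1), ">= 0")
})

test_that("aggregateReplicates averages plants first, then accessions", {
  r <- aggregateReplicates(list(p1 = c(1.2, 1.2, 1.2), p2 = c(1.2, 1.2, 1.2),
                                p3 = c(1.2, 1.2, 1.2)))
  expect_equal(r$two_c_pg, 1.2)
  expect_equal(r$sd_pg, 0)
  r2 <- aggregateReplicates(list(a = 1.30, b = 1.31, c = 1.32))
  expect_equal(r2$two_c_pg, 1.31)
  expect_equal(r2$sd_pg, 0.01)
  r3 <- aggregateReplicates(list(only = 1.5))
  expect_equal(r3$two_c_pg, 1.5)
  expect_equal(r3$sd_pg, 0)
  expect_equal(r3$n_plants, 1L)
  # plant means first: unbalanced measurements must not skew the mean
  r4 <- aggregateReplicates(list(p1 = c(1.0, 1.0, 1.0, 1.0), p2 = 2.0))
  expect_equal(r4$two_c_pg, 1.5)
  expect_error(aggregateReplicates(list()), "invalid input")
})

test_that("reconstructReplicates preserves the summary statistics exactly", {
  for (n in c(3, 9)) {
    v <- reconstructReplicates(1.31, 0.013, n)
    expect_equal(mean(v), 1.31)
    expect_equal(sd(v), 0.013)
    expect_length(v, n)
  }
  expect_error(reconstructReplicates(1, 1, 4), "multiple of 3")
})

test_that("detectG1Peaks recovers synthetic Gaussian peaks", {
  h1 <- gaussianHistogram(200, 4, 1)  # cv 2%
  p1 <- detectG1Peaks(h1, 1)
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$mean - 200), 1)
  expect_lt(abs(p1$cv - 2), 0.5)

  h2 <- gaussianHistogram(c(200, 411), c(4, 8.2), c(1, 1))
  p2 <- detectG1Peaks(h2, 2)
  expect_equal(nrow(p2), 2L)
  expect_lt(abs(p2$mean[1] - 200), 1)
  expect_lt(abs(p2$mean[2] - 411), 1)
  expect_lte(sum(p2$nuclei), sum(histCounts(h2)))

  expect_error(detectG1Peaks(FluorHistogram(0:10, rep(0, 10)), 1),
               "invalid input")
  expect_error(detectG1Peaks(h1, 3), "peaks unresolved")
})

test_that("flow pipeline recovers the generating 2C within 1% at cv <= 3", {
  for (seed in 1:4) {
    for (cv in c(2, 3)) {
      sim <- genFlowHistogram(true2C = 1.217, cv = cv, seed = seed)
      est <- estimate2C(sim$histogram)
      expect_lt(abs(est$two_c_pg - 1.217) / 1.217, 0.01)
    }
  }
  sim <- genFlowHistogram(true2C = 1.772, cv = 2, seed = 9)
  expect_lt(abs(estimate2C(sim$histogram)$two_c_pg - 1.772) / 1.772, 0.01)
})

test_that("bonferroniLetterGroups is a valid compact letter display", {
  same <- bonferroniLetterGroups(list(a = c(1, 1.01, 0.99),
                                      b = c(1, 1.01, 0.99)))
  expect_equal(same$letters, c("A", "A"))

  far <- bonferroniLetterGroups(list(a = 1 + c(-0.01, 0, 0.01),
                                     b = 10 + c(-0.01, 0, 0.01),
                                     c = 100 + c(-0.01, 0, 0.01)))
  expect_equal(far$letters, c("A", "B", "C"))

  # letters shared iff pairwise test non-significant, random panels
  withr::with_seed(21, {
    for (r in 1:8) {
      k <- sample(3:6, 1)
      vals <- setNames(lapply(seq_len(k), function(i)
        rnorm(3, mean = sample(c(0, 0.05, 1, 5), 1), sd = 0.05)),
        paste0("g", seq_len(k)))
      out <- bonferroniLetterGroups(vals, alpha = 0.05)
      sig <- attr(out, "significant")
      lets <- strsplit(setNames(out$letters, out$label), "")
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        ni <- names(vals)[i]; nj <- names(vals)[j]
        shares <- length(intersect(lets[[ni]], lets[[nj]])) > 0
        expect_equal(shares, !sig[ni, nj])
      }
    }
  })
  expect_error(bonferroniLetterGroups(list(a = 1, b = c(1, 2))),
               "cannot test")
})

test_that("spearmanR matches a brute-force rank oracle", {
  expect_equal(spearmanR(1:3, 3:1), -1)
  expect_equal(spearmanR(1:5, 1:5), 1)
  withr::with_seed(33, {
    for (r in 1:15) {
      n <- sample(5:25, 1)
      x <- sample(1:4, n, replace = TRUE)       # heavy ties
      y <- rnorm(n) + x
      if (sd(x) == 0) next
      expect_equal(spearmanR(x, y), bruteSpearman(x, y), tolerance = 1e-12)
    }
  })
  # two tied levels in x perfectly separating the y ranks
  x <- c(1, 1, 1, 2, 2, 2)
  y <- c(5, 6, 7, 50, 60, 70)
  expect_equal(spearmanR(x, y), bruteSpearman(x, y), tolerance = 1e-12)
  expect_error(spearmanR(1:3, 1:4), "length mismatch")
  expect_error(spearmanR(c(1, 1, 1), 1:3), "constant")
})

test_that("relativeVariation matches its definition", {
  expect_equal(relativeVariation(c(1, 2)), 100)
  expect_equal(round(relativeVariation(c(1.390, 1.5, 1.772)), 1), 27.5)
  expect_error(relativeVariation(1.5), ">= 2")
})
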