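test_that("dispersion estimation recovers known truth", {
  withr::with_seed(51, {
    libs <- sprintf("l%02d", 1:8)
    groups <- setNames(rep(c("a", "b"), each = 4), libs)

    # Poisson truth: the common estimate collapses toward zero
    pois <- counts_tbl(matrix(rpois(800 * 8, 100), 800,
                              dimnames = list(sprintf("g%03d", 1:800), libs)))
    est0 <- estimate_dispersion(pois, groups)
    expect_lt(est0$common, 0.05)

    # NB truth 0.4: the common estimate lands nearby
    nb <- counts_tbl(matrix(rnbinom(2000 * 8, mu = 100, size = 2.5), 2000,
                            dimnames = list(sprintf("g%04d", 1:2000), libs)))
    est <- estimate_dispersion(nb, groups)
    expect_gt(est$common, 0.3)
    expect_lt(est$common, 0.5)

    # very large shrinkage pulls every tagwise value onto the common one
    heavy <- estimate_dispersion(nb[1:100, ], groups, shrinkage_weight = 1e6)
    expect_true(all(abs(heavy$tagwise - heavy$common) < 0.01))

    zero <- counts_tbl(matrix(0, 3, 8, dimnames = list(c("a", "b", "c"), libs)))
    expect_error(estimate_dispersion(zero, groups), "zero")
  })
})

test_that("the exact test collapses to the binomial at zero dispersion", {
  libs <- sprintf("l%d", 1:8)
  cases <- list(c(3, 10), c(7, 2), c(0, 5), c(12, 12))
  for (cs in cases) {
    m <- matrix(0, 1, 8, dimnames = list("g1", libs))
    m[1, 1] <- cs[1]; m[1, 5] <- cs[2]
    de <- exact_test(counts_tbl(m), libs[1:4], libs[5:8], dispersion = 0)
    want <- stats::binom.test(cs[1], sum(cs), 0.5)$p.value
    expect_equal(de$p_value, want, tolerance = 1e-12)
  }
  # unequal group sizes change the binomial probability accordingly
  m <- matrix(0, 1, 8, dimnames = list("g1", libs))
  m[1, 1] <- 4; m[1, 3] <- 9
  de <- exact_test(counts_tbl(m), libs[1:2], libs[3:8], dispersion = 0)
  expect_equal(de$p_value, stats::binom.test(4, 13, 2 / 8)$p.value,
               tolerance = 1e-12)
})

test_that("the exact test equals brute-force conditional enumeration", {
  # independent oracle: enumerate every per-library count vector with the
  # observed total and NB weights (the mean parameter cancels)
  brute_p <- function(zA, zB, nA, nB, phi) {
    t <- zA + zB; r <- 1 / phi
    grid <- as.matrix(expand.grid(rep(list(0:t), nA + nB - 1)))
    last <- t - rowSums(grid)
    keep <- last >= 0
    comp <- cbind(grid[keep, , drop = FALSE], last[keep])
    w <- exp(rowSums(lgamma(comp + r) - lgamma(comp + 1)))
    zAs <- rowSums(comp[, seq_len(nA), drop = FALSE])
    pz <- tapply(w, zAs, sum); pz <- pz / sum(pz)
    p_obs <- pz[as.character(zA)]
    sum(pz[pz <= p_obs * (1 + 1e-7)])
  }
  libs <- sprintf("l%d", 1:4)
  for (cs in list(c(3, 12), c(0, 8), c(10, 10), c(14, 2))) {
    m <- matrix(0, 1, 4, dimnames = list("g1", libs))
    m[1, 1] <- cs[1]; m[1, 3] <- cs[2]
    de <- exact_test(counts_tbl(m), libs[1:2], libs[3:4], dispersion = 0.5)
    expect_equal(de$p_value, unname(brute_p(cs[1], cs[2], 2, 2, 0.5)),
                 tolerance = 1e-10)
  }
})

test_that("exact test symmetry, zero genes and fold-change sign conventions", {
  libs <- sprintf("l%d", 1:8)
  withr::with_seed(52, {
    m <- matrix(rnbinom(50 * 8, mu = 60, size = 5), 50,
                dimnames = list(sprintf("g%02d", 1:50), libs))
    m[1, ] <- 0 # all-zero gene: p = 1, log2FC = 0 by contract
    ab <- exact_test(counts_tbl(m), libs[1:4], libs[5:8], 0.2)
    ba <- exact_test(counts_tbl(m), libs[5:8], libs[1:4], 0.2)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$log2_fc, -ba$log2_fc, tolerance = 1e-12)
    expect_equal(ab$p_value[1], 1)
    expect_equal(ab$log2_fc[1], 0)
    # perfectly symmetric counts give p = 1
    sym <- matrix(c(5, 7, 5, 7), 1, dimnames = list("g", sprintf("s%d", 1:4)))
    de <- exact_test(counts_tbl(sym), c("s1", "s2"), c("s3", "s4"), 0.3)
    expect_equal(de$p_value, 1)
  })
  expect_error(exact_test(counts_tbl(matrix(1, 1, 2, dimnames = list("g", c("a", "b")))),
                          "a", "a", 0.1), "disjoint")
})

test_that("BH adjustment reproduces hand step-up values and is order-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5, 0.9, 1.0)), c(0.004, 1, 1, 1))
  withr::with_seed(53, {
    p <- runif(30)
    perm <- sample(30)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("population-specific classification partitions genes correctly", {
  mk <- function(lfc, fdr) {
    tibble::tibble(
      gene_id = sprintf("g%d", seq_along(lfc)), log2_fc = lfc,
      p_value = fdr, fdr = fdr,
      direction = ifelse(fdr < 0.05, ifelse(lfc > 0, "up", "down"), "ns")
    )
  }
  lake <- mk(c(2, -1, 3, 0.5), c(0.01, 0.02, 0.03, 0.60))
  river <- mk(c(1, 0.2, 2.5, -2), c(0.60, 0.50, 0.01, 0.01))
  got <- classify_population_specific(lake, river)
  expect_equal(got$lake_only_up, "g1")
  expect_equal(got$lake_only_down, "g2")
  expect_equal(got$river_only_down, "g4")
  expect_equal(got$shared_up, "g3")
  expect_length(intersect(got$lake_only_up, got$shared_up), 0)

  empty <- classify_population_specific(lake[0, ], river[0, ])
  expect_true(all(lengths(unclass(empty)) == 0))
  expect_error(classify_population_specific(lake, river[1:3, ]), "universe")
})

test_that("chi-squared contrast matches the closed form", {
  got <- chisq_2x2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(got$chi2, 20)
  expect_equal(got$p_value, stats::pchisq(20, 1, lower.tail = FALSE))

  flat <- chisq_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(chisq_2x2(matrix(c(7, 7, 3, 3), 2))$chi2, 0) # proportional rows
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Mann-Whitney U gives the exact enumeration p for small samples", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$u, 0)
  expect_equal(got$p_value, 0.1) # 2 / C(6,3) labelings as extreme
  shift <- mann_whitney(1:10 + 1000, 1:10)
  expect_lt(shift$p_value, 0.001)
  same <- mann_whitney(rep(1:3, 4), rep(1:3, 4))
  expect_gt(same$p_value, 0.9)
})

test_that("type-I error of raw p-values sits at the nominal level", {
  libs <- sprintf("l%d", 1:8)
  fr <- vapply(1:20, function(s) {
    withr::with_seed(6000 + s, {
      cnt <- null_counts(1000, libs)
      mean(exact_test(cnt, libs[1:4], libs[5:8], 0.2)$p_value < 0.05)
    })
  }, numeric(1))
  n_total <- 20 * 1000
  bound <- 2.576 * sqrt(0.05 * 0.95 / n_total)
  expect_gte(mean(fr), 0.05 - bound)
  expect_lte(mean(fr), 0.05 + bound)
})

test_that("a four-fold change is detected with high power", {
  libs <- sprintf("l%d", 1:8)
  hit <- vapply(1:10, function(s) {
    withr::with_seed(7000 + s, {
      m <- matrix(rnbinom(200 * 8, mu = 100, size = 5), 200,
                  dimnames = list(sprintf("g%03d", 1:200), libs))
      m[1:20, 1:4] <- rnbinom(20 * 4, mu = 400, size = 5)
      de <- exact_test(counts_tbl(m), libs[1:4], libs[5:8], 0.2)
      mean(de$fdr[1:20] < 0.05)
    })
  }, numeric(1))
  expect_gt(mean(hit), 0.8)
})
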