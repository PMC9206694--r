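test_that("information component matches an independent high-precision oracle", {
  # expected values computed with a 50-digit evaluation of
  # log2((O + 1/2) / (Nd*Ne/Nt + 1/2)) and frozen
  grid <- rbind(
    c(1, 100, 100, 10000, 0.0),
    c(0, 1500, 500, 100000, -4.0),
    c(20, 1000, 200, 100000, 3.0356239097307213),
    c(0, 1, 1, 1, -1.5849625007211562),
    c(1, 1, 1, 1, 0.0),
    c(2, 10, 5, 100, 1.3219280948873623),
    c(3, 50, 40, 500, -0.36257007938470826),
    c(5, 200, 100, 5000, 0.28950661719498489),
    c(7, 77, 49, 1234, 1.0760120503352159),
    c(10, 1000, 1000, 100000, 0.0),
    c(12, 60, 80, 600, 0.55639334852438529),
    c(25, 500, 300, 20000, 1.6724253419714956),
    c(50, 5000, 400, 1000000, 4.3362833878644324),
    c(100, 2000, 3000, 50000, -0.261837645051033),
    c(250, 10000, 5000, 2000000, 3.2962414512237128),
    c(1000, 50000, 3547, 9000000, 5.629825337779799),
    c(1722, 123000, 3547, 20000000, 6.2704077862114804),
    c(0, 3, 2, 7, -1.4405725913859814),
    c(4, 4, 4, 4, 0.0),
    c(33, 333, 444, 55555, 3.4055426661687088)
  )
  got <- information_component(grid[, 1], grid[, 2], grid[, 3], grid[, 4])
  expect_equal(got, grid[, 5], tolerance = 1e-12)
  # observed equal to expected gives exactly zero; the power-of-two case -4
  expect_identical(information_component(1, 100, 100, 10000), 0)
  expect_identical(information_component(0, 1500, 500, 100000), -4)
})

test_that("count validation rejects impossible contingencies", {
  expect_error(information_component(5, 3, 10, 100),
               class = "icscreen_validation_error")
  expect_error(information_component(1, 1, 1, 0),
               class = "icscreen_validation_error")
  expect_error(information_component(-1, 1, 1, 10),
               class = "icscreen_validation_error")
  expect_error(ic_credibility_bound(1, 10, 10, 100, tail = 1.2),
               class = "icscreen_domain_error")
})

test_that("gamma credibility bound matches a Monte-Carlo posterior oracle", {
  # oracle: empirical quantiles of 10^6 draws from Gamma(O + 0.5, E + 0.5)
  set.seed(424243)
  for (O in c(0, 1, 5, 20, 100)) {
    for (E in c(0.1, 1, 10, 100)) {
      nt <- 1e6
      nd <- 1000 * E   # margins realising this expected count
      ne <- 1000
      draws <- rgamma(1e6, shape = O + 0.5, rate = E + 0.5)
      mc <- log2(quantile(draws, c(0.025, 0.975), names = FALSE))
      expect_equal(ic_credibility_bound(O, nd, ne, nt, 0.025), mc[1],
                   tolerance = 0.01)
      expect_equal(ic_credibility_bound(O, nd, ne, nt, 0.975), mc[2],
                   tolerance = 0.01)
    }
  }
})

test_that("credibility bounds bracket the point estimate", {
  set.seed(99)
  for (i in 1:50) {
    nt <- sample(1000:100000, 1)
    ne <- sample(1:500, 1)
    ndr <- sample(1:min(5000, nt), 1)
    o <- sample(0:min(ne, ndr), 1)
    ic <- information_component(o, ndr, ne, nt)
    lo <- ic_credibility_bound(o, ndr, ne, nt, 0.025)
    hi <- ic_credibility_bound(o, ndr, ne, nt, 0.975)
    expect_lt(lo, ic)
    expect_gt(hi, ic)
  }
})

test_that("IC is monotone in the counts", {
  # strictly increasing in n_observed at fixed margins
  ics <- information_component(0:50, 100, 60, 10000)
  expect_true(all(diff(ics) > 0))
  # strictly decreasing in n_effect at fixed n_observed, n_drug, n_total
  ics2 <- information_component(10, 100, 10:500, 10000)
  expect_true(all(diff(ics2) < 0))
  # the lower bound increases when O doubles at fixed E = 2
  b10 <- ic_credibility_bound(10, 200, 100, 10000, 0.025)
  b20 <- ic_credibility_bound(20, 200, 100, 10000, 0.025)
  expect_gt(b20, b10)
})

test_that("an O = 0 drug can never be significant", {
  for (E in c(0, 0.01, 1, 50)) {
    expect_lt(ic_credibility_bound(0, 1000 * E, 1000, 1e6, 0.025), 0)
  }
})

test_that("ic025 approaches log2(R) for large counts at fixed ratio", {
  b <- ic_credibility_bound(10000, 100000, 125000, 1e7, 0.025)  # E = 1250, R = 8
  expect_gte(b, 2.9)
  expect_lte(b, 3.0)
})

test_that("the closed-form approximation tracks the exact gamma bound", {
  for (O in c(5, 20, 100, 1000)) {
    E <- O / 4
    exact <- ic_credibility_bound(O, 1000 * E, 1000, 1e6, 0.025)
    approx <- ic_credibility_bound(O, 1000 * E, 1000, 1e6, 0.025,
                                   method = "approx")
    expect_equal(approx, exact, tolerance = 0.15)
  }
  expect_error(
    ic_credibility_bound(5, 100, 100, 1000, tail = 0.5, method = "approx"),
    class = "icscreen_domain_error")
})

test_that("ic_stats appends the derived columns and the significance flag", {
  counts <- tibble::tibble(n_observed = c(0, 20), n_drug = c(10, 1000),
                           n_effect = c(5, 200), n_total = c(100, 100000))
  out <- ic_stats(counts)
  expect_equal(out$expected, c(0.5, 2))
  expect_equal(out$significant, out$ic025 > 0)
  expect_true(all(out$ic025 < out$ic & out$ic < out$ic975))
})
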