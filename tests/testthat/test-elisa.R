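test_that("dilution series follow the closed form and reject bad parameters", {
  expect_equal(make_dilution_series(1000, 4, 3), c(1000, 250, 62.5))
  expect_equal(make_dilution_series(1000, 4, 6)[6], 1000 / 4^5)  # 0.9765625
  expect_error(make_dilution_series(1000, 1, 4), "factor")
  expect_error(make_dilution_series(-5, 4, 4), "start_ng")
  expect_error(make_dilution_series(1000, 4, 1), "n_points")
})

test_that("series validation enforces descending constant-ratio amounts and non-negative ODs", {
  expect_error(elisa_series("m", c(250, 1000, 62.5), list(1, 1, 1)),
               "decreasing")
  expect_error(elisa_series("m", c(1000, 500, 62.5), list(1, 1, 1)),
               "constant-ratio")
  expect_error(elisa_series("m", c(1000, 250), list(1, -0.1)), ">= 0")
})

test_that("a curve that never reaches the threshold is censored as '>1000'", {
  amounts <- make_dilution_series(1000, 4, 6)
  s <- elisa_series("weak", amounts, lapply(amounts, function(a) c(0.02, 0.03)))
  r <- binding_threshold(s, od_threshold = 0.2)
  expect_identical(r$censored, "above")
  expect_identical(r$display, ">1000")
  expect_true(is.na(r$threshold_ng))
})

test_that("an exact grid crossing needs no interpolation; saturated curves censor below", {
  amounts <- make_dilution_series(1000, 4, 3)   # 1000, 250, 62.5
  ods <- list(`1000` = c(1.0, 1.0), `250` = c(0.2, 0.2), `62.5` = c(0.1, 0.1))
  r <- binding_threshold(elisa_series("m", amounts, unname(ods)), 0.2)
  expect_equal(r$threshold_ng, 250)
  sat <- elisa_series("hot", amounts, list(c(3), c(3), c(3)))
  r2 <- binding_threshold(sat, 0.2)
  expect_identical(r2$censored, "below")
  expect_identical(r2$display, "<62.5")
})

test_that("interpolated thresholds track the analytic crossing of a saturation curve", {
  od_max <- 3; K <- 100; t <- 0.5
  amounts <- make_dilution_series(1000, 4, 6)
  ods <- lapply(amounts, function(a) rep(od_max * a / (a + K), 2))
  r <- binding_threshold(elisa_series("m", amounts, ods), t)
  analytic <- K * t / (od_max - t)              # 20 ng
  expect_lt(abs(r$threshold_ng - analytic) / analytic, 0.1)
  # interpolation stays inside its bracketing grid amounts
  bracket <- range(amounts[c(max(which(amounts >= r$threshold_ng)),
                             min(which(amounts <= r$threshold_ng)))])
  expect_true(r$threshold_ng >= bracket[1] && r$threshold_ng <= bracket[2])
})

test_that("on a fine dilution grid the threshold matches a brute-force crossing search within 1%", {
  od_max <- 3; K <- 100; t <- 0.5
  amounts <- 1000 / 1.05^(0:120)
  ods <- lapply(amounts, function(a) rep(od_max * a / (a + K), 2))
  r <- binding_threshold(elisa_series("m", amounts, ods), t)
  # oracle: scan a very fine grid of amounts for the first threshold crossing
  grid <- exp(seq(log(min(amounts)), log(max(amounts)), length.out = 200000))
  oracle <- grid[which(od_max * grid / (grid + K) >= t)[1]]
  expect_lt(abs(r$threshold_ng - oracle) / oracle, 0.01)
})

test_that("replicate duplication does not change the threshold and richer curves bind earlier", {
  amounts <- make_dilution_series(1000, 4, 6)
  odA <- lapply(amounts, function(a) rep(3 * a / (a + 150), 2))
  odB <- lapply(amounts, function(a) rep(3 * a / (a + 15), 2))
  rA <- binding_threshold(elisa_series("A", amounts, odA), 0.4)
  rB <- binding_threshold(elisa_series("B", amounts, odB), 0.4)
  expect_lt(rB$threshold_ng, rA$threshold_ng)   # B's OD dominates A's
  odA2 <- lapply(odA, function(x) rep(x, 2))
  rA2 <- binding_threshold(elisa_series("A", amounts, odA2), 0.4)
  expect_equal(rA$threshold_ng, rA2$threshold_ng)
})

test_that("non-monotone curves use the lowest crossing and warn", {
  amounts <- make_dilution_series(1000, 4, 5)
  ods <- list(c(0.1), c(0.9), c(0.1), c(0.9), c(0.1))  # two crossings
  expect_warning(r <- binding_threshold(elisa_series("m", amounts, ods), 0.5),
                 "lowest amount")
  expect_lt(r$threshold_ng, amounts[4])   # below the first (lowest-amount) crossing
})

test_that("the control-based OD threshold follows mean + 3 sd with override", {
  expect_equal(od_threshold_from_controls(rep(0.05, 4)), 0.05)
  expect_equal(od_threshold_from_controls(c(0.04, 0.06)),
               0.05 + 3 * sd(c(0.04, 0.06)))    # ~0.0924
  expect_equal(od_threshold_from_controls(c(0.04, 0.06), override = 0.2), 0.2)
  expect_error(od_threshold_from_controls(0.05), ">= 2")
})

test_that("noise-free simulated thresholds rank opposite to true affinity", {
  b <- small_bundle()
  res <- elisa_thresholds(b$elisa, od_threshold = b$ground_truth$od_threshold)
  te <- b$ground_truth$elisa
  m <- merge(res, te, by = "mab_id")
  expect_identical(m$censored.x, m$censored.y)   # censoring states recovered
  un <- m[m$censored.x == "none", ]
  expect_true(cor(un$threshold_ng, un$true_affinity, method = "spearman") < 0)
  ranked <- un[order(un$true_affinity), ]
  expect_true(all(diff(ranked$threshold_ng) <= 1e-9))
})
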