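test_that("the spline reproduces affine knot data exactly on the grid", {
  cur <- fit_curve(c(10, 50, 200, 1000), 3 + 2 * c(10, 50, 200, 1000))
  expect_equal(cur$grid$value, 3 + 2 * cur$grid$size, tolerance = 1e-9)
  # zero interpolation error at the knots
  expect_equal(cur$interpolant(cur$knots$size), cur$knots$value,
               tolerance = 1e-9)
  expect_error(fit_curve(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_curve(c(1, 2, 2), c(1, 2, 3)), "ascending|duplicate")
})

test_that("the dense grid over 100..100,000 has exactly 99,901 points", {
  knots <- c(100, 200, 500, 1000, 2000, 5000, 10000, 20000, 50000, 100000)
  cur <- fit_curve(knots, log(knots))
  expect_identical(nrow(cur$grid), 99901L)
  expect_equal(cur$grid$size[1], 100)
  expect_equal(cur$grid$size[99901], 100000)
})

test_that("interior spline error on smooth data is small", {
  # knots on a cubic polynomial; interior grid deviation stays tiny
  f <- function(x) 1e-6 * x^3 - 2e-4 * x^2 + 0.1 * x + 5
  knots <- seq(100, 1000, by = 100)
  cur <- fit_curve(knots, f(knots))
  interior <- cur$grid$size >= 300 & cur$grid$size <= 800
  expect_lt(max(abs(cur$grid$value[interior] - f(cur$grid$size[interior]))),
            1e-2 * max(abs(f(knots))))
})

test_that("min_size_for scans the grid and respects monotonicity", {
  knots <- c(100, 200, 500, 1000, 2000)
  vals <- c(10, 18, 30, 40, 48) # monotone increasing
  cur <- fit_curve(knots, vals)
  # threshold at a knot value of a strictly increasing curve hits the knot
  est <- min_size_for(cur, 30, pool_total = 4000)
  expect_equal(est$minimum_size, 500)
  expect_equal(est$ratio, 500 / 4000)
  # brute-force scan oracle for an off-knot threshold
  est2 <- min_size_for(cur, 24)
  scan <- cur$grid$size[which(cur$grid$value >= 24)[1]]
  expect_equal(est2$minimum_size, scan)
  expect_gt(est2$minimum_size, 200); expect_lt(est2$minimum_size, 500)
  # monotone in the threshold
  sizes <- vapply(c(12, 20, 28, 36, 44), function(th)
    min_size_for(cur, th)$minimum_size, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # unattainable threshold
  miss <- min_size_for(cur, 60)
  expect_false(miss$attained)
  expect_true(is.na(miss$minimum_size))
})

test_that("peak_size equals the brute-force grid argmax", {
  # rise then fall: interior peak
  cur <- fit_curve(c(100, 500, 1000, 2000, 5000), c(5, 40, 60, 55, 20))
  pk <- peak_size(cur)
  expect_equal(pk$size, cur$grid$size[which.max(cur$grid$value)])
  expect_gt(pk$size, 500); expect_lt(pk$size, 2000)
  # monotone curve: peak at the last grid point
  mono <- fit_curve(c(10, 20, 40, 80), c(1, 2, 4, 8))
  expect_equal(peak_size(mono)$size, 80)
  # symmetric tent: peak at the center knot
  tent <- fit_curve(c(10, 20, 30), c(0, 10, 0))
  expect_equal(peak_size(tent)$size, 20)
})

test_that("coverage targets and table mirror the standard report layout", {
  tg <- coverage_targets(1000, 321.5)
  expect_equal(tg$value, c(50, 100, 321.5))
  expect_equal(tg$metric, c("richness", "richness", "true_diversity"))
  rich <- fit_curve(c(100, 500, 1000, 2000), c(30, 90, 140, 190))
  div <- fit_curve(c(100, 500, 1000, 2000), c(20, 60, 80, 70))
  tab <- coverage_table(rich, div, total_richness = 1000, overall_D = 75,
                        pool_total = 4000)
  expect_equal(tab$threshold_name,
               c("5% total richness", "10% total richness",
                 "Overall true diversity", "Maximum true diversity"))
  # 5% coverage needs fewer compounds than 10% on a monotone curve
  expect_lt(tab$minimum_size[1], tab$minimum_size[2])
  expect_true(all(tab$ratio_of_pool <= 1, na.rm = TRUE))
})
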