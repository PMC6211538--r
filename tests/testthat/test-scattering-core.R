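# Debye sums, amplitudes, rg and theoretical p(r).

test_that("single- and two-point form factors match closed forms", {
  b <- 1e-12
  one <- point_set(0, 0, 0, b)
  q <- seq(0, 0.5, by = 0.01)
  ff1 <- form_factor(one, q)
  expect_equal(ff1$P, rep(b^2, length(q)))
  expect_equal(ff1$A00, rep(b, length(q)))
  expect_equal(ff1$beta, rep(1, length(q)))

  d <- 50
  two <- make_assembly(synthetic_spec("two_points", distance = d,
                                      b_per_point = b))
  ff2 <- form_factor(two, q)
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  expect_equal(ff2$P, 2 * b^2 * (1 + sinc(q * d)), tolerance = 1e-12)
  expect_equal(ff2$A00, 2 * b * sinc(q * d / 2), tolerance = 1e-12)
  # forward limit for arbitrary sets
  ps <- make_assembly(synthetic_spec("sphere", radius = 30, n_points = 50,
                                     seed = 9))
  expect_equal(form_factor(ps, c(0, 0.1))$P[1], attr(ps, "total_b")^2)
})

test_that("beta lies in [0, 1] on a dense grid and equals A00^2/P", {
  q <- seq(0, 1, by = 0.002)
  for (sh in c("two_points", "sphere", "mock_receptor")) {
    ps <- make_assembly(synthetic_spec(sh, radius = 35, distance = 40,
                                       n_points = 120, seed = 5))
    ff <- form_factor(ps, q)
    expect_true(all(ff$beta <= 1 + 1e-9))
    expect_true(all(ff$beta >= 0))
    expect_equal(ff$beta[1], 1, tolerance = 1e-12)
    expect_equal(ff$beta, ff$A00^2 / ff$P, tolerance = 1e-9)
  }
})

test_that("radius of gyration reproduces shell and solid-ball identities", {
  R <- 42
  shell <- make_assembly(synthetic_spec("shell", radius = R, n_points = 500,
                                        seed = 2))
  # rg is taken about the sampled centroid, which sits ~R/sqrt(n) off the
  # true center for a finite random shell
  expect_equal(radius_of_gyration(shell), R, tolerance = 1e-3)

  # deterministic fine-grid sampling of a homogeneous ball
  g <- seq(-50, 50, by = 2.5)
  gr <- expand.grid(x = g, y = g, z = g)
  gr <- gr[gr$x^2 + gr$y^2 + gr$z^2 <= 50^2, ]
  ball <- point_set(gr$x, gr$y, gr$z, rep(1e-13, nrow(gr)))
  expect_equal(radius_of_gyration(ball), sqrt(3 / 5) * 50, tolerance = 0.01)

  same <- point_set(rep(1, 5), rep(2, 5), rep(3, 5), rep(1e-13, 5))
  expect_equal(radius_of_gyration(same), 0)
})

test_that("two-point p(r) occupies one bin with dmax at the separation", {
  two <- make_assembly(synthetic_spec("two_points", distance = 50))
  pr <- theoretical_pr(two, bin_width = 1)
  expect_equal(sum(pr$p > 0), 1)
  expect_lt(abs(pr$r[pr$p > 0] - 50), 1)       # bin center holding d = 50
  expect_lt(abs(attr(pr, "dmax") - 50), 1.51)  # within a bin of the truth
  expect_error(theoretical_pr(point_set(0, 0, 0, 1e-12)), "two points")
})

test_that("Debye sum and p(r) sine transform are a transform pair", {
  q <- seq(0, 0.3, by = 0.01)
  ps <- make_assembly(synthetic_spec("sphere", radius = 40, n_points = 300,
                                     seed = 7))
  ff <- form_factor(ps, q, method = "exact")
  pr <- theoretical_pr(ps, bin_width = 0.02)
  expect_lt(max(abs(pr_to_iq(pr, q) - ff$P) / ff$P), 1e-3)
  # rg routes agree
  expect_equal(attr(pr, "rg"), radius_of_gyration(ps), tolerance = 1e-9)
  expect_equal(attr(pr, "i0"), attr(ps, "total_b")^2)
})

test_that("histogram acceleration matches the exact double sum to 1e-4", {
  ps <- make_assembly(synthetic_spec("sphere", radius = 50, n_points = 600,
                                     seed = 3))
  q <- seq(0, 0.3, by = 0.01)
  fe <- form_factor(ps, q, method = "exact")
  fh <- form_factor(ps, q, method = "histogram")
  expect_lt(max(abs(fh$P - fe$P) / fe$P), 1e-4)
})

test_that("scaling b scales P and A00 but not beta, rg or dmax", {
  ps <- make_assembly(synthetic_spec("mock_receptor", n_points = 150,
                                     seed = 4))
  c2 <- 3.7
  ps2 <- point_set(ps$x, ps$y, ps$z, c2 * ps$b)
  q <- seq(0, 0.3, by = 0.02)
  f1 <- form_factor(ps, q); f2 <- form_factor(ps2, q)
  expect_equal(f2$P, c2^2 * f1$P, tolerance = 1e-12)
  expect_equal(f2$A00, c2 * f1$A00, tolerance = 1e-12)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-9)
  expect_equal(radius_of_gyration(ps2), radius_of_gyration(ps))
  p1 <- theoretical_pr(ps); p2 <- theoretical_pr(ps2)
  expect_equal(attr(p1, "dmax"), attr(p2, "dmax"))
})

test_that("degenerate inputs are refused", {
  expect_error(form_factor(make_assembly(synthetic_spec("two_points")),
                           c(0.2, 0.1)), "increasing")
  zero <- point_set(c(0, 1), c(0, 0), c(0, 0), c(1e-12, -1e-12))
  expect_error(amplitude_A00(zero, 0.1), "zero")
})
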