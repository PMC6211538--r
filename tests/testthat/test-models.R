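# Mixture models 1-4: nesting identities, smearing, chi-square, fitting and
# F-tests.

ms <- function(id, ...) {
  mc <- mock_small_closed(); mo <- mock_small_open()
  comps <- if (id %in% c(3, 4)) list(closed = mc$ff, open = mo$ff)
           else list(closed = mc$ff)
  model_spec(id, comps, subunit_r = mc$r_sub,
             conc_n = molar_to_numdens(0.54e-6), ...)
}

test_that("models 2-4 collapse onto their nested special cases exactly", {
  q <- q_data_grid(60)
  p_base <- list(K = 1.2, B = 1e-6, rg_olig = 300, gamma = 0.02, alpha = 0.3)
  I1 <- model_intensity(ms(1), p_base, q)
  # gamma = 0: model 2 == model 1
  expect_equal(model_intensity(ms(2), modifyList(p_base, list(gamma = 0)), q),
               I1, tolerance = 1e-14)
  # alpha endpoints of model 3
  mo <- mock_small_open()
  I1_open <- model_intensity(model_spec(1, list(open = mo$ff),
                                        conc_n = molar_to_numdens(0.54e-6)),
                             p_base, q)
  expect_equal(model_intensity(ms(3), modifyList(p_base, list(alpha = 0)), q),
               I1, tolerance = 1e-14)
  expect_equal(model_intensity(ms(3), modifyList(p_base, list(alpha = 1)), q),
               I1_open, tolerance = 1e-14)
  # model 4 nesting chain
  expect_equal(model_intensity(ms(4), modifyList(p_base, list(gamma = 0)), q),
               model_intensity(ms(3), p_base, q), tolerance = 1e-14)
  expect_equal(model_intensity(ms(4), modifyList(p_base, list(alpha = 0)), q),
               model_intensity(ms(2), p_base, q), tolerance = 1e-14)
})

test_that("model evaluation refuses missing pieces and off-grid q", {
  expect_error(model_intensity(ms(1), list(K = 1), q_data_grid(10)),
               "missing parameter")
  expect_error(model_intensity(ms(1), list(K = 1, B = 0), c(0.1, 0.5)),
               "outside tabulated range")
  mc <- mock_small_closed()
  expect_error(model_spec(3, list(a = mc$ff),
                          conc_n = molar_to_numdens(1e-6)), "two components")
})

test_that("smearing preserves identities and adds widths in quadrature", {
  q <- seq(0, 0.4, by = 0.002)
  I <- exp(-(q - 0.2)^2 / (2 * 0.01^2))
  expect_identical(smear(I, q, rep(0, length(q))), I)
  flat <- rep(3.14, length(q))
  expect_equal(smear(flat, q, 0.01 * q), flat, tolerance = 1e-12)
  sm <- smear(I, q, rep(0.008, length(q)))
  mu <- sum(sm * q) / sum(sm)
  w <- sqrt(sum(sm * (q - mu)^2) / sum(sm))
  expect_equal(w, sqrt(0.01^2 + 0.008^2), tolerance = 0.02)
})

test_that("chi-square arithmetic and its null distribution are right", {
  q <- seq(0.01, 0.1, length.out = 10)
  cur <- sans_curve(q, rep(1, 10), rep(0.1, 10))
  expect_equal(chi_square(cur, rep(1, 10))$chi2, 0)
  off <- rep(1, 10); off[4] <- 1 + 2 * 0.1
  expect_equal(chi_square(cur, off)$chi2, 4, tolerance = 1e-12)
  # large-sample reduced chi2 -> 1
  set.seed(42)
  n <- 1e4
  qq <- seq_len(n) / n
  I <- rnorm(n, 10, 0.5)
  big <- sans_curve(qq, I, rep(0.5, n))
  cs <- chi_square(big, rep(10, n), n_params = 4)
  expect_equal(cs$chi2_reduced, 1, tolerance = 0.03)
  expect_equal(cs$dof, n - 4)
})

test_that("noise-free model-1 data are recovered to 1e-6 relative", {
  spec <- ms(1)
  q <- q_data_grid(80)
  truep <- list(K = 1.1, B = 0.02)
  I <- model_intensity(spec, truep, q)
  cur <- sans_curve(q, I, sigma = pmax(1e-12, 0.01 * abs(I)))
  f <- fit_model(spec, cur, start = list(K = 0.5, B = 0))
  expect_true(f$converged)
  expect_equal(f$params[["K"]], 1.1, tolerance = 1e-6)
  expect_equal(f$params[["B"]], 0.02, tolerance = 1e-6)
  expect_lt(f$chi2, 1e-10)
})

test_that("fits are deterministic and respect chi2 nesting monotonicity", {
  spec2 <- ms(2)
  q <- q_data_grid(100)
  cur <- simulate_curve(spec2, list(K = 1.05, B = 2e-7, rg_olig = 300,
                                    gamma = 0.015),
                        q, noise_spec(seed = 77))
  fa <- fit_model(spec2, cur, n_starts = 3, seed = 5)
  fb <- fit_model(spec2, cur, n_starts = 3, seed = 5)
  expect_identical(fa$params, fb$params)
  expect_identical(fa$chi2, fb$chi2)

  f1 <- fit_model(ms(1), cur)
  # complex models started from the simpler optimum can only improve chi2
  f2 <- fit_model(spec2, cur, start = as.list(f1$params))
  f3 <- fit_model(ms(3), cur, start = as.list(f1$params))
  f4 <- fit_model(ms(4), cur, start = as.list(f2$params))
  expect_lte(f2$chi2, f1$chi2 + 1e-9)
  expect_lte(f3$chi2, f1$chi2 + 1e-9)
  expect_lte(f4$chi2, f2$chi2 + 1e-9)
})

test_that("smearing leaves a flat background-only signal unchanged in fit", {
  spec <- ms(1)
  q <- q_data_grid(60)
  # background-dominated: K tiny
  I <- model_intensity(spec, list(K = 1e-6, B = 0.05), q)
  cur <- sans_curve(q, I, sigma = rep(1e-4, length(q)),
                    sigma_q = 0.1 * q / 2.355)
  f <- fit_model(spec, cur)
  expect_equal(f$params[["B"]], 0.05, tolerance = 1e-4)
})

test_that("F-test conventions: symmetric equal-parameter case and no-gain", {
  fake <- function(chi2, n_params, n = 100) {
    structure(list(chi2 = chi2, chi2_reduced = chi2 / (n - n_params),
                   dof = n - n_params, n_params = n_params, n_points = n),
              class = "sans_fit")
  }
  eq <- f_test(fake(100, 2), fake(100, 2))
  expect_equal(eq$mode, "variance")
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 0.5)   # one-sided upper tail at F = 1 on (f, f)
  ne <- f_test(fake(100, 2), fake(100, 4))
  expect_equal(ne$mode, "nested")
  expect_equal(ne$p, 1)
  expect_false(ne$significant)
  gain <- f_test(fake(200, 2), fake(100, 4))
  expect_lt(gain$p, 0.05)
  expect_error(f_test(fake(1, 2, 50), fake(1, 2, 60)), "same data")
})

test_that("fit reports serialize to JSON and a residual table", {
  spec <- ms(1)
  q <- q_data_grid(40)
  cur <- simulate_curve(spec, list(K = 1, B = 2e-7), q, noise_spec(seed = 3))
  f <- fit_model(spec, cur)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(f, cur, jf, tf)
  rep <- jsonlite::read_json(jf)
  expect_equal(rep$model_id, 1L)
  expect_equal(length(rep$params), 2)
  tab <- read.table(tf)
  expect_equal(nrow(tab), nrow(cur))
})
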