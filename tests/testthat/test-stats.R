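# Calibration, P/E-values, the cloud-filter estimate, staged filters,
# bias correction and boundary definition.

test_that("calibration is deterministic and location-equivariant", {
  p <- make_profile(30, seed = 50)
  c1 <- calibrate(p, n_samples = 200, rng_seed = 3)
  c2 <- calibrate(p, n_samples = 200, rng_seed = 3)
  expect_identical(c1$forward_tail, c2$forward_tail)
  expect_identical(c1$gapped_max, c2$gapped_max)
  # shifting all scores by +c shifts tau by +c and leaves the rate alone:
  # verified on the fitter itself
  set.seed(51)
  x <- rexp(2000, log(2))
  f1 <- cloudfb:::.fit_gpd_tail(sort(x)[1501:2000] - quantile(x, 0.75))
  f2 <- cloudfb:::.fit_gpd_tail(sort(x + 5)[1501:2000] -
                                  quantile(x + 5, 0.75))
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-9)
  expect_equal(f1$xi, f2$xi, tolerance = 1e-9)
  expect_error(calibrate(p, n_samples = 50), "n_samples")
})

test_that("the tail fitter recovers exponential parameters", {
  set.seed(52)
  x <- rexp(10000, log(2))        # lambda = ln 2, location 0
  tm <- 0.5
  t0 <- as.numeric(quantile(x, 1 - tm, type = 7))
  ft <- cloudfb:::.fit_gpd_tail(x[x > t0] - t0)
  tau <- if (abs(ft$xi) < 1e-8) t0 + ft$sigma * log(tm)
         else t0 + ft$sigma / ft$xi * (tm^ft$xi - 1)
  expect_lt(abs(tau - 0), 0.2)            # recovered location
  expect_lt(abs(1 / ft$sigma - log(2)), 0.1)  # recovered rate
  expect_lt(abs(ft$xi), 0.12)             # shape near zero
})

test_that("forward P-values behave like probabilities with closed-form tail", {
  p <- make_profile(30, seed = 53)
  cal <- calibrate(p, n_samples = 500, rng_seed = 4, tail_shape = 0)
  ft <- cal$forward_tail
  # boundary: P(tau) is 1 by construction of the location
  expect_equal(pvalue(ft$tau, cal, "forward"), 1, tolerance = 1e-9)
  # closed form at depth ln(1e4)/lambda below: P = 1e-4
  s4 <- ft$tau + log(1e4) / ft$lambda
  expect_equal(pvalue(s4, cal, "forward"), 1e-4, tolerance = 1e-12)
  # monotone nonincreasing, in (0, 1]
  s <- seq(ft$tau - 5, ft$tau + 30, by = 0.25)
  pv <- pvalue(s, cal, "forward")
  expect_true(all(diff(pv) <= 0))
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("empirical exceedance of fresh nulls matches fitted P-values", {
  p <- make_profile(30, seed = 54)
  cal <- calibrate(p, n_samples = 1000, rng_seed = 5)
  # fresh null sample
  prep <- cloudfb:::prep_profile(p)
  set.seed(55)
  seqs <- lapply(1:4000, function(i)
    sample.int(20, 100, replace = TRUE, prob = amino_alphabet()$background))
  fs <- cloudfb:::cpp_forward_score_batch(prep, seqs)
  # the error budget has two parts: binomial noise of the fresh sample
  # and the calibration's own fitting noise, which grows with the
  # extrapolation depth below the tail anchor (~30% relative at P = 0.01
  # for a 1000-sequence calibration)
  for (lev in c(0.1, 0.01)) {
    got <- mean(pvalue(fs, cal, "forward") <= lev)
    se <- sqrt(lev * (1 - lev) / 4000)
    expect_lt(abs(got - lev), 4 * se + 0.9 * lev)
  }
  # gapped-max nominal level at the seed filter threshold
  vs <- cloudfb:::cpp_viterbi_score_batch(prep, seqs)
  got <- mean(pvalue(vs, cal, "gapped_max") < 0.01)
  expect_lt(abs(got - 0.01), 3 * sqrt(0.01 * 0.99 / 4000) + 0.003)
})

test_that("null P-values are close to uniform in the calibrated tail", {
  p <- make_profile(30, seed = 56)
  cal <- calibrate(p, n_samples = 1000, rng_seed = 6)
  prep <- cloudfb:::prep_profile(p)
  set.seed(57)
  seqs <- lapply(1:10000, function(i)
    sample.int(20, 100, replace = TRUE, prob = amino_alphabet()$background))
  pv <- pvalue(cloudfb:::cpp_forward_score_batch(prep, seqs), cal,
               "forward")
  # restrict to the fitted tail region and compare with Uniform(0, tm)
  tm <- cal$forward_tail$tail_mass
  tail_p <- pv[pv < tm] / tm
  u <- seq_along(sort(tail_p)) / length(tail_p)
  ks <- max(abs(sort(tail_p) - u))
  expect_lt(ks, 0.05)
})

test_that("E-values scale P-values by database size and preserve ranks", {
  expect_equal(evalue(1e-4, 1000), 0.1)
  expect_equal(pvalue_from_evalue(0.05, 5000), 1e-5)
  p <- c(1e-6, 1e-4, 1e-2)
  expect_equal(order(evalue(p, 17)), order(p))       # rank preservation
  expect_true(all(evalue(1e-3, c(10, 100, 1000)) ==
                    c(0.01, 0.1, 1)))                # monotone in db size
})

test_that("the cloud-filter estimate follows the printed arithmetic", {
  cs <- cloud_scores(12, 9, 11, 8.5)
  expect_equal(cloud_filter_estimate(cs), 2.5 + max(9, 8.5) + 3)  # 14.5
  # both passes stopping at the seed anti-diagonals: Z = A = 0
  cs0 <- cloud_scores(7, 7, 6.5, 6.5)
  expect_equal(cloud_filter_estimate(cs0), max(7, 6.5))
  expect_error(cloud_scores(5, 6, 7, 7))  # best_fwd < best_infwd
  # pure-function property over random inputs
  set.seed(58)
  for (rep in 1:10000) {
    bf <- runif(1, -10, 40); z <- runif(1, 0, 15)
    bb <- runif(1, -10, 40); a <- runif(1, 0, 15)
    cs <- cloud_scores(bf, bf - z, bb, bb - a)
    est <- cloud_filter_estimate(cs)
    expect_identical(est, a + max(bf - z, bb - a) + z)
    expect_gte(est, max(cs$best_infwd, cs$best_inbkwd))
  }
})

test_that("staged filters label candidates with the first rejecting stage", {
  hits <- data.frame(
    seed_p = c(1e-3, 0.02, 1e-3, 1e-3, NA),
    cloud_p = c(1e-4, NA, 0.01, 1e-4, NA),
    forward_p = c(5e-5, NA, NA, 5e-4, 2e-5))
  out <- apply_filters(hits)
  expect_equal(out$stage, c("pass", "seed", "cloud", "forward", "pass"))
  expect_error(filter_thresholds(1e-4, 1e-3, 0.01))  # wrong ordering
})

test_that("bias correction is zero at background and positive for repeats", {
  # profile whose emissions equal the background: the posterior-weighted
  # emission distribution is the background itself
  m <- 10
  em <- matrix(rep(amino_alphabet()$background, each = m), m)
  tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.4, 0.6, 0.4, 0.6), each = m + 1),
               m + 1)
  p0 <- profile_hmm("bg", em, tr)
  t0 <- rand_target(12)
  post0 <- posterior_full(forward_full(p0, t0), backward_full(p0, t0))
  expect_equal(bias_correct(post0, p0, t0, 1, 12), 0, tolerance = 1e-6)

  # a peaked profile against a homopolymer of its dominant residue:
  # the aligned region is compositionally biased, correction positive
  set.seed(59)
  p1 <- make_profile(10, peak = 0.7)
  dom <- which.max(p1$match_emissions[1, ])
  t1 <- target_sequence("poly", rep(dom, 12))
  post1 <- posterior_full(forward_full(p1, t1), backward_full(p1, t1))
  expect_gt(bias_correct(post1, p1, t1, 1, 12), 0)

  # identical under full and full-coverage sparse posteriors
  L <- full_layout(p1$m, t1$n)
  spost <- sparse_posterior(sparse_forward(p1, t1, L),
                            sparse_backward(p1, t1, L))
  expect_equal(bias_correct(spost, p1, t1, 1, 12),
               bias_correct(post1, p1, t1, 1, 12), tolerance = 1e-9)
})

test_that("posterior boundaries track a sharp alignment and flag empties", {
  set.seed(60)
  pr <- planted_pair(m = 30, decoy_n = 40, divergence = 0.1)
  f <- forward_full(pr$profile, pr$target)
  b <- backward_full(pr$profile, pr$target)
  post <- posterior_full(f, b)
  bnd <- define_boundaries(post)
  expect_false(bnd$empty)
  # the inferred region overlaps the planted interval substantially
  ov <- min(bnd$tend, pr$end) - max(bnd$tstart, pr$start) + 1
  expect_gt(ov / (pr$end - pr$start + 1), 0.5)
  # full vs sparse agreement under full coverage
  L <- full_layout(pr$profile$m, pr$target$n)
  spost <- sparse_posterior(sparse_forward(pr$profile, pr$target, L),
                            sparse_backward(pr$profile, pr$target, L))
  bnd2 <- define_boundaries(spost)
  expect_equal(bnd2$tstart, bnd$tstart)
  expect_equal(bnd2$tend, bnd$tend)
  # near-zero posteriors flag an empty region
  fake <- list(B = rep(1e-6, 50), E = rep(1e-6, 50))
  expect_true(define_boundaries(fake)$empty)
})
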