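# Full-matrix Forward/Backward/Viterbi/posterior/MEA against the
# path-enumeration oracle and their mutual consistency properties.

test_that("single-path closed form holds for m = 1, n = 1 (core model)", {
  set.seed(10)
  # close off the I0/D0 origin states so entry -> M1 is the only path in
  em <- matrix(rgamma(20, 1), 1)
  em <- em / sum(em)
  tr <- rbind(c(0.7, 0.1, 0.2, 1, 0, 1, 0),   # node 0: I0->M1 = D0->M1 = 0
              c(1.0, 0.0, 0.0, 1, 0, 1, 0))   # node 1: M1 -> end certain
  p <- profile_hmm("one", em, tr)
  t <- rand_target(1)
  f <- forward_full(p, t, mode = "global")
  prep <- cloudfb:::prep_profile(p)
  # single path: origin -> M1 (entry transition) emitting t1, free end
  expected <- log(0.7) + prep$msc[2, t$residues[1]]
  expect_equal(f$score, expected, tolerance = 1e-12)
})

test_that("forward/backward/viterbi match enumeration for all m, n <= 3", {
  set.seed(11)
  for (mode in c("global", "local")) {
    for (rep in 1:10) {
      m <- sample(1:3, 1); n <- sample(1:3, 1)
      p <- rand_profile(m)
      t <- rand_target(n)
      paths <- enumerate_paths(p, t$residues, mode)
      logp <- vapply(paths, `[[`, 0, "logp")
      f <- forward_full(p, t, mode = mode)
      b <- backward_full(p, t, mode = mode)
      v <- viterbi_full(p, t, mode = mode)
      expect_equal(exp(f$score), exp(lse(logp)), tolerance = 1e-9)
      expect_equal(exp(b$score), exp(lse(logp)), tolerance = 1e-9)
      expect_equal(exp(v$score), exp(max(logp)), tolerance = 1e-9)
    }
  }
})

test_that("posterior cell probabilities match enumeration cell usage", {
  set.seed(12)
  for (rep in 1:6) {
    m <- sample(2:3, 1); n <- sample(2:3, 1)
    p <- rand_profile(m)
    t <- rand_target(n)
    paths <- enumerate_paths(p, t$residues, "local")
    pp <- oracle_posterior(paths, m, n)
    post <- posterior_full(forward_full(p, t), backward_full(p, t))
    expect_equal(post$M, pp[1, , ], tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(post$I, pp[2, , ], tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(post$D, pp[3, , ], tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("MEA alignment attains the enumerated maximum posterior gain", {
  set.seed(13)
  for (rep in 1:6) {
    m <- sample(2:3, 1); n <- sample(2:3, 1)
    p <- rand_profile(m)
    t <- rand_target(n)
    paths <- enumerate_paths(p, t$residues, "local")
    post <- posterior_full(forward_full(p, t), backward_full(p, t))
    aln <- mea_full(post)
    expect_equal(aln$gain, oracle_mea_gain(paths, post$M, post$I),
                 tolerance = 1e-9)
    # the reported path is legal: monotone, starts/ends on match cells
    if (nrow(aln$path) > 1) {
      di <- diff(aln$path$i); dj <- diff(aln$path$j)
      expect_true(all(di >= 0 & dj >= 0 & (di + dj) >= 1))
    }
  }
})

test_that("forward score dominates viterbi and equals backward", {
  set.seed(14)
  for (rep in 1:15) {
    p <- rand_profile(sample(2:20, 1))
    t <- rand_target(sample(2:30, 1))
    f <- forward_full(p, t)
    b <- backward_full(p, t)
    v <- viterbi_full(p, t)
    expect_gte(f$score, v$score - 1e-9)
    expect_equal(f$score, b$score, tolerance = 1e-6)
    expect_false(anyNA(f$M)); expect_false(anyNA(b$M))
  }
})

test_that("row-major and anti-diagonal fill orders agree", {
  set.seed(15)
  for (rep in 1:5) {
    p <- rand_profile(sample(3:15, 1))
    t <- rand_target(sample(3:25, 1))
    f1 <- forward_full(p, t, order = "row")
    f2 <- forward_full(p, t, order = "antidiagonal")
    expect_equal(f1$score, f2$score, tolerance = 1e-9)
    expect_equal(f1$M, f2$M)
    expect_equal(f1$I, f2$I)
    expect_equal(f1$D, f2$D)
  }
})

test_that("strongly mismatching input stays finite", {
  # a profile emitting only residue 1 vs a target with none of it:
  # emission log-odds of other residues are tiny but scores remain finite
  em <- matrix(1e-9, 3, 20)
  em[, 1] <- 1 - 19e-9
  tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.4, 0.6, 0.4, 0.6), each = 4), 4)
  p <- profile_hmm("only-A", em, tr)
  t <- target_sequence("t", "WWWW")
  f <- forward_full(p, t)
  b <- backward_full(p, t)
  expect_true(is.finite(f$score))
  expect_true(is.finite(b$score))
  expect_false(anyNA(f$M))
})

test_that("match posteriors in a target column sum to at most one", {
  set.seed(16)
  for (rep in 1:5) {
    p <- rand_profile(sample(3:12, 1))
    t <- rand_target(sample(3:20, 1))
    post <- posterior_full(forward_full(p, t), backward_full(p, t))
    expect_true(all(colSums(post$M) <= 1 + 1e-6))
    expect_true(all(post$M >= 0 & post$M <= 1))
    # unreachable cells (row 0 / col 0 in local mode) have posterior zero
    expect_true(all(post$M[1, ] == 0))
    expect_true(all(post$M[, 1] == 0))
  }
})

test_that("a sequence profile aligned to its own sequence follows the diagonal", {
  set.seed(17)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    s <- rand_target(n, "self")
    p <- profile_from_sequence(s)
    v <- viterbi_full(p, s)
    paths <- enumerate_paths(p, s$residues, "local")
    logp <- vapply(paths, `[[`, 0, "logp")
    expect_equal(v$score, max(logp), tolerance = 1e-9)
    # the optimal path is the all-match main diagonal
    best <- paths[[which.max(logp)]]$cells
    expect_true(all(best$s == "M"))
    expect_equal(best$i, best$j)
    expect_equal(v$path$state, rep("M", nrow(v$path)))
    expect_equal(v$path$i, v$path$j)
  }
})

test_that("uniform-zero posterior input yields an empty alignment quietly", {
  ppM <- matrix(0, 5, 7)
  ppI <- matrix(0, 5, 7)
  r <- cloudfb:::cpp_mea(ppM, ppI, 1)
  expect_equal(r$gain, 0)
})
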