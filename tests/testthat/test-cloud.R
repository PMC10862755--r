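# Cloud search: pruning rules, linear-space bookkeeping, the
# quadratic-space reference, union, trimming, reorientation.

test_that("anti-diagonal pruning applies the two retention rules", {
  pp <- prune_params(alpha = 12, beta = 20, gamma = 1)
  # alpha rule: -13 < 0 - 12 is pruned, others kept
  expect_equal(prune_antidiagonal(c(0, -5, -13), 0, 0, pp), c(1L, 2L))
  # beta rule: everything below max_o - beta goes, flood fill stops
  expect_equal(prune_antidiagonal(c(4, 3), 4, 25, pp), integer(0))
  # no pruning while the anti-diagonal is shorter than gamma
  pp5 <- prune_params(12, 20, 5)
  expect_equal(prune_antidiagonal(c(-100, -200, -300), -100, 50, pp5),
               c(1L, 3L))
  # interior low cells survive: pruning works inward from the ends only
  expect_equal(prune_antidiagonal(c(0, -40, 0), 0, 0, pp), c(1L, 3L))
})

test_that("cloud matrix slots follow the mod-3 recycling rule", {
  s <- cloud_matrix_slot(3, 4)
  expect_equal(s$row, 1)   # (3 + 4) mod 3
  expect_equal(s$col, 4)
  # the row written for anti-diagonal d is the row that held d - 3
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cloud_matrix_slot(i, j)$row,
                 cloud_matrix_slot(i + 3, j)$row)
  }
  # at most two (i, j) pairs are stored per anti-diagonal
  set.seed(20)
  p <- rand_profile(12); t <- rand_target(15)
  cf <- cloud_search_forward(p, t, seed(2, 2, 8, 9))
  expect_false(any(duplicated(cf$bounds$d)))  # one [lo, hi] pair per d
})

test_that("unpruned flood fill covers the reachable quadrant", {
  set.seed(21)
  p <- rand_profile(8); t <- rand_target(10)
  inf <- prune_params(Inf, Inf, 1)
  cf <- cloud_search_forward(p, t, seed(1, 1, 8, 10), inf)
  cells <- cloud_cells(cf$bounds)
  expect_equal(nrow(cells), 8 * 10)  # full quadrant down-right of (1,1)
  cb <- cloud_search_backward(p, t, seed(1, 1, 8, 10), inf)
  expect_equal(nrow(cloud_cells(cb$bounds)), 8 * 10)
  # partial quadrant from an interior begin cell
  cf2 <- cloud_search_forward(p, t, seed(3, 4, 8, 10), inf)
  c2 <- cloud_cells(cf2$bounds)
  expect_true(all(c2$i >= 3 & c2$j >= 4))
  expect_equal(nrow(c2), 6 * 7)
})

test_that("forward pass values equal the quadratic-space reference", {
  set.seed(22)
  for (rep in 1:6) {
    m <- sample(10:30, 1); n <- sample(10:40, 1)
    p <- rand_profile(m); t <- rand_target(n)
    sd <- seed(2, 2, min(m, 7), min(n, 8))
    pp <- prune_params(6, 10, 3)
    ref <- cloud_ref_forward(p, t, sd, pp)
    got <- cloud_search_forward(p, t, sd, pp, debug = TRUE)
    expect_equal(as.data.frame(got$bounds), ref$bounds,
                 ignore_attr = TRUE)
    expect_equal(got$best, ref$best, tolerance = 1e-9)
    expect_equal(got$best_in, ref$best_in, tolerance = 1e-9)
    fin <- is.finite(got$M) & is.finite(ref$M)
    expect_equal(got$M[fin], ref$M[fin], tolerance = 1e-9)
  }
})

test_that("planted-homolog cloud values match the reference cellwise", {
  set.seed(23)
  pr <- planted_pair(m = 50, decoy_n = 50)
  sds <- kmer_seed_search(pr$profile, pr$target)
  expect_gt(nrow(sds), 0)
  sd <- seed(sds$ib[1], sds$jb[1], sds$ie[1], sds$je[1])
  ref <- cloud_ref_forward(pr$profile, pr$target, sd, prune_params())
  got <- cloud_search_forward(pr$profile, pr$target, sd, prune_params(),
                              debug = TRUE)
  expect_equal(as.data.frame(got$bounds), ref$bounds, ignore_attr = TRUE)
  fin <- is.finite(got$M) & is.finite(ref$M)
  expect_equal(got$M[fin], ref$M[fin], tolerance = 1e-9)
})

test_that("backward pass values match the reversed quadratic-space oracle", {
  set.seed(29)
  for (rep in 1:4) {
    m <- sample(10:25, 1); n <- sample(10:30, 1)
    p <- rand_profile(m); t <- rand_target(n)
    sd <- seed(2, 2, min(m, 7), min(n, 8))
    pp <- prune_params(6, 10, 3)
    got <- cloud_search_backward(p, t, sd, pp, debug = TRUE)
    # oracle: quadratic-space forward flood fill on the reversed problem
    rt <- target_sequence("rev", rev(t$residues))
    rsd <- seed(m + 1 - sd$ie, n + 1 - sd$je, m + 1 - sd$ib, n + 1 - sd$jb)
    ref <- cloud_ref_forward(NULL, rt, rsd, pp,
                             prep = cloudfb:::.prep_reversed(p))
    expect_equal(got$best, ref$best, tolerance = 1e-9)
    expect_equal(got$best_in, ref$best_in, tolerance = 1e-9)
    mapped <- data.frame(d = m + n + 2 - ref$bounds$d,
                         ilo = m + 1 - ref$bounds$ihi,
                         ihi = m + 1 - ref$bounds$ilo)
    mapped <- mapped[order(mapped$d), ]
    expect_equal(as.data.frame(got$bounds), mapped, ignore_attr = TRUE)
    refM <- ref$M[(m + 1):1, (n + 1):1, drop = FALSE]
    fin <- is.finite(got$M) & is.finite(refM)
    expect_equal(got$M[fin], refM[fin], tolerance = 1e-9)
  }
})

test_that("backward cloud is the point reflection of the forward cloud on a symmetric problem", {
  # reversal invariance needs uniform emissions plus tMI = tIM and
  # tMD = tDM (the model read backwards is then the model itself)
  m <- 7; n <- 9
  em <- matrix(rep(amino_alphabet()$background, each = m), m)
  tr <- matrix(rep(c(0.8, 0.1, 0.1, 0.9, 0.1, 0.9, 0.1), each = m + 1),
               m + 1)
  p <- profile_hmm("sym", em, tr)
  t <- target_sequence("t", rep(1L, n))
  pp <- prune_params(2, 4, 2)
  cf <- cloud_search_forward(p, t, seed(1, 1, m, n), pp)
  cb <- cloud_search_backward(p, t, seed(1, 1, m, n), pp)
  fcells <- cloud_cells(cf$bounds)
  bcells <- cloud_cells(cb$bounds)
  reflected <- data.frame(i = m + 1 - bcells$i, j = n + 1 - bcells$j)
  reflected <- reflected[order(reflected$i, reflected$j), ]
  expect_equal(fcells$i, reflected$i)
  expect_equal(fcells$j, reflected$j)
  expect_equal(cf$best, cb$best, tolerance = 1e-9)
})

test_that("cloud union covers both inputs and passes lone bounds through", {
  mk <- function(d, lo, hi) cloudfb:::new_cloud_bounds(d, lo, hi, 20, 20)
  f <- mk(c(5, 6, 7), c(2, 3, 3), c(4, 5, 6))
  b <- mk(c(5, 6), c(1, 2), c(3, 3))
  u <- cloud_union(f, b)
  expect_equal(u$ilo[u$d == 5], 1)   # covers 1..4
  expect_equal(u$ihi[u$d == 5], 4)
  expect_equal(u$ilo[u$d == 7], 3)   # forward-only bound passes through
  expect_equal(u$ihi[u$d == 7], 6)
  # union is a superset of both inputs
  uc <- cloud_cells(u)
  key <- function(x) paste(x$i, x$j)
  expect_true(all(key(cloud_cells(f)) %in% key(uc)))
  expect_true(all(key(cloud_cells(b)) %in% key(uc)))
  # disjoint clouds do not intersect
  b2 <- mk(c(6, 7), c(19, 19), c(20, 20))
  expect_null(cloud_union(f, b2))
})

test_that("the rectangular fallback spans exactly the seed rectangle", {
  rb <- fallback_rectangle(seed(2, 3, 5, 9))
  expect_equal(rb$row, 2:5)
  expect_true(all(rb$left == 3))
  expect_true(all(rb$right == 9))
  st <- cloud_stats(rb, 10, 12)
  expect_equal(st$cells, 4 * 7)
  rb1 <- fallback_rectangle(seed(4, 4, 4, 4))
  expect_equal(nrow(rb1), 1)
  expect_equal(cloud_stats(rb1, 5, 5)$cells, 1)
})

test_that("trimming removes spurs and keeps rectangles unchanged", {
  mk <- function(d, lo, hi) cloudfb:::new_cloud_bounds(d, lo, hi, 30, 30)
  # a 3x3 rectangle (rows 1..3, cols 1..3) in anti-diagonal form
  rect <- mk(2:6, c(1, 1, 1, 2, 3), c(1, 2, 3, 3, 3))
  expect_equal(as.data.frame(trim_cloud(rect)), as.data.frame(rect))
  # widening the last bound to [1,3] adds (1,5) and (2,4); the spur (1,5)
  # has no in-cloud predecessor and is removed, while (2,4) is reachable
  # (via (1,3)) and sits on the final anti-diagonal, so it stays
  spur <- mk(2:6, c(1, 1, 1, 2, 1), c(1, 2, 3, 3, 3))
  tr <- trim_cloud(spur)
  key <- function(x) paste(x$i, x$j)
  expect_false("1 5" %in% key(cloud_cells(tr)))
  expect_setequal(key(cloud_cells(tr)),
                  c(key(cloud_cells(rect)), "2 4"))
})

test_that("trim equals the reachability oracle on random clouds", {
  set.seed(24)
  n_checked <- 0
  for (rep in 1:60) {
    u <- rand_cloud(20, 20)
    if (is.null(u)) next
    tr <- trim_cloud(u)
    oracle <- reachability_oracle(cloud_cells(u))
    got <- cloud_cells(tr)
    key <- function(x) paste(x$i, x$j)
    # trim output is always a subset of its input
    expect_true(all(key(got) %in% key(cloud_cells(u))))
    # and matches the oracle exactly whenever the oracle's rows are
    # contiguous (the regime the bound representation can express)
    rows_ok <- all(vapply(unique(oracle$i), function(i) {
      js <- sort(oracle$j[oracle$i == i])
      length(js) == js[length(js)] - js[1] + 1
    }, TRUE))
    if (rows_ok) {
      n_checked <- n_checked + 1
      expect_setequal(key(got), key(oracle))
    }
  }
  expect_gt(n_checked, 10)
})

test_that("reorientation preserves the cell set of trimmed clouds", {
  # single anti-diagonal
  one <- cloudfb:::new_cloud_bounds(4, 1, 3, 10, 10)
  rb <- reorient_to_rows(one)
  expect_equal(rb$row, 1:3)
  expect_equal(rb$left, c(3, 2, 1))
  expect_equal(rb$right, c(3, 2, 1))
  # random trimmed clouds rasterize identically in both representations
  set.seed(25)
  done <- 0
  for (rep in 1:40) {
    u <- rand_cloud(15, 15)
    if (is.null(u)) next
    tr <- trim_cloud(u)
    cells <- cloud_cells(tr)
    rows_ok <- all(vapply(unique(cells$i), function(i) {
      js <- sort(cells$j[cells$i == i])
      length(js) == js[length(js)] - js[1] + 1
    }, TRUE))
    if (!rows_ok) next
    done <- done + 1
    rb <- reorient_to_rows(tr)
    rc <- cloud_cells(rb)
    expect_equal(paste(sort(paste(rc$i, rc$j))),
                 paste(sort(paste(cells$i, cells$j))))
  }
  expect_gt(done, 10)
})

test_that("larger alpha or beta never shrinks the retained cloud", {
  set.seed(26)
  for (rep in 1:5) {
    p <- rand_profile(15); t <- rand_target(20)
    sd <- seed(2, 2, 10, 12)
    key <- function(b) paste(cloud_cells(b)$i, cloud_cells(b)$j)
    small <- cloud_search_forward(p, t, sd, prune_params(3, 6, 2))
    big_a <- cloud_search_forward(p, t, sd, prune_params(8, 6, 2))
    big_b <- cloud_search_forward(p, t, sd, prune_params(3, 15, 2))
    expect_true(all(key(small$bounds) %in% key(big_a$bounds)))
    expect_true(all(key(small$bounds) %in% key(big_b$bounds)))
  }
})

test_that("best_in freezes at the seed's far anti-diagonal", {
  set.seed(27)
  p <- rand_profile(20); t <- rand_target(25)
  sd <- seed(2, 2, 6, 7)
  cf <- cloud_search_forward(p, t, sd)
  cb <- cloud_search_backward(p, t, sd)
  expect_gte(cf$best, cf$best_in)
  expect_gte(cb$best, cb$best_in)
  # with the seed's end on the first anti-diagonal, best_in == best at d0
  sd0 <- seed(3, 3, 3, 3)
  c0 <- cloud_search_forward(p, t, sd0)
  expect_equal(c0$best_in, 0)  # frozen at the seed cell itself
})

test_that("seeds outside the matrix are rejected", {
  set.seed(28)
  p <- rand_profile(5); t <- rand_target(6)
  expect_error(cloud_search_forward(p, t, seed(1, 1, 6, 3)), "outside")
  expect_error(seed(3, 2, 2, 5))  # ib > ie
})
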