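# Sparse layout construction and sparse Forward/Backward/posterior/MEA.

test_that("flat-array retrieval follows block_offset + (j - row_offset)", {
  # the documented arithmetic on a hand-built layout
  lay <- structure(list(row0 = 4L, nrow = 1L, total = 30L,
                        row_off = 3L, row_len = 10L, blk_off = 17L,
                        left = 4L, right = 11L, m = 10L, n = 20L),
                   class = "sparse_layout")
  expect_equal(layout_index(lay, 4, 5), 17 + (5 - 3) + 1)  # 1-based
  expect_true(is.na(layout_index(lay, 5, 5)))
  expect_true(is.na(layout_index(lay, 4, 2)))
})

test_that("full-matrix layouts allocate at least (m+1)(n+1) slots", {
  L <- full_layout(6, 9)
  expect_gte(L$total, 7 * 10)
  # padding stays a small fraction here
  expect_lte(L$total - L$cloud_cells, L$total / 2)
  expect_equal(L$cloud_cells, 6 * 9)
})

test_that("every forward dependency of every cloud cell is allocated", {
  set.seed(30)
  checked <- 0
  for (rep in 1:25) {
    u <- rand_cloud(15, 15)
    if (is.null(u)) next
    rb <- reorient_to_rows(trim_cloud(u))
    if (nrow(rb) == 0) next
    L <- build_layout(rb, 15, 15)
    cells <- cloud_cells(rb)
    for (r in seq_len(nrow(cells))) {
      i <- cells$i[r]; j <- cells$j[r]
      expect_false(is.na(layout_index(L, i, j)))
      for (dep in list(c(i - 1, j - 1), c(i - 1, j), c(i, j - 1))) {
        if (dep[1] < 0 || dep[2] < 0) next
        expect_false(is.na(layout_index(L, dep[1], dep[2])),
                     info = sprintf("dep (%d,%d) of (%d,%d)",
                                    dep[1], dep[2], i, j))
      }
    }
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("layout construction rejects invalid row bounds", {
  bad <- cloudfb:::new_row_bounds(2:3, c(5, 4), c(3, 9))  # empty run
  expect_error(build_layout(bad, 10, 10), "empty row run")
  oob <- cloudfb:::new_row_bounds(2:3, c(1, 1), c(12, 9))
  expect_error(build_layout(oob, 10, 10), "outside")
})

test_that("sparse results over a full layout equal the full-matrix results", {
  set.seed(31)
  for (rep in 1:6) {
    m <- sample(5:20, 1); n <- sample(5:30, 1)
    p <- rand_profile(m); t <- rand_target(n)
    L <- full_layout(m, n)
    f1 <- forward_full(p, t); b1 <- backward_full(p, t)
    f2 <- sparse_forward(p, t, L); b2 <- sparse_backward(p, t, L)
    expect_equal(f2$score, f1$score, tolerance = 1e-6)
    expect_equal(b2$score, b1$score, tolerance = 1e-6)
    post1 <- posterior_full(f1, b1)
    post2 <- sparse_posterior(f2, b2)
    for (i in 1:m) for (j in 1:n) {
      k <- layout_index(L, i, j)
      expect_equal(post2$M[k], post1$M[i + 1, j + 1], tolerance = 1e-6)
      expect_equal(post2$I[k], post1$I[i + 1, j + 1], tolerance = 1e-6)
    }
    a1 <- mea_full(post1); a2 <- sparse_mea(post2)
    expect_equal(a2$gain, a1$gain, tolerance = 1e-6)
    expect_equal(a2$path, a1$path)
  }
})

test_that("a single-diagonal cloud scores exactly the match-only paths", {
  set.seed(32)
  for (rep in 1:4) {
    n <- sample(3:4, 1)
    p <- rand_profile(n); t <- rand_target(n)
    rb <- cloudfb:::new_row_bounds(1:n, 1:n, 1:n)  # main diagonal only
    L <- build_layout(rb, n, n)
    sf <- sparse_forward(p, t, L)
    # oracle: enumerate local paths confined to the diagonal cells
    paths <- enumerate_paths(p, t$residues, "local")
    ok <- vapply(paths, function(pa) {
      all(pa$cells$i == pa$cells$j)
    }, TRUE)
    expected <- lse(vapply(paths[ok], `[[`, 0, "logp"))
    expect_equal(sf$score, expected, tolerance = 1e-9)
  }
})

test_that("sparse forward and backward totals agree on real clouds", {
  set.seed(33)
  for (rep in 1:5) {
    pr <- planted_pair(m = 40, decoy_n = 60)
    sds <- kmer_seed_search(pr$profile, pr$target)
    if (!nrow(sds)) next
    sd <- seed(sds$ib[1], sds$jb[1], sds$ie[1], sds$je[1])
    cf <- cloud_search_forward(pr$profile, pr$target, sd)
    cb <- cloud_search_backward(pr$profile, pr$target, sd)
    u <- cloud_union(cf$bounds, cb$bounds)
    if (is.null(u)) next
    rb <- reorient_to_rows(trim_cloud(u))
    L <- build_layout(rb, pr$profile$m, pr$target$n)
    sf <- sparse_forward(pr$profile, pr$target, L)
    sb <- sparse_backward(pr$profile, pr$target, L)
    expect_equal(sf$score, sb$score, tolerance = 1e-6)
    post <- sparse_posterior(sf, sb)
    expect_true(all(post$M >= 0 & post$M <= 1))
    # cells-computed statistic equals cloud plus padding
    expect_equal(L$total, L$cloud_cells + (L$total - L$cloud_cells))
    expect_lte(L$cloud_cells, L$total)
  }
})

test_that("padding slots are never written to a finite value", {
  set.seed(34)
  rb <- cloudfb:::new_row_bounds(integer(0), integer(0), integer(0))
  while (nrow(rb) == 0) {
    u <- NULL
    while (is.null(u)) u <- rand_cloud(12, 12)
    rb <- reorient_to_rows(trim_cloud(u))
  }
  L <- build_layout(rb, 12, 12)
  p <- rand_profile(12); t <- rand_target(12)
  sf <- sparse_forward(p, t, L)
  rows <- L$row0 + seq_len(L$nrow) - 1L
  for (r in seq_len(L$nrow)) {
    cols <- L$row_off[r] + seq_len(L$row_len[r]) - 1L
    for (j in cols) {
      k <- L$blk_off[r] + (j - L$row_off[r]) + 1L
      inside <- j >= L$left[r] && j <= L$right[r] && rows[r] >= 1 && j >= 1
      if (!inside) {
        expect_identical(sf$M[k], -Inf)
        expect_identical(sf$I[k], -Inf)
        expect_identical(sf$D[k], -Inf)
      }
    }
  }
})

test_that("enlarging the cloud never decreases the sparse forward score", {
  set.seed(35)
  p <- rand_profile(15); t <- rand_target(20)
  # nested rectangles as row bounds
  scores <- sapply(c(4, 8, 12, 15), function(w) {
    rb <- cloudfb:::new_row_bounds(1:w, rep(1L, w),
                                   rep(min(20L, w + 5L), w))
    sparse_forward(p, t, build_layout(rb, 15, 20),
                   want_cells = FALSE)$score
  })
  expect_true(all(diff(scores) >= -1e-9))
})
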