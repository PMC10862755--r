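# Independent oracles: explicit path enumeration for the DP algorithms,
# quadratic-space cloud-search reference, and cloud reachability.

# Enumerate every legal state path of the model against a digitized
# sequence, returning for each path its log-odds and the core cells it
# visits.  mode "global": paths start in M0/I0/D0 at (0,0) and end at
# (m, n); mode "local": N loop, fragment entry at any match cell, free
# exit from any match cell, C loop.
enumerate_paths <- function(p, res, mode = c("local", "global")) {
  mode <- match.arg(mode)
  prep <- cloudfb:::prep_profile(p)
  m <- p$m; n <- length(res)
  msc <- prep$msc; isc <- prep$isc; tr <- prep$tr; entry <- prep$entry
  lnNN <- log(n / (n + 2)); lnNB <- log(2 / (n + 2))
  paths <- list()
  add_path <- function(logp, cells)
    paths[[length(paths) + 1]] <<- list(logp = logp, cells = cells)
  tcol <- function(from, to) switch(paste0(from, to),
    MM = 1, MD = 2, MI = 3, II = 4, IM = 5, DD = 6, DM = 7)
  if (mode == "global") {
    recur <- function(state, i, j, logp, cells) {
      if (i == m && j == n) {
        endp <- switch(state, M = tr[m + 1, 1], I = tr[m + 1, 5],
                       D = tr[m + 1, 7])
        add_path(logp + endp, cells)
      }
      if (i < m && j < n)
        recur("M", i + 1, j + 1,
              logp + tr[i + 1, tcol(state, "M")] + msc[i + 2, res[j + 1]],
              rbind(cells, list(s = "M", i = i + 1, j = j + 1)))
      if (j < n && state %in% c("M", "I"))
        recur("I", i, j + 1,
              logp + tr[i + 1, tcol(state, "I")] + isc[i + 1, res[j + 1]],
              rbind(cells, list(s = "I", i = i, j = j + 1)))
      if (i < m && state %in% c("M", "D"))
        recur("D", i + 1, j, logp + tr[i + 1, tcol(state, "D")],
              rbind(cells, list(s = "D", i = i + 1, j = j)))
    }
    for (st in c("M", "I", "D"))
      recur(st, 0, 0, 0, data.frame(s = character(0), i = integer(0),
                                    j = integer(0)))
  } else {
    recur <- function(state, i, j, logp, cells) {
      if (state == "M")  # free exit, C loop, C->T
        add_path(logp + (n - j) * lnNN + lnNB, cells)
      if (i < m && j < n)
        recur("M", i + 1, j + 1,
              logp + tr[i + 1, tcol(state, "M")] + msc[i + 2, res[j + 1]],
              rbind(cells, list(s = "M", i = i + 1, j = j + 1)))
      if (j < n && state %in% c("M", "I"))
        recur("I", i, j + 1,
              logp + tr[i + 1, tcol(state, "I")] + isc[i + 1, res[j + 1]],
              rbind(cells, list(s = "I", i = i, j = j + 1)))
      if (i < m && state %in% c("M", "D"))
        recur("D", i + 1, j, logp + tr[i + 1, tcol(state, "D")],
              rbind(cells, list(s = "D", i = i + 1, j = j)))
    }
    for (i1 in 1:m) for (j1 in 1:n) {
      recur("M", i1, j1,
            (j1 - 1) * lnNN + lnNB + entry[i1 + 1] + msc[i1 + 1, res[j1]],
            data.frame(s = "M", i = i1, j = j1))
    }
  }
  paths
}

# per-cell usage probabilities from enumerated paths: 3 x (m+1) x (n+1)
# array over states M, I, D
oracle_posterior <- function(paths, m, n) {
  tot <- lse(vapply(paths, `[[`, 0, "logp"))
  pp <- array(0, c(3, m + 1, n + 1))
  for (pa in paths) {
    w <- exp(pa$logp - tot)
    cc <- pa$cells
    for (r in seq_len(nrow(cc))) {
      si <- match(cc$s[r], c("M", "I", "D"))
      pp[si, cc$i[r] + 1, cc$j[r] + 1] <- pp[si, cc$i[r] + 1, cc$j[r] + 1] + w
    }
  }
  pp
}

# maximum posterior gain over enumerated paths (the MEA oracle)
oracle_mea_gain <- function(paths, ppM, ppI, ins_weight = 1) {
  best <- 0
  for (pa in paths) {
    cc <- pa$cells
    g <- 0
    for (r in seq_len(nrow(cc))) {
      if (cc$s[r] == "M") g <- g + ppM[cc$i[r] + 1, cc$j[r] + 1]
      if (cc$s[r] == "I") g <- g + ins_weight * ppI[cc$i[r] + 1, cc$j[r] + 1]
    }
    best <- max(best, g)
  }
  best
}

# quadratic-space reference implementation of the forward cloud pass:
# same seed initialization, recurrence and pruning rules, but full
# matrices instead of the 3-row recycled storage
cloud_ref_forward <- function(p, t, sd, params,
                              prep = cloudfb:::prep_profile(p)) {
  m <- prep$m; n <- t$n; res <- t$residues
  M <- matrix(-Inf, m + 1, n + 1); I <- M; D <- M
  lse2 <- function(a, b) {
    if (a == -Inf) return(b); if (b == -Inf) return(a)
    mx <- max(a, b); mx + log1p(exp(-abs(a - b)))
  }
  M[sd$ib + 1, sd$jb + 1] <- I[sd$ib + 1, sd$jb + 1] <-
    D[sd$ib + 1, sd$jb + 1] <- 0
  bounds <- data.frame(d = sd$ib + sd$jb, ilo = sd$ib, ihi = sd$ib)
  maxo <- 0; best_in <- NA; detarget <- sd$ie + sd$je
  if (bounds$d[1] == detarget) best_in <- maxo
  a1 <- sd$ib; b1 <- sd$ib; a2 <- NA; b2 <- NA
  d <- sd$ib + sd$jb
  repeat {
    d <- d + 1
    lo <- a1; hi <- b1 + 1
    if (!is.na(a2)) { lo <- min(lo, a2 + 1); hi <- max(hi, b2 + 1) }
    lo <- max(lo, sd$ib, d - n); hi <- min(hi, m, d - sd$jb)
    if (lo > hi || d > m + n) break
    vals <- rep(-Inf, hi - lo + 1)
    for (i in lo:hi) {
      j <- d - i; c <- res[j]
      in1 <- function(ii) !is.na(a1) && ii >= a1 && ii <= b1
      in2 <- function(ii) !is.na(a2) && ii >= a2 && ii <= b2
      g <- function(X, ii, jj, ok) if (ok(ii)) X[ii + 1, jj + 1] else -Inf
      tr <- prep$tr
      vm <- prep$msc[i + 1, c] +
        lse2(lse2(g(M, i - 1, j - 1, in2) + tr[i, 1],
                  g(I, i - 1, j - 1, in2) + tr[i, 5]),
             g(D, i - 1, j - 1, in2) + tr[i, 7])
      vi <- prep$isc[i + 1, c] + lse2(g(M, i, j - 1, in1) + tr[i + 1, 3],
                                      g(I, i, j - 1, in1) + tr[i + 1, 4])
      vd <- lse2(g(M, i - 1, j, in1) + tr[i, 2],
                 g(D, i - 1, j, in1) + tr[i, 6])
      M[i + 1, j + 1] <- vm; I[i + 1, j + 1] <- vi; D[i + 1, j + 1] <- vd
      vals[i - lo + 1] <- vm
    }
    maxd <- max(vals); maxo <- max(maxo, maxd)
    if (hi - lo + 1 >= params$gamma) {
      keep <- prune_antidiagonal(vals, maxd, maxo, params)
      if (!length(keep)) break
      klo <- lo + keep[1] - 1; khi <- lo + keep[2] - 1
    } else { klo <- lo; khi <- hi }
    bounds <- rbind(bounds, data.frame(d = d, ilo = klo, ihi = khi))
    if (d == detarget) best_in <- maxo
    a2 <- a1; b2 <- b1; a1 <- klo; b1 <- khi
  }
  if (is.na(best_in)) best_in <- maxo
  list(bounds = bounds, best = maxo, best_in = best_in, M = M)
}

# brute-force reachability oracle on an explicit cell set: cells reachable
# from the first anti-diagonal AND able to reach the last anti-diagonal
# (moves: M = (+1,+1), I = (0,+1), D = (+1,0))
reachability_oracle <- function(cells) {
  key <- function(i, j) paste(i, j)
  cs <- unique(cells[, c("i", "j")])
  inset <- new.env()
  for (r in seq_len(nrow(cs))) assign(key(cs$i[r], cs$j[r]), TRUE, inset)
  has <- function(i, j) !is.null(inset[[key(i, j)]])
  d <- cs$i + cs$j
  d0 <- min(d); d1 <- max(d)
  fr <- new.env(); br <- new.env()
  for (r in which(d == d0)) assign(key(cs$i[r], cs$j[r]), TRUE, fr)
  for (dd in (d0 + 1):d1) {
    for (r in which(d == dd)) {
      i <- cs$i[r]; j <- cs$j[r]
      ok <- (!is.null(fr[[key(i - 1, j - 1)]])) ||
        (!is.null(fr[[key(i, j - 1)]])) || (!is.null(fr[[key(i - 1, j)]]))
      if (ok) assign(key(i, j), TRUE, fr)
    }
  }
  for (r in which(d == d1)) assign(key(cs$i[r], cs$j[r]), TRUE, br)
  for (dd in (d1 - 1):d0) {
    for (r in which(d == dd)) {
      i <- cs$i[r]; j <- cs$j[r]
      ok <- (!is.null(br[[key(i + 1, j + 1)]])) ||
        (!is.null(br[[key(i, j + 1)]])) || (!is.null(br[[key(i + 1, j)]]))
      if (ok) assign(key(i, j), TRUE, br)
    }
  }
  keep <- vapply(seq_len(nrow(cs)), function(r) {
    !is.null(fr[[key(cs$i[r], cs$j[r])]]) &&
      !is.null(br[[key(cs$i[r], cs$j[r])]])
  }, TRUE)
  out <- cs[keep, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

# random "natural" cloud: union of two drifting-interval flood-fill-like
# bounds, the shape trim_cloud is designed for
rand_cloud <- function(m = 20, n = 20) {
  mk <- function(i0, j0, steps, dirn) {
    d0 <- i0 + j0
    lo <- hi <- i0
    ds <- d0; los <- lo; his <- hi
    for (s in seq_len(steps)) {
      d <- d0 + dirn * s
      lo <- max(1, min(m, lo + sample(c(-1, 0, 1), 1)))
      hi <- max(lo, min(m, hi + sample(c(-1, 0, 1), 1)))
      lo <- min(lo, hi)
      # clip to valid j range
      lo <- max(lo, d - n); hi <- min(hi, d - 1)
      if (lo > hi) break
      ds <- c(ds, d); los <- c(los, lo); his <- c(his, hi)
    }
    cloudfb:::new_cloud_bounds(ds, los, his, m, n)
  }
  ib <- sample(1:(m %/% 2), 1); jb <- sample(1:(n %/% 2), 1)
  steps <- sample(5:(m + n - ib - jb - 2), 1)
  f <- mk(ib, jb, steps, 1L)
  de <- max(f$d)
  ivals <- f$ilo[nrow(f)]:f$ihi[nrow(f)]
  ie <- ivals[sample.int(length(ivals), 1)]
  b <- mk(ie, de - ie, steps, -1L)
  cloud_union(f, b)
}
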