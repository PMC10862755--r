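# Cloud search: seeded, pruned anti-diagonal flood fill in linear space,
# followed by union, trimming and reorientation of the resulting bounds.

#' Cloud-search pruning parameters
#'
#' `alpha` is the per-anti-diagonal score drop-off (cells scoring more than
#' `alpha` nats below the best cell on their anti-diagonal are pruned),
#' `beta` the global drop-off relative to the best score seen anywhere so
#' far (the X-drop analogue), and `gamma` the anti-diagonal length below
#' which no pruning is applied.
#'
#' @param alpha,beta Drop-offs in nats; defaults 12 and 20.
#' @param gamma Minimum anti-diagonal length before pruning; default 5.
#' @return A `prune_params` object.
#' @export
prune_params <- function(alpha = 12, beta = 20, gamma = 5) {
  stopifnot(alpha > 0, beta > 0, gamma >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = as.integer(gamma)),
            class = "prune_params")
}

#' Alignment seed
#'
#' The begin and end cells anchoring cloud search, usually the first and
#' last aligned positions of a prefilter alignment.
#'
#' @param ib,jb Begin cell (model position, target position), 1-based.
#' @param ie,je End cell; must satisfy `ib <= ie`, `jb <= je`.
#' @param score,pvalue Optional source alignment score (nats) and P-value.
#' @return A `seed` object.
#' @export
seed <- function(ib, jb, ie, je, score = NA_real_, pvalue = NA_real_) {
  stopifnot(1 <= ib, ib <= ie, 1 <= jb, jb <= je)
  structure(list(ib = as.integer(ib), jb = as.integer(jb),
                 ie = as.integer(ie), je = as.integer(je),
                 score = score, pvalue = pvalue),
            class = "seed")
}

new_cloud_bounds <- function(d, ilo, ihi, m, n) {
  b <- data.frame(d = as.integer(d), ilo = as.integer(ilo),
                  ihi = as.integer(ihi))
  b <- b[order(b$d), , drop = FALSE]
  rownames(b) <- NULL
  structure(b, class = c("cloud_bounds", "data.frame"), m = m, n = n)
}

#' @export
print.cloud_bounds <- function(x, ...) {
  cat(sprintf("cloud_bounds: %d anti-diagonals, %d cells\n",
              nrow(x), sum(x$ihi - x$ilo + 1L)))
  invisible(x)
}

#' Enumerate the cells of a cloud
#'
#' Rasterizes anti-diagonal bounds (or row bounds) into an explicit set of
#' `(i, j)` cells; mainly useful for testing and visualization.
#'
#' @param b A `cloud_bounds` or `row_bounds` object.
#' @return Data frame with columns `i`, `j`.
#' @export
cloud_cells <- function(b) {
  if (nrow(b) == 0)
    return(data.frame(i = integer(0), j = integer(0)))
  if (inherits(b, "cloud_bounds")) {
    cells <- do.call(rbind, lapply(seq_len(nrow(b)), function(r) {
      i <- b$ilo[r]:b$ihi[r]
      cbind(i = i, j = b$d[r] - i)
    }))
  } else if (inherits(b, "row_bounds")) {
    cells <- do.call(rbind, lapply(seq_len(nrow(b)), function(r) {
      if (b$left[r] > b$right[r]) return(NULL)
      j <- b$left[r]:b$right[r]
      cbind(i = rep(b$row[r], length(j)), j = j)
    }))
  } else stop("not a bounds object")
  cells <- as.data.frame(cells)
  cells[order(cells$i, cells$j), , drop = FALSE]
}

#' Prune one anti-diagonal
#'
#' Applies the two retention rules to the match-state values of a computed
#' anti-diagonal: a cell is kept if its value is at least `max_d - alpha`
#' (per-anti-diagonal drop-off) and at least `max_o - beta` (global
#' drop-off).  Pruning proceeds inward from the two ends only, so the
#' retained range is contiguous and interior low-scoring cells survive; no
#' pruning happens at all while the anti-diagonal is shorter than `gamma`
#' cells.  An empty result signals that the flood fill stops.
#'
#' @param values Match-state values (nats) along the anti-diagonal.
#' @param max_d Maximum of `values`.
#' @param max_o Best score seen on any anti-diagonal so far.
#' @param params [prune_params()].
#' @return Integer vector `c(first, last)` of retained indices (1-based
#'   into `values`), or `integer(0)` when every cell is pruned.
#' @export
prune_antidiagonal <- function(values, max_d, max_o, params = prune_params()) {
  L <- length(values)
  if (L < params$gamma) return(c(1L, L))
  keep <- values >= (max_d - params$alpha) & values >= (max_o - params$beta)
  if (!any(keep)) return(integer(0))
  c(which(keep)[1], tail(which(keep), 1))
}

#' Storage slot of a cell in the 3-row cloud matrix
#'
#' During either cloud-search pass only three anti-diagonals are resident;
#' the value of cell `(i, j)` lives at row `(i + j) mod 3`, column `j`, so
#' the row written for anti-diagonal `d` recycles the row that held `d - 3`.
#'
#' @param i,j Cell coordinates.
#' @return List with `row` (0-based, in 0..2) and `col` (= `j`).
#' @export
cloud_matrix_slot <- function(i, j) {
  list(row = (i + j) %% 3L, col = j)
}

.cloud_pass <- function(profile, target, sd, params, backward, debug) {
  stopifnot(inherits(sd, "seed"))
  if (sd$ie > profile$m || sd$je > target$n)
    stop("seed lies outside the alignment matrix")
  m <- profile$m; n <- target$n
  if (!backward) {
    r <- cpp_cloud_search(prep_profile(profile), target$residues,
                          sd$ib, sd$jb, sd$ie, sd$je,
                          params$alpha, params$beta, params$gamma, debug)
    bounds <- new_cloud_bounds(r$bounds[, 1], r$bounds[, 2], r$bounds[, 3],
                               m, n)
  } else {
    # the backward pass is the exact mirror of the forward pass: the
    # forward flood fill run on the reversed profile and sequence from
    # the reflected seed, with bounds mapped back
    r <- cpp_cloud_search(.prep_reversed(profile), rev(target$residues),
                          m + 1L - sd$ie, n + 1L - sd$je,
                          m + 1L - sd$ib, n + 1L - sd$jb,
                          params$alpha, params$beta, params$gamma, debug)
    bounds <- new_cloud_bounds(m + n + 2L - r$bounds[, 1],
                               m + 1L - r$bounds[, 3],
                               m + 1L - r$bounds[, 2], m, n)
  }
  out <- list(bounds = bounds, best = r$best, best_in = r$best_in)
  if (debug) {
    out$M <- if (backward) {
      r$M[(m + 1L):1L, (n + 1L):1L, drop = FALSE]
    } else r$M
  }
  out
}

#' Forward cloud-search pass
#'
#' Flood-fills the matrix down and right from the seed's begin cell, one
#' anti-diagonal at a time, using the Forward (log-sum) core recurrence
#' with `M = I = D = 0` at the begin cell, pruning each anti-diagonal with
#' [prune_antidiagonal()]'s rules.  Only three anti-diagonals are resident
#' at any time (see [cloud_matrix_slot()]).
#'
#' @param profile A [profile_hmm()].
#' @param target A [target_sequence()].
#' @param sd A [seed()].
#' @param params [prune_params()].
#' @param debug If `TRUE`, also return the dense matrix of computed
#'   match-state values (testing only).
#' @return List with `bounds` (a `cloud_bounds`), `best` (best match-state
#'   score seen anywhere, nats) and `best_in` (best score seen up to and
#'   including the anti-diagonal containing the seed's end cell).
#' @export
cloud_search_forward <- function(profile, target, sd,
                                 params = prune_params(), debug = FALSE) {
  .cloud_pass(profile, target, sd, params, backward = FALSE, debug = debug)
}

#' Backward cloud-search pass
#'
#' Mirror image of [cloud_search_forward()]: flood-fills up and left from
#' the seed's end cell using the Backward recurrence; `best_in` freezes at
#' the anti-diagonal containing the begin cell.
#'
#' @inheritParams cloud_search_forward
#' @export
cloud_search_backward <- function(profile, target, sd,
                                  params = prune_params(), debug = FALSE) {
  .cloud_pass(profile, target, sd, params, backward = TRUE, debug = debug)
}

#' Union of forward and backward clouds
#'
#' Combines the two bounds per anti-diagonal into one covering interval;
#' anti-diagonals present in only one cloud pass through unchanged.  When
#' the two clouds share no cell the union is not useful (the seed region
#' was split by a low-homology gap) and `NULL` is returned: callers fall
#' back to [fallback_rectangle()].
#'
#' @param fwd,bkwd `cloud_bounds` from the two passes.
#' @return A `cloud_bounds`, or `NULL` when the clouds do not intersect.
#' @export
cloud_union <- function(fwd, bkwd) {
  stopifnot(inherits(fwd, "cloud_bounds"), inherits(bkwd, "cloud_bounds"))
  shared <- intersect(fwd$d, bkwd$d)
  ov <- FALSE
  for (d in shared) {
    f <- fwd[fwd$d == d, ]; b <- bkwd[bkwd$d == d, ]
    if (f$ilo <= b$ihi && b$ilo <= f$ihi) { ov <- TRUE; break }
  }
  if (!ov) return(NULL)
  ds <- sort(union(fwd$d, bkwd$d))
  ilo <- ihi <- integer(length(ds))
  for (k in seq_along(ds)) {
    d <- ds[k]
    lo <- Inf; hi <- -Inf
    f <- which(fwd$d == d)
    if (length(f)) { lo <- min(lo, fwd$ilo[f]); hi <- max(hi, fwd$ihi[f]) }
    b <- which(bkwd$d == d)
    if (length(b)) { lo <- min(lo, bkwd$ilo[b]); hi <- max(hi, bkwd$ihi[b]) }
    ilo[k] <- lo; ihi[k] <- hi
  }
  new_cloud_bounds(ds, ilo, ihi, attr(fwd, "m"), attr(fwd, "n"))
}

#' Rectangular fallback bounds
#'
#' Row bounds covering the rectangle spanned by the seed, used when the
#' forward and backward clouds do not intersect.
#'
#' @param sd A [seed()].
#' @return A `row_bounds` object covering rows `ib..ie`, columns `jb..je`.
#' @export
fallback_rectangle <- function(sd) {
  stopifnot(inherits(sd, "seed"))
  new_row_bounds(sd$ib:sd$ie, rep(sd$jb, sd$ie - sd$ib + 1L),
                 rep(sd$je, sd$ie - sd$ib + 1L))
}

#' Trim protrusions from a cloud union
#'
#' Removes the cells that cannot lie on any path from the cloud's first
#' anti-diagonal to its last: a forward sweep clips each bound to the cells
#' reachable from the retained bounds of the previous two anti-diagonals,
#' and a reverse sweep clips to the cells that can reach the following two.
#' After trimming, the cells of every matrix row form one contiguous run.
#'
#' @param u A `cloud_bounds` (typically from [cloud_union()]).
#' @return A trimmed `cloud_bounds` (a subset of the input).
#' @export
trim_cloud <- function(u) {
  stopifnot(inherits(u, "cloud_bounds"))
  b <- as.data.frame(u)
  nb <- nrow(b)
  if (nb <= 1) return(u)
  empty <- rep(FALSE, nb)
  # helper: the interval reachable on anti-diagonal d[k] from the retained
  # interval at index kk (one step: I keeps i, D adds 1; two steps via M
  # add 1); returns NULL when kk contributes nothing
  contrib <- function(kk, dk, step) {
    if (kk < 1 || kk > nb || empty[kk]) return(NULL)
    gap <- dk - b$d[kk]
    if (step > 0) {
      if (gap == 1L) c(b$ilo[kk], b$ihi[kk] + 1L)
      else if (gap == 2L) c(b$ilo[kk] + 1L, b$ihi[kk] + 1L)
      else NULL
    } else {
      if (gap == -1L) c(b$ilo[kk] - 1L, b$ihi[kk])
      else if (gap == -2L) c(b$ilo[kk] - 1L, b$ihi[kk] - 1L)
      else NULL
    }
  }
  sweep1 <- function(idx, step) {
    for (k in idx) {
      c1 <- contrib(k - step, b$d[k], step)
      c2 <- contrib(k - 2L * step, b$d[k], step)
      if (is.null(c1) && is.null(c2)) {
        # unreachable from inside the cloud on this side
        empty[k] <<- TRUE
        next
      }
      lo <- min(c(c1[1], c2[1])); hi <- max(c(c1[2], c2[2]))
      b$ilo[k] <<- max(b$ilo[k], lo)
      b$ihi[k] <<- min(b$ihi[k], hi)
      if (b$ilo[k] > b$ihi[k]) empty[k] <<- TRUE
    }
  }
  sweep1(2:nb, 1L)              # forward: reachable from the first bound
  sweep1((nb - 1):1, -1L)       # reverse: can reach the last bound
  keep <- !empty & b$ilo <= b$ihi
  new_cloud_bounds(b$d[keep], b$ilo[keep], b$ihi[keep],
                   attr(u, "m"), attr(u, "n"))
}

new_row_bounds <- function(row, left, right) {
  b <- data.frame(row = as.integer(row), left = as.integer(left),
                  right = as.integer(right))
  b <- b[order(b$row), , drop = FALSE]
  rownames(b) <- NULL
  structure(b, class = c("row_bounds", "data.frame"))
}

#' @export
print.row_bounds <- function(x, ...) {
  cat(sprintf("row_bounds: rows %d..%d, %d cells\n",
              min(x$row), max(x$row), sum(pmax(x$right - x$left + 1L, 0L))))
  invisible(x)
}

#' Reorient anti-diagonal bounds into row bounds
#'
#' Converts trimmed anti-diagonal cloud bounds into per-row column
#' intervals.  For a trimmed cloud whose rows are contiguous the cell set
#' is identical under both representations.  Pruning jitter can
#' occasionally pinch a single anti-diagonal and leave an interior one-cell
#' hole in a row even though trimming correctly kept both sides (each still
#' lies on a legal through-path); because the row representation requires
#' one contiguous run per row, such holes are closed by taking the row's
#' hull (`fill_gaps = TRUE`, the default) — a strict superset of the cloud
#' that can only improve the sparse approximation.  With
#' `fill_gaps = FALSE` a non-contiguous row is an error.
#'
#' @param tb A trimmed `cloud_bounds`.
#' @param fill_gaps Close interior row holes with the row hull.
#' @return A `row_bounds` object.
#' @export
reorient_to_rows <- function(tb, fill_gaps = TRUE) {
  stopifnot(inherits(tb, "cloud_bounds"))
  if (nrow(tb) == 0)
    return(new_row_bounds(integer(0), integer(0), integer(0)))
  rows <- list()
  for (k in seq_len(nrow(tb))) {
    for (i in tb$ilo[k]:tb$ihi[k]) {
      j <- tb$d[k] - i
      key <- as.character(i)
      if (is.null(rows[[key]])) rows[[key]] <- c(j, j)
      else rows[[key]] <- c(min(rows[[key]][1], j), max(rows[[key]][2], j))
    }
  }
  ri <- as.integer(names(rows))
  rb <- new_row_bounds(ri, vapply(rows, `[`, 0, 1), vapply(rows, `[`, 0, 2))
  n_interval <- sum(rb$right - rb$left + 1L)
  n_cells <- nrow(unique(cloud_cells(tb)))
  if (n_interval != n_cells && !fill_gaps)
    stop("cloud rows are not contiguous; trim_cloud() must be applied first")
  rb
}

#' Cloud occupancy statistics
#'
#' @param rb A `row_bounds`.
#' @param m,n Full matrix dimensions.
#' @return List with `cells` (cloud cells) and `fraction` of the full
#'   `(m+1)(n+1)` matrix.
#' @export
cloud_stats <- function(rb, m, n) {
  cells <- sum(pmax(rb$right - rb$left + 1L, 0L))
  list(cells = cells, fraction = cells / ((m + 1) * (n + 1)))
}
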