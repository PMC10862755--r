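# Flat-array sparse matrix over row bounds, and the sparse
# Forward/Backward/posterior/MEA stage computed over it.

#' Build a flat-array sparse layout over row bounds
#'
#' Allocates one contiguous block of flat-array slots per matrix row,
#' covering that row's cloud run plus padding cells chosen so that every
#' recurrence dependency `(i-1, j-1)`, `(i-1, j)`, `(i, j-1)` (and the
#' mirrored backward dependencies) of every cloud cell resolves to an
#' allocated slot: each row's allocation is extended one column left and
#' right of its run and widened to cover the runs of the adjacent rows,
#' and one pure-padding row is added above and below the cloud.  Padding
#' slots permanently hold log-space probability zero (`-Inf`), so they
#' never inject probability.  The flat position of logical cell `(i, j)`
#' is `block_offset[i] + (j - row_offset[i])`.
#'
#' @param rb A `row_bounds` object (from [reorient_to_rows()] or
#'   [fallback_rectangle()]).
#' @param m,n Model length and target length (full-matrix dimensions).
#' @return A `sparse_layout` object.
#' @export
build_layout <- function(rb, m, n) {
  stopifnot(inherits(rb, "row_bounds"))
  if (any(rb$left > rb$right))
    stop("row bounds contain an empty row run (trim contract violated)")
  if (any(rb$left < 0) || any(rb$right > n) || any(rb$row < 1) ||
      any(rb$row > m))
    stop("row bounds outside the alignment matrix")
  r0 <- min(rb$row); r1 <- max(rb$row)
  rows <- r0:r1
  left <- rep(NA_integer_, length(rows))
  right <- rep(NA_integer_, length(rows))
  left[rb$row - r0 + 1L] <- rb$left
  right[rb$row - r0 + 1L] <- rb$right
  # add padding rows above and below (clipped to the matrix)
  lr0 <- max(r0 - 1L, 0L)
  lr1 <- min(r1 + 1L, m)
  lrows <- lr0:lr1
  getL <- function(i) if (i >= r0 && i <= r1) left[i - r0 + 1L] else NA
  getR <- function(i) if (i >= r0 && i <= r1) right[i - r0 + 1L] else NA
  row_off <- row_len <- integer(length(lrows))
  lft <- rgt <- integer(length(lrows))
  for (k in seq_along(lrows)) {
    i <- lrows[k]
    Lc <- c(getL(i) - 1L, getL(i + 1L) - 1L, getL(i - 1L))
    Rc <- c(getR(i) + 1L, getR(i + 1L), getR(i - 1L) + 1L)
    if (all(is.na(Lc))) { Lc <- 0L; Rc <- 0L }  # isolated sentinel slot
    Li <- max(min(Lc, na.rm = TRUE), 0L)
    Ri <- min(max(Rc, na.rm = TRUE), n)
    row_off[k] <- Li
    row_len[k] <- Ri - Li + 1L
    lft[k] <- if (is.na(getL(i))) 1L else getL(i)
    rgt[k] <- if (is.na(getR(i))) 0L else getR(i)
  }
  blk <- cumsum(c(0L, head(row_len, -1L)))
  structure(list(row0 = lr0, nrow = length(lrows), total = sum(row_len),
                 row_off = row_off, row_len = row_len, blk_off = blk,
                 left = lft, right = rgt, m = m, n = n,
                 cloud_cells = sum(pmax(rgt - lft + 1L, 0L))),
            class = "sparse_layout")
}

#' @export
print.sparse_layout <- function(x, ...) {
  cat(sprintf(
    "sparse_layout: rows %d..%d, %d cloud cells + %d padding = %d slots\n",
    x$row0, x$row0 + x$nrow - 1L, x$cloud_cells, x$total - x$cloud_cells,
    x$total))
  invisible(x)
}

#' Flat-array index of a logical cell
#'
#' The retrieval rule `block_offset[i] + (j - row_offset[i])`.
#'
#' @param layout A `sparse_layout`.
#' @param i,j Logical (full-matrix) row and column.
#' @return 1-based index into the flat arrays, or `NA` if `(i, j)` is
#'   outside the allocation.
#' @export
layout_index <- function(layout, i, j) {
  if (i < layout$row0 || i >= layout$row0 + layout$nrow) return(NA_integer_)
  r <- i - layout$row0 + 1L
  c <- j - layout$row_off[r]
  if (c < 0 || c >= layout$row_len[r]) return(NA_integer_)
  layout$blk_off[r] + c + 1L
}

#' Layout covering the full matrix
#'
#' Convenience constructor: row bounds covering every core cell (rows
#' `1..m`, columns `1..n`).  With this layout every sparse result equals
#' the corresponding full-matrix result.
#'
#' @param m,n Matrix dimensions.
#' @return A `sparse_layout`.
#' @export
full_layout <- function(m, n) {
  build_layout(new_row_bounds(1:m, rep(1L, m), rep(n, m)), m, n)
}

#' Sparse Forward
#'
#' Forward algorithm restricted to the cloud: cells outside the layout's
#' cloud runs implicitly carry probability zero.  The local-alignment
#' wrapper states are computed densely per column (their cost is linear
#' in the target length).
#'
#' @param profile A [profile_hmm()].
#' @param target A [target_sequence()].
#' @param layout A `sparse_layout` whose `m`, `n` match the pair.
#' @param want_cells Keep the flat value arrays (needed for posterior
#'   decoding); set `FALSE` when only the score matters.
#' @return A `sparse_dp` object: `score` (nats), flat arrays `M`, `I`,
#'   `D`, special-state vectors, and the layout.
#' @export
sparse_forward <- function(profile, target, layout, want_cells = TRUE) {
  stopifnot(inherits(layout, "sparse_layout"), layout$m == profile$m,
            layout$n == target$n)
  r <- cpp_sparse_forward(prep_profile(profile), target$residues,
                          unclass(layout), want_cells)
  structure(list(score = r$score, M = r$M, I = r$I, D = r$D,
                 specials = r$specials, layout = layout,
                 direction = "forward"),
            class = "sparse_dp")
}

#' Sparse Backward
#'
#' @inheritParams sparse_forward
#' @return A `sparse_dp` object (direction `"backward"`); its total score
#'   equals the sparse Forward score up to roundoff.
#' @export
sparse_backward <- function(profile, target, layout, want_cells = TRUE) {
  stopifnot(inherits(layout, "sparse_layout"), layout$m == profile$m,
            layout$n == target$n)
  r <- cpp_sparse_backward(prep_profile(profile), target$residues,
                           unclass(layout), want_cells)
  structure(list(score = r$score, M = r$M, I = r$I, D = r$D,
                 specials = r$specials, layout = layout,
                 direction = "backward"),
            class = "sparse_dp")
}

#' @export
print.sparse_dp <- function(x, ...) {
  cat(sprintf("sparse_dp (%s): score = %.4f nats over %d cloud cells\n",
              x$direction, x$score, x$layout$cloud_cells))
  invisible(x)
}

#' Sparse posterior decoding
#'
#' Cellwise `forward + backward - total` over the flat arrays,
#' exponentiated; cells outside the cloud have posterior zero.
#'
#' @param fwd,bkwd `sparse_dp` objects over the same layout.
#' @return A `sparse_posterior` object with flat arrays `M`, `I`, `D`,
#'   per-column `B` and `E` posteriors, the total score, and the layout.
#' @export
sparse_posterior <- function(fwd, bkwd) {
  stopifnot(inherits(fwd, "sparse_dp"), inherits(bkwd, "sparse_dp"),
            fwd$direction == "forward", bkwd$direction == "backward")
  total <- fwd$score
  pp <- function(a, b) {
    x <- exp(a + b - total)
    x[!is.finite(x)] <- 0
    pmin(pmax(x, 0), 1)
  }
  structure(list(M = pp(fwd$M, bkwd$M), I = pp(fwd$I, bkwd$I),
                 D = pp(fwd$D, bkwd$D),
                 B = pp(fwd$specials$B, bkwd$specials$B),
                 E = pp(fwd$specials$E, bkwd$specials$E),
                 total = total, layout = fwd$layout),
            class = "sparse_posterior")
}

#' Sparse maximum expected accuracy alignment
#'
#' The posterior-gain alignment of [mea_full()], restricted to the cloud.
#'
#' @param post A `sparse_posterior`.
#' @param ins_weight Relative gain weight of insert cells.
#' @return An `alignment` object.
#' @export
sparse_mea <- function(post, ins_weight = 1) {
  stopifnot(inherits(post, "sparse_posterior"))
  r <- cpp_sparse_mea(post$M, post$I, unclass(post$layout), ins_weight)
  new_alignment(r$path, gain = r$gain)
}

#' Sparse Forward scores for many targets
#'
#' Batch scorer: runs sparse Forward over the same layout for every
#' target (all targets must share the layout's length) and returns only
#' the scores.  Used for null-score simulation and filtering studies.
#'
#' @param profile A [profile_hmm()].
#' @param targets List of [target_sequence()] objects (or bare digitized
#'   integer vectors), all of length `layout$n`.
#' @param layout A `sparse_layout`; defaults to full coverage.
#' @return Numeric vector of scores in nats.
#' @export
sparse_forward_scores <- function(profile, targets, layout = NULL) {
  seqs <- lapply(targets, function(t)
    if (inherits(t, "target_seq")) t$residues else as.integer(t))
  ns <- unique(lengths(seqs))
  stopifnot(length(ns) == 1)
  if (is.null(layout)) layout <- full_layout(profile$m, ns)
  stopifnot(layout$n == ns)
  cpp_sparse_forward_score_batch(prep_profile(profile), seqs,
                                 unclass(layout))
}

#' Dump a layout's cloud runs as TSV
#'
#' Debug/visualization helper: writes one line per row with its cloud run.
#'
#' @param layout A `sparse_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  rows <- layout$row0 + seq_len(layout$nrow) - 1L
  keep <- layout$left <= layout$right
  write.table(data.frame(row = rows[keep], left = layout$left[keep],
                         right = layout$right[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
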