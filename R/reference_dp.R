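# Full-matrix Forward/Backward/Viterbi, posterior decoding and maximum
# expected accuracy alignment: the quadratic-space reference path
# (`--full-dp` in the CLI) and the correctness oracle for the sparse stage.

#' Full-matrix Forward algorithm
#'
#' Fills the three `(m+1) x (n+1)` log-space matrices `M`, `I`, `D` and the
#' local-alignment special states, returning the total log-odds score in
#' nats: the log of the summed probability of all alignments of the target
#' to the model, relative to the background model.
#'
#' @param profile A [profile_hmm()].
#' @param target A [target_sequence()].
#' @param mode `"local"` (default): begin/end wrapper states with uniform
#'   fragment entry, free exit from any match state, unihit (no J state).
#'   `"global"`: the bare core model anchored at the matrix corners (used
#'   by the enumeration oracle and by cloud search internals).
#' @param order Fill order, `"row"` (row-major) or `"antidiagonal"`; the
#'   results are identical, the option exists to verify exactly that.
#' @return A `dp_matrices` object: matrices `M`, `I`, `D`, per-column
#'   special-state vectors, and `score` (nats).
#' @export
forward_full <- function(profile, target, mode = c("local", "global"),
                         order = c("row", "antidiagonal")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  r <- cpp_forward(prep_profile(profile), target$residues,
                   mode == "local", order == "antidiagonal", TRUE)
  structure(list(M = r$M, I = r$I, D = r$D, specials = r$specials,
                 score = r$score, mode = mode, direction = "forward",
                 m = profile$m, n = target$n,
                 query = profile$name, target = target$name),
            class = "dp_matrices")
}

#' Full-matrix Backward algorithm
#'
#' The reverse-sweep counterpart of [forward_full()]: each cell holds the
#' log probability of all alignment completions starting from that cell.
#' The total Backward score equals the Forward score (up to roundoff).
#'
#' @inheritParams forward_full
#' @return A `dp_matrices` object (direction `"backward"`).
#' @export
backward_full <- function(profile, target, mode = c("local", "global")) {
  mode <- match.arg(mode)
  r <- cpp_backward(prep_profile(profile), target$residues, mode == "local")
  structure(list(M = r$M, I = r$I, D = r$D, specials = r$specials,
                 score = r$score, mode = mode, direction = "backward",
                 m = profile$m, n = target$n,
                 query = profile$name, target = target$name),
            class = "dp_matrices")
}

#' @export
print.dp_matrices <- function(x, ...) {
  cat(sprintf("dp_matrices (%s, %s): %d x %d, score = %.4f nats\n",
              x$direction, x$mode, x$m, x$n, x$score))
  invisible(x)
}

#' Full-matrix Viterbi alignment
#'
#' Maximum-probability single alignment path (the analogue of optimal
#' local alignment).  Ties in the traceback prefer M over D over I.
#'
#' @inheritParams forward_full
#' @return An `alignment` object: `score` (nats), the core state path as a
#'   data frame (`state` in M/I/D, `i`, `j`), and query/target spans.
#' @export
viterbi_full <- function(profile, target, mode = c("local", "global")) {
  mode <- match.arg(mode)
  r <- cpp_viterbi(prep_profile(profile), target$residues, mode == "local")
  new_alignment(r$path, score = r$score,
                query = profile$name, target = target$name)
}

# shared constructor for alignment results (viterbi / MEA paths)
new_alignment <- function(path_mat, score = NA_real_, gain = NA_real_,
                          query = NA_character_, target = NA_character_) {
  keep <- path_mat[, 2] >= 1 & path_mat[, 3] >= 1
  path_mat <- path_mat[keep, , drop = FALSE]
  path <- data.frame(state = c("M", "I", "D")[path_mat[, 1]],
                     i = path_mat[, 2], j = path_mat[, 3])
  spans <- if (nrow(path)) {
    mrow <- path$state == "M"
    list(qstart = min(path$i[mrow]), qend = max(path$i[mrow]),
         tstart = min(path$j[path$state != "D"]),
         tend = max(path$j[path$state != "D"]))
  } else {
    list(qstart = NA_integer_, qend = NA_integer_,
         tstart = NA_integer_, tend = NA_integer_)
  }
  structure(c(list(path = path, score = score, gain = gain,
                   query = query, target = target), spans),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment %s vs %s: q[%s-%s] t[%s-%s]",
              x$query, x$target, x$qstart, x$qend, x$tstart, x$tend))
  if (!is.na(x$score)) cat(sprintf(", score %.4f nats", x$score))
  if (!is.na(x$gain)) cat(sprintf(", posterior gain %.4f", x$gain))
  cat("\n")
  invisible(x)
}

#' Viterbi scores for many targets
#'
#' Batch scorer returning only the maximum-probability alignment score for
#' each target (rolling two-row storage, no traceback); the workhorse of
#' gapped-score null calibration.
#'
#' @param profile A [profile_hmm()].
#' @param targets List of [target_sequence()] objects or digitized integer
#'   vectors.
#' @return Numeric vector of local Viterbi scores in nats.
#' @export
viterbi_scores <- function(profile, targets) {
  seqs <- lapply(targets, function(t)
    if (inherits(t, "target_seq")) t$residues else as.integer(t))
  cpp_viterbi_score_batch(prep_profile(profile), seqs)
}

#' Forward scores for many targets
#'
#' Batch scorer returning only the full Forward score per target (rolling
#' two-row storage); used by [calibrate()].
#'
#' @inheritParams viterbi_scores
#' @return Numeric vector of Forward scores in nats.
#' @export
forward_scores <- function(profile, targets) {
  seqs <- lapply(targets, function(t)
    if (inherits(t, "target_seq")) t$residues else as.integer(t))
  cpp_forward_score_batch(prep_profile(profile), seqs)
}

#' Posterior decoding from Forward and Backward matrices
#'
#' Combines Forward and Backward cellwise (`fwd + bkwd - total` in log
#' space, exponentiated) into the posterior probability that each cell lies
#' on the true alignment path, for each of the M, I, D states, plus
#' per-column posteriors of the begin (B) and end (E) wrapper states.
#'
#' @param fwd,bkwd `dp_matrices` from [forward_full()] / [backward_full()]
#'   on the same profile/target pair and mode.
#' @return A `posterior_matrix` object with matrices `M`, `I`, `D` in
#'   `[0, 1]`, vectors `B`, `E`, and the total score.
#' @export
posterior_full <- function(fwd, bkwd) {
  stopifnot(inherits(fwd, "dp_matrices"), inherits(bkwd, "dp_matrices"),
            fwd$direction == "forward", bkwd$direction == "backward",
            fwd$mode == bkwd$mode, fwd$m == bkwd$m, fwd$n == bkwd$n)
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
                 total = total, m = fwd$m, n = fwd$n,
                 query = fwd$query, target = fwd$target),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("posterior_matrix: %d x %d, total %.4f nats\n",
              x$m, x$n, x$total))
  invisible(x)
}

#' Maximum expected accuracy alignment (full matrix)
#'
#' Finds the legal alignment path maximizing the summed posterior
#' probability of its emitting cells: match posteriors on diagonal steps
#' plus `ins_weight` times insert posteriors on horizontal steps (delete
#' steps gain nothing).  Ties prefer M over D over I.
#'
#' @param post A `posterior_matrix` from [posterior_full()].
#' @param ins_weight Relative gain weight of insert cells (default 1).
#' @return An `alignment` object with the `gain` field set.
#' @export
mea_full <- function(post, ins_weight = 1) {
  stopifnot(inherits(post, "posterior_matrix"))
  r <- cpp_mea(post$M, post$I, ins_weight)
  new_alignment(r$path, gain = r$gain, query = post$query,
                target = post$target)
}
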