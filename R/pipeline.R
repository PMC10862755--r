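# End-to-end search orchestration: seeds -> cloud search -> staged filters
# -> sparse Forward/Backward -> bias, boundaries, MEA -> ranked report.

#' Search a target database with query profiles
#'
#' Runs the full pipeline for every query/target candidate pair: seed
#' generation (internal k-mer search, or an external seed table), the
#' seed-stage P-value filter, forward+backward cloud search from the best
#' seed, the cloud filter on the estimated Forward score, sparse
#' Forward/Backward over the trimmed cloud, the Forward filter, posterior
#' decoding, composition-bias correction, boundary definition and maximum
#' expected accuracy alignment.  Candidates whose forward and backward
#' clouds do not intersect fall back to the rectangular matrix spanned by
#' the seed.  With `full_dp = TRUE` the quadratic-space reference
#' algorithms replace cloud search and the sparse stage (the cloud filter
#' is then skipped).
#'
#' @param queries A `profile_hmm` or list of them (a `target_seq` query is
#'   converted with [profile_from_sequence()]).
#' @param targets A `target_seq` or list of them.
#' @param seeds Optional external seed table from [read_seed_file()]; when
#'   absent, [kmer_seed_search()] supplies seeds.
#' @param params Cloud-search [prune_params()].
#' @param thresholds Staged [filter_thresholds()].
#' @param full_dp Use the full-matrix reference path.
#' @param E_max Report threshold: hits with E-value above this are
#'   suppressed (default 10).
#' @param rng_seed Seed for calibration reproducibility.
#' @param calibration_samples,calibration_length Null-simulation size per
#'   query passed to [calibrate()].
#' @param seed_k,kmer_threshold,ungapped_threshold,max_seeds Internal
#'   seeding controls, see [kmer_seed_search()].
#' @param bias_correction Apply the composition-bias score adjustment
#'   (disable with `FALSE`).
#' @param keep_rejected Keep records of candidates rejected at a filter
#'   stage (with their stage label) in the result.
#' @return A `cloudfb_hits` object: a data frame of hits sorted by
#'   ascending E-value (columns `query`, `target`, `qstart`, `qend`,
#'   `tstart`, `tend`, `bitscore`, `evalue`, `cloud_fraction`, `stage`,
#'   plus diagnostic columns), with per-hit alignments in
#'   `attr(x, "alignments")` and per-query calibrations in
#'   `attr(x, "calibrations")`.
#' @export
search <- function(queries, targets, seeds = NULL,
                   params = prune_params(),
                   thresholds = filter_thresholds(),
                   full_dp = FALSE, E_max = 10, rng_seed = 42L,
                   calibration_samples = 1000L, calibration_length = 100L,
                   seed_k = 6L, kmer_threshold = 3, ungapped_threshold = 8,
                   max_seeds = 1000L, bias_correction = TRUE,
                   keep_rejected = FALSE) {
  if (inherits(queries, "target_seq")) queries <- profile_from_sequence(queries)
  if (inherits(queries, "profile_hmm")) queries <- list(queries)
  if (inherits(targets, "target_seq")) targets <- list(targets)
  stopifnot(length(queries) >= 1)
  db_size <- length(targets)
  tnames <- vapply(targets, function(t) t$name, "")

  rows <- list()
  alns <- list()
  calibs <- list()

  for (qi in seq_along(queries)) {
    q <- with_prep(queries[[qi]])
    calib <- calibrate(q, n_samples = calibration_samples,
                       rng_seed = rng_seed + qi - 1L,
                       null_length = calibration_length)
    calibs[[q$name]] <- calib

    for (ti in seq_along(targets)) {
      t <- targets[[ti]]
      rec <- tryCatch(
        .search_one(q, t, calib, db_size, seeds, params, thresholds,
                    full_dp, seed_k, kmer_threshold, ungapped_threshold,
                    max_seeds, bias_correction),
        error = function(e) {
          warning(sprintf("candidate %s vs %s failed: %s", q$name, t$name,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(rec)) next
      if (rec$row$stage != "pass" && !keep_rejected) next
      rows[[length(rows) + 1L]] <- rec$row
      if (!is.null(rec$alignment))
        alns[[paste(q$name, t$name, sep = "\r")]] <- rec$alignment
    }
  }

  hits <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  keep <- hits$stage != "pass" | (!is.na(hits$evalue) & hits$evalue <= E_max)
  hits <- hits[keep, , drop = FALSE]
  ord <- order(hits$evalue, hits$query, hits$target)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, class = c("cloudfb_hits", "data.frame"),
            alignments = alns, calibrations = calibs, db_size = db_size)
}

.empty_hits <- function() {
  data.frame(query = character(0), target = character(0),
             qstart = integer(0), qend = integer(0),
             tstart = integer(0), tend = integer(0),
             bitscore = numeric(0), evalue = numeric(0),
             cloud_fraction = numeric(0), stage = character(0),
             seed_p = numeric(0), cloud_p = numeric(0),
             forward_p = numeric(0), bias_bits = numeric(0),
             fallback = logical(0))
}

# one query/target candidate through the staged pipeline
.search_one <- function(q, t, calib, db_size, seeds, params, thresholds,
                        full_dp, seed_k, kmer_threshold, ungapped_threshold,
                        max_seeds, bias_correction = TRUE) {
  row <- .empty_hits()[0, ]
  base <- data.frame(query = q$name, target = t$name,
                     qstart = NA_integer_, qend = NA_integer_,
                     tstart = NA_integer_, tend = NA_integer_,
                     bitscore = NA_real_, evalue = NA_real_,
                     cloud_fraction = NA_real_, stage = "seed",
                     seed_p = NA_real_, cloud_p = NA_real_,
                     forward_p = NA_real_, bias_bits = NA_real_,
                     fallback = FALSE)

  # --- seed stage: only the best-scoring seed per pair goes downstream ---
  if (!is.null(seeds)) {
    cand <- seeds[seeds$query == q$name & seeds$target == t$name, ,
                  drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(cand$pvalue), , drop = FALSE]
    sd <- seed(cand$qstart[1], cand$tstart[1], cand$qend[1], cand$tend[1],
               pvalue = cand$pvalue[1])
    base$seed_p <- cand$pvalue[1]
  } else {
    cand <- kmer_seed_search(q, t, k = seed_k,
                             kmer_threshold = kmer_threshold,
                             ungapped_threshold = ungapped_threshold,
                             max_seeds = max_seeds)
    if (!nrow(cand)) return(NULL)
    base$seed_p <- pvalue(cand$score[1], calib, "gapped_max")
    sd <- seed(cand$ib[1], cand$jb[1], cand$ie[1], cand$je[1],
               score = cand$score[1], pvalue = base$seed_p)
  }
  if (base$seed_p >= thresholds$seed_p) {
    base$stage <- "seed"
    return(list(row = base, alignment = NULL))
  }

  m <- q$m; n <- t$n
  if (full_dp) {
    fwd <- forward_full(q, t)
    fscore <- fwd$score
    base$cloud_fraction <- 1
    base$forward_p <- pvalue(fscore, calib, "forward")
    if (base$forward_p > thresholds$forward_p) {
      base$stage <- "forward"
      return(list(row = base, alignment = NULL))
    }
    bkwd <- backward_full(q, t)
    post <- posterior_full(fwd, bkwd)
    aln <- mea_full(post)
  } else {
    cf <- cloud_search_forward(q, t, sd, params)
    cb <- cloud_search_backward(q, t, sd, params)
    u <- cloud_union(cf$bounds, cb$bounds)
    if (is.null(u)) {
      rb <- fallback_rectangle(sd)
      base$fallback <- TRUE
    } else {
      cs <- cloud_scores(cf$best, cf$best_in, cb$best, cb$best_in)
      est <- cloud_filter_estimate(cs)
      base$cloud_p <- pvalue(est, calib, "forward")
      if (base$cloud_p > thresholds$cloud_p) {
        base$stage <- "cloud"
        return(list(row = base, alignment = NULL))
      }
      rb <- reorient_to_rows(trim_cloud(u))
    }
    layout <- build_layout(rb, m, n)
    st <- cloud_stats(rb, m, n)
    base$cloud_fraction <- st$fraction
    fwd <- sparse_forward(q, t, layout)
    fscore <- fwd$score
    base$forward_p <- pvalue(fscore, calib, "forward")
    if (base$forward_p > thresholds$forward_p) {
      base$stage <- "forward"
      return(list(row = base, alignment = NULL))
    }
    bkwd <- sparse_backward(q, t, layout)
    post <- sparse_posterior(fwd, bkwd)
    aln <- sparse_mea(post)
  }

  bnd <- define_boundaries(post)
  tstart <- suppressWarnings(min(c(aln$tstart, bnd$tstart), na.rm = TRUE))
  tend <- suppressWarnings(max(c(aln$tend, bnd$tend), na.rm = TRUE))
  if (!is.finite(tstart) || !is.finite(tend)) {
    tstart <- NA_integer_; tend <- NA_integer_
  }
  bias <- if (bias_correction) bias_correct(post, q, t, tstart, tend) else 0
  final <- fscore - bias
  p_final <- pvalue(final, calib, "forward")

  base$stage <- "pass"
  base$qstart <- aln$qstart; base$qend <- aln$qend
  base$tstart <- as.integer(tstart); base$tend <- as.integer(tend)
  base$bias_bits <- nats_to_bits(bias)
  base$bitscore <- nats_to_bits(final)
  base$evalue <- evalue(p_final, db_size)
  list(row = base, alignment = aln)
}

#' @export
print.cloudfb_hits <- function(x, ...) {
  cat(sprintf("cloudfb_hits: %d hits over %d targets\n", nrow(x),
              attr(x, "db_size")))
  if (nrow(x)) {
    print.data.frame(head(as.data.frame(x)[, c("query", "target", "qstart",
                                               "qend", "tstart", "tend",
                                               "bitscore", "evalue",
                                               "stage")], 20))
  }
  invisible(x)
}

#' Alignment stored for a hit
#'
#' @param hits A `cloudfb_hits` object.
#' @param query,target Pair identifiers.
#' @return The `alignment` object, or `NULL` if the pair has none.
#' @export
hit_alignment <- function(hits, query, target) {
  attr(hits, "alignments")[[paste(query, target, sep = "\r")]]
}

#' Write a search report
#'
#' Tab-separated report sorted by ascending E-value, with a header line.
#' Optionally appends human-readable alignment blocks with a per-position
#' posterior confidence band.
#'
#' @param hits A `cloudfb_hits` object.
#' @param path Output path.
#' @param alignments Append alignment blocks.
#' @return `path`, invisibly.
#' @export
write_report <- function(hits, path, alignments = FALSE) {
  df <- as.data.frame(hits)
  df <- df[df$stage == "pass", , drop = FALSE]
  cols <- c("query", "target", "qstart", "qend", "tstart", "tend",
            "bitscore", "evalue", "cloud_fraction", "stage")
  out <- df[, cols]
  out$bitscore <- sprintf("%.2f", out$bitscore)
  out$evalue <- sprintf("%.3g", out$evalue)
  out$cloud_fraction <- sprintf("%.4f", out$cloud_fraction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  if (alignments && nrow(df)) {
    for (r in seq_len(nrow(df))) {
      a <- hit_alignment(hits, df$query[r], df$target[r])
      if (is.null(a)) next
      writeLines(sprintf("# %s vs %s  q[%d-%d] t[%d-%d]",
                         df$query[r], df$target[r], a$qstart, a$qend,
                         a$tstart, a$tend), con)
      writeLines(paste0("# states: ", paste(a$path$state, collapse = "")),
                 con)
    }
  }
  invisible(path)
}
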