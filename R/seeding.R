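# Seed generation: an internal k-mer based prefilter (double co-diagonal
# k-mer match -> ungapped extension -> banded gapped Viterbi), and a reader
# for external m8-style seed files.

#' k-mer seed search
#'
#' A three-stage prefilter producing alignment seeds for a query/target
#' pair, in the style of fast k-mer seeded protein search tools:
#' (i) candidate diagonals must carry two non-overlapping length-`k`
#' windows whose summed match log-odds exceed `kmer_threshold`;
#' (ii) each candidate diagonal's best ungapped segment score must exceed
#' `ungapped_threshold`; (iii) surviving diagonals are aligned with a
#' banded gapped Viterbi to produce the seed's begin/end cells and gapped
#' score.  At most `max_seeds` candidates are returned, best first.
#'
#' @param profile A [profile_hmm()].
#' @param target A [target_sequence()].
#' @param k k-mer length (>= 3).
#' @param kmer_threshold Minimum summed log-odds (nats) of a length-`k`
#'   diagonal window.
#' @param ungapped_threshold Minimum ungapped segment score (nats).
#' @param max_seeds Maximum number of seeds returned.
#' @param band Half-width of the gapped-alignment band around a diagonal.
#' @return Data frame of seed candidates: `query`, `target`, `ib`, `jb`,
#'   `ie`, `je`, `ungapped`, `score` (gapped, nats); zero rows when nothing
#'   survives (including when `k` exceeds either length).
#' @export
kmer_seed_search <- function(profile, target, k = 6L,
                             kmer_threshold = 3, ungapped_threshold = 8,
                             max_seeds = 1000L, band = 8L) {
  stopifnot(k >= 3)
  empty <- data.frame(query = character(0), target = character(0),
                      ib = integer(0), jb = integer(0), ie = integer(0),
                      je = integer(0), ungapped = numeric(0),
                      score = numeric(0))
  m <- profile$m; n <- target$n
  if (k > m || k > n) return(empty)
  prep <- prep_profile(profile)
  # per-cell match log-odds, model position x target position
  S <- prep$msc[-1, target$residues, drop = FALSE]
  S[!is.finite(S)] <- -30  # keep segment arithmetic finite

  cand <- list()
  for (g in (1L - m):(n - 1L)) {  # diagonal g = j - i
    ilo <- max(1L, 1L - g); ihi <- min(m, n - g)
    len <- ihi - ilo + 1L
    if (len < k) next
    v <- S[cbind(ilo:ihi, (ilo:ihi) + g)]
    cs <- cumsum(c(0, v))
    win <- cs[(k + 1L):(len + 1L)] - cs[seq_len(len - k + 1L)]
    hits <- which(win >= kmer_threshold)
    if (length(hits) < 2L) next
    if (max(hits) - min(hits) < k) next  # need two non-overlapping windows
    # stage (ii): best ungapped segment on the diagonal (Kadane)
    best <- run <- 0
    for (x in v) { run <- max(0, run + x); best <- max(best, run) }
    if (best < ungapped_threshold) next
    cand[[length(cand) + 1L]] <- c(g = g, ungapped = best)
  }
  if (!length(cand)) return(empty)
  cand <- as.data.frame(do.call(rbind, cand))
  cand <- cand[order(-cand$ungapped), , drop = FALSE]
  cand <- head(cand, max_seeds)

  out <- lapply(seq_len(nrow(cand)), function(r) {
    bv <- cpp_banded_viterbi(prep, target$residues, cand$g[r], band)
    if (!is.finite(bv$score) || is.na(bv$qstart)) return(NULL)
    data.frame(query = profile$name, target = target$name,
               ib = bv$qstart, jb = bv$tstart, ie = bv$qend, je = bv$tend,
               ungapped = cand$ungapped[r], score = bv$score)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty)
  # best-scoring first; deterministic tie-break on coordinates
  out <- out[order(-out$score, out$ib, out$jb), , drop = FALSE]
  rownames(out) <- NULL
  head(out, max_seeds)
}

#' Read an external seed file
#'
#' Ingests a BLAST m8-style TSV of prefilter alignments (columns `query`,
#' `target`, `qstart`, `qend`, `tstart`, `tend`, `evalue`; 1-based
#' inclusive, query coordinates already in profile/consensus positions).
#' E-values are converted to P-values by inverting the database-size
#' adjustment, and candidates failing the seed filter (P >= `seed_p`)
#' are dropped.
#'
#' @param path TSV path (no header).
#' @param queries,targets Lists of profiles / target sequences the ids
#'   must resolve against.
#' @param db_size Database size the E-values were computed with; defaults
#'   to `length(targets)`.
#' @param seed_p Seed filter threshold.
#' @return Data frame with the file columns plus `pvalue`.
#' @export
read_seed_file <- function(path, queries, targets,
                           db_size = length(targets), seed_p = 0.01) {
  cols <- c("query", "target", "qstart", "qend", "tstart", "tend", "evalue")
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0 ||
      !length(readLines(path, n = 1))) {
    df <- as.data.frame(setNames(rep(list(character(0)), 7), cols))
    df$pvalue <- numeric(0)
    return(df)
  }
  df <- read.table(path, sep = "\t", col.names = cols,
                   stringsAsFactors = FALSE)
  qnames <- vapply(queries, function(q) q$name, "")
  tnames <- vapply(targets, function(t) t$name, "")
  badq <- setdiff(unique(df$query), qnames)
  if (length(badq)) stop(sprintf("unknown query id '%s' in seed file",
                                 badq[1]))
  badt <- setdiff(unique(df$target), tnames)
  if (length(badt)) stop(sprintf("unknown target id '%s' in seed file",
                                 badt[1]))
  if (any(df$qstart > df$qend))
    stop("seed file has qstart > qend")
  if (any(df$tstart > df$tend))
    stop("seed file has tstart > tend")
  df$pvalue <- pvalue_from_evalue(df$evalue, db_size)
  df <- df[df$pvalue < seed_p, , drop = FALSE]
  rownames(df) <- NULL
  df
}
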