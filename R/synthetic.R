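# Synthetic benchmark generator: family profiles, divergent homologs
# embedded mid-sequence in shuffled decoys, pure-decoy databases, and the
# recall evaluator.  Everything is reproducible from an integer seed.

#' Generate a synthetic family profile
#'
#' Match emissions are peaked: each position has one dominant residue
#' (probability `peak`) with the remaining mass spread as the background;
#' transitions favor match-match.
#'
#' @param m Model length.
#' @param peak Dominant-residue emission probability.
#' @param name Model name.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A [profile_hmm()].
#' @export
make_profile <- function(m, peak = 0.45, name = "synthetic", seed = NULL) {
  gen <- function() {
    alphabet <- amino_alphabet()
    dom <- sample.int(alphabet$k, m, replace = TRUE)
    em <- matrix(rep((1 - peak) * alphabet$background, each = m), m)
    em[cbind(seq_len(m), dom)] <- em[cbind(seq_len(m), dom)] + peak
    tuple <- c(MM = 0.90, MD = 0.05, MI = 0.05, II = 0.4, IM = 0.6,
               DD = 0.4, DM = 0.6)
    tr <- matrix(rep(tuple, each = m + 1), m + 1)
    profile_hmm(name, em, tr, alphabet = alphabet)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Sample a divergent homolog of a profile
#'
#' Walks the profile's match states emitting the consensus residue at each
#' position, then adds noise: each residue is substituted with a background
#' draw with probability `divergence` (so `divergence = 0` reproduces the
#' consensus and the expected residue identity is roughly
#' `1 - divergence`); insertions (background residues) and deletions each
#' occur with probability `indel_rate` per position.
#'
#' @param profile A [profile_hmm()].
#' @param divergence Per-position substitution probability.
#' @param indel_rate Per-position insertion/deletion probability.
#' @param name Sequence name.
#' @param seed Optional integer seed.
#' @return A [target_sequence()].
#' @export
sample_homolog <- function(profile, divergence = 0.3, indel_rate = 0.02,
                           name = "homolog", seed = NULL) {
  gen <- function() {
    k <- profile$alphabet$k
    bg <- profile$alphabet$background
    cons <- digitize(profile$consensus, profile$alphabet)
    res <- integer(0)
    for (i in seq_len(profile$m)) {
      if (runif(1) < indel_rate) next  # deletion
      r <- cons[i]
      if (runif(1) < divergence) r <- sample.int(k, 1, prob = bg)
      res <- c(res, r)
      if (runif(1) < indel_rate)      # insertion
        res <- c(res, sample.int(k, 1, prob = bg))
    }
    if (!length(res)) res <- sample.int(k, 1, prob = bg)
    target_sequence(name, res, profile$alphabet)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Shuffle a sequence
#'
#' Random permutation of the residues: composition and length are
#' preserved exactly, order is destroyed.
#'
#' @param x A [target_sequence()].
#' @param name Name of the shuffled sequence.
#' @param seed Optional integer seed.
#' @return A [target_sequence()].
#' @export
shuffle_sequence <- function(x, name = paste0(x$name, "-shuffled"),
                             seed = NULL) {
  gen <- function() target_sequence(name, sample(x$residues))
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Random background sequence
#'
#' Residues drawn i.i.d. from the background distribution (the
#' distributional equivalent of sampling a natural sequence and shuffling
#' it).
#'
#' @param n Length.
#' @param name Sequence name.
#' @param seed Optional integer seed.
#' @return A [target_sequence()].
#' @export
random_sequence <- function(n, name = "decoy", seed = NULL) {
  alphabet <- amino_alphabet()
  gen <- function()
    target_sequence(name, sample.int(alphabet$k, n, replace = TRUE,
                                     prob = alphabet$background), alphabet)
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Embed a sequence in the middle of a decoy
#'
#' Splices `true_seq` into the midpoint of `decoy`, mimicking the
#' sub-sequence nature of protein domains.
#'
#' @param true_seq The homologous [target_sequence()] to plant.
#' @param decoy The host decoy sequence.
#' @param name Name of the embedded sequence.
#' @return List with `seq` (the combined [target_sequence()]) and the
#'   planted interval `start`, `end` (1-based inclusive).
#' @export
embed_sequence <- function(true_seq, decoy, name = true_seq$name) {
  h <- decoy$n %/% 2L
  res <- c(decoy$residues[seq_len(h)], true_seq$residues,
           if (h < decoy$n) decoy$residues[(h + 1L):decoy$n])
  list(seq = target_sequence(name, res),
       start = h + 1L, end = h + true_seq$n)
}

#' Benchmark specification
#'
#' @param n_families Number of family profiles.
#' @param model_length Model length (single value or range to sample).
#' @param n_true Embedded homologs per family.
#' @param n_decoys Pure shuffled-decoy sequences.
#' @param divergence,indel_rate Homolog noise rates
#'   (see [sample_homolog()]).
#' @param decoy_length_mean,decoy_length_sd Decoy length distribution
#'   (normal, truncated at 30).
#' @param peak Profile emission peakedness.
#' @param seed Integer seed: generation is fully reproducible.
#' @return A `benchmark_spec` object.
#' @export
benchmark_spec <- function(n_families = 1L, model_length = 100L,
                           n_true = 20L, n_decoys = 200L,
                           divergence = 0.3, indel_rate = 0.02,
                           decoy_length_mean = 150, decoy_length_sd = 30,
                           peak = 0.45, seed = 7L) {
  stopifnot(n_families >= 0, n_true >= 0, n_decoys >= 0,
            divergence >= 0, divergence <= 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(as.list(environment()), class = "benchmark_spec")
}

#' Generate a synthetic benchmark
#'
#' Builds family profiles, a labeled target database (homologs embedded
#' mid-sequence in shuffled decoys, plus pure decoys) and a truth table
#' sufficient to recompute every evaluation number.
#'
#' @param spec A [benchmark_spec()].
#' @param dir Optional output directory; when given, writes
#'   `profiles.hmm`, `targets.fasta` and `truth.tsv` there.
#' @return List with `profiles` (list), `targets` (list), and `truth`
#'   (data frame: `target`, `family`, `start`, `end`, `is_true`).
#' @export
make_benchmark <- function(spec = benchmark_spec(), dir = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  withr_seed(spec$seed, {
    profiles <- list()
    targets <- list()
    truth <- list()
    rlen <- function() {
      max(30L, as.integer(round(rnorm(1, spec$decoy_length_mean,
                                      spec$decoy_length_sd))))
    }
    for (f in seq_len(spec$n_families)) {
      mlen <- if (length(spec$model_length) > 1)
        sample(spec$model_length[1]:spec$model_length[2], 1)
      else spec$model_length
      fam <- sprintf("fam%03d", f)
      profiles[[fam]] <- make_profile(mlen, peak = spec$peak, name = fam)
      for (s in seq_len(spec$n_true)) {
        hom <- sample_homolog(profiles[[fam]], spec$divergence,
                              spec$indel_rate,
                              name = sprintf("%s-true%03d", fam, s))
        decoy <- random_sequence(rlen())
        emb <- embed_sequence(hom, decoy)
        targets[[emb$seq$name]] <- emb$seq
        truth[[length(truth) + 1L]] <-
          data.frame(target = emb$seq$name, family = fam,
                     start = emb$start, end = emb$end, is_true = TRUE)
      }
    }
    for (s in seq_len(spec$n_decoys)) {
      nm <- sprintf("decoy%05d", s)
      targets[[nm]] <- random_sequence(rlen(), name = nm)
      truth[[length(truth) + 1L]] <-
        data.frame(target = nm, family = NA_character_,
                   start = NA_integer_, end = NA_integer_, is_true = FALSE)
    }
    truth <- do.call(rbind, truth)
    out <- list(profiles = profiles, targets = targets, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      if (length(profiles))
        write_profiles(profiles, file.path(dir, "profiles.hmm"))
      write_fasta(unname(targets), file.path(dir, "targets.fasta"))
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Identity of a sequence to a profile consensus
#'
#' Fraction of consensus positions matched identically in a simple
#' ungapped best-offset comparison; used to characterize homolog
#' divergence settings.
#'
#' @param x A [target_sequence()].
#' @param profile A [profile_hmm()].
#' @return Identity fraction in `[0, 1]`.
#' @export
consensus_identity <- function(x, profile) {
  cons <- digitize(profile$consensus, profile$alphabet)
  m <- length(cons); n <- x$n
  best <- 0
  for (off in -(m - 1):(n - 1)) {
    i <- seq_len(m)
    j <- i + off
    ok <- j >= 1 & j <= n
    if (!any(ok)) next
    best <- max(best, sum(cons[i[ok]] == x$residues[j[ok]]) / m)
  }
  best
}

#' Evaluate a ranked hit list against the truth table
#'
#' Applies the benchmark's labeling convention: a hit is a true positive
#' when its query matches the target's planted family and the alignment
#' covers at least `coverage` of the planted interval; a hit entirely
#' within shuffled sequence (pure decoy target, or no overlap with the
#' planted interval) is a false positive; other hits (wrong family, or
#' partial coverage) are neutral.  `recall0` is the fraction of all
#' planted positives ranked (by ascending E-value) above the best false
#' positive.
#'
#' @param hits A `cloudfb_hits` object (or data frame with `query`,
#'   `target`, `tstart`, `tend`, `evalue`).
#' @param truth Truth table from [make_benchmark()].
#' @param coverage Minimum planted-interval coverage for a true positive.
#' @return List with `recall0`, `n_true`, `n_found`, and `curve` (data
#'   frame of recall vs. false-positive count).
#' @export
evaluate_ranking <- function(hits, truth, coverage = 0.5) {
  df <- as.data.frame(hits)
  df <- df[!is.na(df$evalue), , drop = FALSE]
  df <- df[order(df$evalue), , drop = FALSE]
  n_true_total <- sum(truth$is_true)
  lab <- character(nrow(df))
  for (r in seq_len(nrow(df))) {
    tt <- truth[truth$target == df$target[r], , drop = FALSE]
    if (!nrow(tt)) { lab[r] <- "neutral"; next }
    if (!tt$is_true[1]) { lab[r] <- "fp"; next }
    ov <- max(0, min(df$tend[r], tt$end[1]) - max(df$tstart[r], tt$start[1])
              + 1)
    if (ov == 0) { lab[r] <- "fp"; next }      # entirely in shuffled flank
    if (!identical(df$query[r], tt$family[1])) { lab[r] <- "neutral"; next }
    cov <- ov / (tt$end[1] - tt$start[1] + 1)
    lab[r] <- if (cov >= coverage) "tp" else "neutral"
  }
  # one credit per planted positive (best-ranked alignment counts)
  seen <- character(0)
  tp_cum <- fp_cum <- integer(nrow(df))
  tp <- fp <- 0L
  for (r in seq_len(nrow(df))) {
    if (lab[r] == "tp" && !(df$target[r] %in% seen)) {
      tp <- tp + 1L
      seen <- c(seen, df$target[r])
    } else if (lab[r] == "fp") fp <- fp + 1L
    tp_cum[r] <- tp
    fp_cum[r] <- fp
  }
  recall0 <- if (any(lab == "fp")) {
    tp_cum[which(lab == "fp")[1]] / n_true_total
  } else tp / max(n_true_total, 1L)
  curve <- data.frame(fp = fp_cum, recall = tp_cum / max(n_true_total, 1L))
  list(recall0 = recall0, n_true = n_true_total, n_found = tp,
       curve = curve)
}
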