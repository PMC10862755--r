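# Profile-HMM data model: construction, validation, HMMER3 ASCII I/O,
# single-sequence profiles, and target sequences.

#' Construct a profile HMM
#'
#' Low-level constructor for the query model.  A profile of length `m` has
#' per-position match emission distributions, a single insert emission
#' distribution shared by all insert states (the common convention; it
#' normally equals the background), and per-node core transitions.  Local
#' alignment uses begin/end wrapper states configured at alignment time:
#' entry into every match state has probability `2 / (m (m + 1))` and exit
#' from any match state is free, which places uniform probability on each
#' alignment fragment (the implicit probabilistic model of local
#' alignment); N/C flanking loops are target-length dependent.
#'
#' @param name Model name.
#' @param match_emissions `m x k` matrix of match emission probabilities;
#'   rows must sum to one.
#' @param transitions `(m + 1) x 7` matrix of core transition probabilities
#'   with columns `MM, MD, MI, II, IM, DD, DM` (row 1 is the begin node 0).
#' @param insert_emissions Length-`k` insert emission distribution shared by
#'   all insert states; defaults to the background.
#' @param consensus Length-`m` consensus string; defaults to the per-position
#'   emission argmax.
#' @param alphabet An [amino_alphabet()].
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, transitions,
                        insert_emissions = NULL, consensus = NULL,
                        alphabet = amino_alphabet()) {
  match_emissions <- as.matrix(match_emissions)
  m <- nrow(match_emissions)
  if (is.null(insert_emissions)) insert_emissions <- alphabet$background
  if (is.null(consensus)) {
    consensus <- paste(alphabet$symbols[apply(match_emissions, 1, which.max)],
                       collapse = "")
  }
  p <- structure(
    list(name = name, m = m,
         match_emissions = match_emissions,
         insert_emissions = as.numeric(insert_emissions),
         transitions = as.matrix(transitions),
         consensus = consensus,
         alphabet = alphabet),
    class = "profile_hmm")
  validate_profile(p)
  p
}

# column order of the core transition matrix (spec 7-tuple order)
TR_COLS <- c("MM", "MD", "MI", "II", "IM", "DD", "DM")

#' Validate profile-HMM invariants
#'
#' Checks that every match emission row sums to one, that the three outgoing
#' transition groups (from M, from I, from D) each sum to one, and that the
#' model has at least one position.
#'
#' @param p A `profile_hmm`.
#' @param tol Tolerance on probability sums.
#' @return `p`, invisibly; errors describe the failing position.
#' @export
validate_profile <- function(p, tol = 1e-6) {
  stopifnot(inherits(p, "profile_hmm"))
  if (p$m < 1) stop("profile must have m >= 1")
  k <- p$alphabet$k
  if (ncol(p$match_emissions) != k)
    stop("match emission matrix must have k columns")
  rs <- rowSums(p$match_emissions)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("match emission row %d sums to %.8f, not 1",
                 which(abs(rs - 1) > tol)[1], rs[which(abs(rs - 1) > tol)[1]]))
  if (abs(sum(p$insert_emissions) - 1) > tol)
    stop("insert emission distribution does not sum to 1")
  tr <- p$transitions
  if (nrow(tr) != p$m + 1 || ncol(tr) != 7)
    stop("transition matrix must be (m+1) x 7")
  colnames(tr) <- TR_COLS
  gm <- tr[, "MM"] + tr[, "MD"] + tr[, "MI"]
  gi <- tr[, "II"] + tr[, "IM"]
  gd <- tr[, "DD"] + tr[, "DM"]
  for (g in list(M = gm, I = gi, D = gd)) {
    bad <- which(abs(g - 1) > tol)
    if (length(bad))
      stop(sprintf("outgoing transition group does not sum to 1 at node %d",
                   bad[1] - 1L))
  }
  invisible(p)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': m = %d positions, alphabet k = %d\n",
              x$name, x$m, x$alphabet$k))
  cat(sprintf("consensus: %s\n", x$consensus))
  invisible(x)
}

# Prepared (log-odds) form consumed by the C++ kernels: match/insert score
# matrices (m+1) x (k+1) with a wildcard column of zeros, log transitions,
# and log local-entry probabilities.
prep_profile <- function(p) {
  pr <- attr(p, "prep")
  if (!is.null(pr)) return(pr)
  m <- p$m
  bg <- p$alphabet$background
  msc <- rbind(-Inf, log(sweep(p$match_emissions, 2, bg, "/")))
  isc <- matrix(rep(log(p$insert_emissions / bg), each = m + 1), m + 1)
  msc <- cbind(msc, 0)
  isc <- cbind(isc, 0)
  msc[1, ] <- -Inf
  tr <- log(p$transitions)
  # implicit-model local entry: probability 2/(m(m+1)) into every match
  # state, with free exit, puts uniform mass on each alignment fragment
  # (i <= j) and sums to exactly 1 over fragments
  entry <- c(-Inf, rep(log(2) - log(m * (m + 1)), m))
  list(msc = msc, isc = isc, tr = tr, entry = entry, m = m)
}

# attach the prepared form so repeated alignments against the same profile
# skip the log conversions
with_prep <- function(p) {
  if (is.null(attr(p, "prep"))) attr(p, "prep") <- prep_profile(p)
  p
}

# prepared form of the reversed model (reversed emissions; transitions
# re-read in the reverse direction, swapping the MI/IM and MD/DM roles).
# Path products are preserved exactly, so running the forward machinery on
# this prep is the mirror image of running it on the original — note the
# reversed transition groups are not themselves normalized distributions
# (HMM reversal would need stationary reweighting), which is irrelevant
# for mirrored path scores.
.prep_reversed <- function(p) {
  prep <- prep_profile(p)
  m <- p$m
  msc <- prep$msc
  msc[2:(m + 1), ] <- msc[(m + 1):2, , drop = FALSE]
  isc <- prep$isc[c(m + 1, m:1), , drop = FALSE]
  tr <- prep$tr
  src <- (m + 1):1                     # node m - i' for i' = 0..m
  tr <- cbind(MM = prep$tr[src, 1], MD = prep$tr[src, 7],
              MI = prep$tr[src, 5], II = prep$tr[src, 4],
              IM = prep$tr[src, 3], DD = prep$tr[src, 6],
              DM = prep$tr[src, 2])
  list(msc = msc, isc = isc, tr = tr, entry = prep$entry, m = m)
}

#' Target sequence
#'
#' A digitized protein sequence.  Residues are stored as 1-based indices
#' over the alphabet, with ambiguity codes mapped to the wildcard code.
#'
#' @param name Sequence identifier.
#' @param x Either a residue string or an already-digitized integer vector.
#' @param alphabet An [amino_alphabet()].
#' @return Object of class `target_seq` with fields `name`, `residues`, `n`.
#' @export
target_sequence <- function(name, x, alphabet = amino_alphabet()) {
  res <- if (is.character(x)) digitize(x, alphabet) else as.integer(x)
  if (length(res) < 1) stop(sprintf("sequence '%s' is empty", name))
  if (any(res < 1L | res > alphabet$wildcard))
    stop(sprintf("sequence '%s' has residue codes outside the alphabet", name))
  structure(list(name = name, residues = res, n = length(res)),
            class = "target_seq")
}

#' @export
print.target_seq <- function(x, ...) {
  cat(sprintf("target_seq '%s': n = %d\n", x$name, x$n))
  invisible(x)
}

# ---------------------------------------------------------------------------
# HMMER3 ASCII profile I/O
# ---------------------------------------------------------------------------

.parse_logprob <- function(tok, lineno) {
  v <- suppressWarnings(as.numeric(tok))
  v[tok == "*"] <- Inf
  if (anyNA(v))
    stop(sprintf("line %d: unparseable probability field '%s'",
                 lineno, tok[which(is.na(v))[1]]))
  exp(-v)
}

#' Read HMMER3 ASCII profiles
#'
#' Parses one or more profile records from a HMMER3 ASCII (`HMMER3/f`
#' dialect) file.  Stored negative-natural-log values are exponentiated into
#' probabilities; the consensus column is extracted when present (otherwise
#' the per-position emission argmax is used).  Calibration (`STATS`) lines
#' are ignored: score statistics are recomputed by [calibrate()].
#'
#' @param path Path to a `.hmm` file.
#' @return List of [profile_hmm()] objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  out <- list()
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    while (i <= nl && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > nl) break
    if (!grepl("^HMMER3/f", lines[i]))
      stop(sprintf("line %d: expected 'HMMER3/f' header, got '%s'",
                   i, substr(lines[i], 1, 30)))
    i <- i + 1L
    name <- NULL; leng <- NULL; alph <- NULL
    while (i <= nl && !grepl("^HMM\\s", lines[i])) {
      key <- sub("^(\\S+).*", "\\1", lines[i])
      val <- trimws(sub("^\\S+\\s*", "", lines[i]))
      if (key == "NAME") name <- val
      if (key == "LENG") leng <- as.integer(val)
      if (key == "ALPH") alph <- tolower(val)
      i <- i + 1L
    }
    if (i > nl) stop("truncated record: no HMM line found")
    if (is.null(name) || is.null(leng))
      stop(sprintf("line %d: record is missing NAME or LENG", i))
    if (!identical(alph, "amino"))
      stop(sprintf("unsupported alphabet '%s' (only 'amino' is supported)",
                   alph))
    alphabet <- amino_alphabet()
    k <- alphabet$k
    i <- i + 2L  # skip the two HMM header lines (residues, transition order)
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (identical(toks[1], "COMPO")) i <- i + 1L
    # node 0: insert emission line + transition line
    ins0 <- .parse_logprob(strsplit(trimws(lines[i]), "\\s+")[[1]][1:k], i)
    i <- i + 1L
    tr <- matrix(NA_real_, leng + 1L, 7L,
                 dimnames = list(NULL, TR_COLS))
    t0 <- .parse_logprob(strsplit(trimws(lines[i]), "\\s+")[[1]][1:7], i)
    # file order m->m m->i m->d i->m i->i d->m d->d  ->  spec order
    tr[1L, ] <- t0[c(1, 3, 2, 5, 4, 7, 6)]
    i <- i + 1L
    em <- matrix(NA_real_, leng, k)
    cons <- character(leng)
    for (node in seq_len(leng)) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) < k + 1L || suppressWarnings(as.integer(toks[1])) != node)
        stop(sprintf("line %d: expected match line for node %d", i, node))
      em[node, ] <- .parse_logprob(toks[2:(k + 1L)], i)
      extra <- toks[-seq_len(k + 1L)]
      cons[node] <- if (length(extra) >= 2 && nchar(extra[2]) == 1 &&
                        extra[2] != "-") extra[2] else NA_character_
      i <- i + 1L
      iem <- .parse_logprob(strsplit(trimws(lines[i]), "\\s+")[[1]][1:k], i)
      if (node == 1L) ins1 <- iem
      i <- i + 1L
      tn <- .parse_logprob(strsplit(trimws(lines[i]), "\\s+")[[1]][1:7], i)
      tr[node + 1L, ] <- tn[c(1, 3, 2, 5, 4, 7, 6)]
      i <- i + 1L
    }
    if (i > nl || !grepl("^//", lines[i]))
      stop(sprintf("line %d: expected record terminator '//'", i))
    i <- i + 1L
    if (anyNA(cons))
      cons <- alphabet$symbols[apply(em, 1, which.max)]
    # stored values have limited precision; renormalize to exact sums
    em <- em / rowSums(em)
    tr[, c("MM", "MD", "MI")] <- tr[, c("MM", "MD", "MI"), drop = FALSE] /
      rowSums(tr[, c("MM", "MD", "MI"), drop = FALSE])
    tr[, c("II", "IM")] <- tr[, c("II", "IM"), drop = FALSE] /
      rowSums(tr[, c("II", "IM"), drop = FALSE])
    tr[, c("DD", "DM")] <- tr[, c("DD", "DM"), drop = FALSE] /
      rowSums(tr[, c("DD", "DM"), drop = FALSE])
    ins <- if (exists("ins1", inherits = FALSE)) ins1 else ins0
    out[[length(out) + 1L]] <- profile_hmm(
      name = name, match_emissions = em, transitions = tr,
      insert_emissions = ins / sum(ins),
      consensus = paste(cons, collapse = ""), alphabet = alphabet)
  }
  if (!length(out)) stop(sprintf("no profile records found in %s", path))
  out
}

#' Write profiles as HMMER3 ASCII
#'
#' Inverse of [read_profiles()] (modulo fields the package does not model,
#' which are written with placeholder values).  Probabilities are stored as
#' negative natural logs with enough digits to round-trip to within 1e-9.
#'
#' @param profiles A `profile_hmm` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "profile_hmm")) profiles <- list(profiles)
  fmt <- function(p) {
    ifelse(p <= 0, "*", sprintf("%.9f", -log(p)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    k <- p$alphabet$k
    cat("HMMER3/f [cloudfb]\n", file = con)
    cat(sprintf("NAME  %s\n", p$name), file = con)
    cat(sprintf("LENG  %d\n", p$m), file = con)
    cat("ALPH  amino\n", file = con)
    cat("RF    no\n", file = con)
    cat("MM    no\n", file = con)
    cat("CONS  yes\n", file = con)
    cat("CS    no\n", file = con)
    cat("MAP   yes\n", file = con)
    cat(sprintf("HMM  %s\n", paste(sprintf("%8s", p$alphabet$symbols),
                                   collapse = " ")), file = con)
    cat("      m->m m->i m->d i->m i->i d->m d->d\n", file = con)
    tr_file <- function(row) {  # spec order -> file order
      paste(fmt(row[c(1, 3, 2, 5, 4, 7, 6)]), collapse = "  ")
    }
    ins <- paste(fmt(p$insert_emissions), collapse = "  ")
    cat(sprintf("          %s\n", ins), file = con)
    cat(sprintf("          %s\n", tr_file(p$transitions[1, ])), file = con)
    cons <- strsplit(p$consensus, "")[[1]]
    for (node in seq_len(p$m)) {
      cat(sprintf("  %5d   %s  %d %s - - -\n", node,
                  paste(fmt(p$match_emissions[node, ]), collapse = "  "),
                  node, cons[node]), file = con)
      cat(sprintf("          %s\n", ins), file = con)
      cat(sprintf("          %s\n", tr_file(p$transitions[node + 1, ])),
          file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# single-sequence profiles
# ---------------------------------------------------------------------------

# score-implied conditional substitution probabilities from a half-bit
# substitution matrix: q(c | a) proportional to bg_c * 2^(S[a,c]/2)
.subst_conditionals <- function(scoring, alphabet) {
  mats <- c("BLOSUM62", "BLOSUM45", "BLOSUM50", "BLOSUM80", "BLOSUM100",
            "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!scoring %in% mats)
    stop(sprintf("unknown scoring matrix '%s'; available: %s",
                 scoring, paste(mats, collapse = ", ")))
  e <- new.env()
  utils::data(list = scoring, package = "Biostrings", envir = e)
  S <- get(scoring, envir = e)[alphabet$symbols, alphabet$symbols]
  Q <- sweep(2 ^ (S / 2), 2, alphabet$background, "*")
  Q / rowSums(Q)
}

#' Profile from a single query sequence
#'
#' Builds a profile in which emission probabilities are not position
#' specific but depend only on the observed residue: position i emits with
#' the substitution-matrix-implied conditional distribution given the query
#' residue at i.  All positions share one fixed transition 7-tuple.
#'
#' @param seq A [target_sequence()] (or residue string).
#' @param scoring Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open Probability of opening an insertion or deletion
#'   (`M -> I` and `M -> D` each get this value).
#' @param gap_extend Probability of extending an insertion or deletion.
#' @param name Model name; defaults to the sequence name.
#' @return A [profile_hmm()] with `m` equal to the sequence length.
#' @export
profile_from_sequence <- function(seq, scoring = "BLOSUM62",
                                  gap_open = 0.02, gap_extend = 0.4,
                                  name = NULL) {
  if (is.character(seq)) seq <- target_sequence("query", seq)
  stopifnot(inherits(seq, "target_seq"), seq$n >= 1)
  alphabet <- amino_alphabet()
  Q <- .subst_conditionals(scoring, alphabet)
  res <- seq$residues
  # wildcard query positions emit the background
  em <- matrix(NA_real_, seq$n, alphabet$k)
  for (i in seq_len(seq$n)) {
    em[i, ] <- if (res[i] > alphabet$k) alphabet$background else Q[res[i], ]
  }
  tuple <- c(MM = 1 - 2 * gap_open, MD = gap_open, MI = gap_open,
             II = gap_extend, IM = 1 - gap_extend,
             DD = gap_extend, DM = 1 - gap_extend)
  tr <- matrix(rep(tuple, each = seq$n + 1), seq$n + 1)
  profile_hmm(name = if (is.null(name)) seq$name else name,
              match_emissions = em, transitions = tr,
              consensus = undigitize(res, alphabet), alphabet = alphabet)
}

#' Consensus sequence of a profile
#'
#' @param p A `profile_hmm`.
#' @return A [target_sequence()] holding the consensus residues.
#' @export
profile_consensus <- function(p) {
  target_sequence(paste0(p$name, "-consensus"), p$consensus, p$alphabet)
}

# ---------------------------------------------------------------------------
# FASTA I/O (via Biostrings)
# ---------------------------------------------------------------------------

#' Read a protein FASTA file
#'
#' @param path FASTA file of protein sequences; lowercase residues are
#'   case-folded, ambiguity codes map to the wildcard.
#' @return List of [target_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop(sprintf("no sequences in %s", path))
  nms <- sub("\\s.*$", "", names(aa))
  out <- vector("list", length(aa))
  for (s in seq_along(aa)) {
    str <- as.character(aa[[s]])
    out[[s]] <- tryCatch(
      target_sequence(nms[s], str),
      error = function(e) stop(sprintf("record '%s': %s", nms[s],
                                       conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs A `target_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "target_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    cat(sprintf(">%s\n%s\n", s$name, undigitize(s$residues)), file = con)
  }
  invisible(path)
}
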