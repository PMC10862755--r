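# Shared fixtures: random model/sequence generators used across tests.

# log-sum-exp over a vector
lse <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

# random profile with Dirichlet-ish emissions and valid random transitions
rand_profile <- function(m, name = "p") {
  a <- amino_alphabet()
  em <- matrix(rgamma(m * a$k, 0.5), m)
  em <- em / rowSums(em)
  tr <- t(replicate(m + 1, {
    mm <- rgamma(3, 1); mm <- mm / sum(mm)
    ii <- rgamma(2, 1); ii <- ii / sum(ii)
    dd <- rgamma(2, 1); dd <- dd / sum(dd)
    c(mm[1], mm[2], mm[3], ii[1], ii[2], dd[1], dd[2])
  }))
  profile_hmm(name, em, tr)
}

rand_target <- function(n, name = "t") {
  target_sequence(name, sample.int(20, n, replace = TRUE))
}

# a planted-homolog pair: profile plus a target with a homolog embedded
# mid-decoy; returns the pair and the planted interval
planted_pair <- function(m = 50, decoy_n = 100, divergence = 0.3,
                         peak = 0.35) {
  p <- make_profile(m, peak = peak)
  hom <- sample_homolog(p, divergence = divergence)
  emb <- embed_sequence(hom, random_sequence(decoy_n))
  list(profile = p, target = emb$seq, start = emb$start, end = emb$end)
}
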