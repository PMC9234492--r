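# Independent oracles used across test files.

# closed-form area of an amplitude/width-parameterized Gaussian peak
gaussian_area <- function(amplitude, sd) amplitude * sd * sqrt(2 * pi)

# expected choice share of each alternative position (1..k) under a single
# part-worth vector, averaged over the tasks of a coded design
logit_share_oracle <- function(design, beta) {
  U <- drop(design$X %*% beta)
  k <- design$n_alternatives + as.integer(design$opt_out)
  Um <- matrix(U, nrow = k)
  Pm <- apply(Um, 2, function(u) exp(u - max(u)) / sum(exp(u - max(u))))
  rowMeans(Pm)
}

# two-sample permutation p-value for the difference in means
permutation_p <- function(a, b, n_perm = 10000, seed = 1) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    n <- length(a)
    hits <- sum(replicate(n_perm, {
      idx <- sample(length(pool), n)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    }))
    (hits + 1) / (n_perm + 1)
  })
}

# brute-force check that a compact letter display encodes exactly the
# not-significantly-different relation
cld_matches_relation <- function(sig, letters_out) {
  k <- nrow(sig)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(strsplit(letters_out[i], "")[[1]],
                              strsplit(letters_out[j], "")[[1]])) > 0
    if (share == sig[i, j]) return(FALSE)  # share iff NOT different
  }
  TRUE
}

# enumerate all symmetric logical flag matrices for k groups
all_flag_matrices <- function(k) {
  np <- k * (k - 1) / 2
  lapply(seq_len(2^np) - 1, function(code) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(np) - 1)) > 0)
    m <- matrix(FALSE, k, k)
    m[upper.tri(m)] <- bits
    m | t(m)
  })
}
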