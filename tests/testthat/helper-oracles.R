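# Independent oracles used across the suite: brute-force path enumeration
# for the two-state HMM, all-pairs AUC, and small fixture builders.

# Exhaustive posterior/xi/log-likelihood over all 2^N state paths.
enum_posterior <- function(pi, A, emis) {
  N <- nrow(emis)
  paths <- as.matrix(expand.grid(rep(list(0:1), N)))
  probs <- apply(paths, 1, function(s) {
    p <- pi[s[1] + 1] * emis[1, s[1] + 1]
    if (N > 1) {
      for (n in 2:N) p <- p * A[s[n - 1] + 1, s[n] + 1] * emis[n, s[n] + 1]
    }
    p
  })
  Z <- sum(probs)
  gamma <- t(vapply(seq_len(N), function(n) {
    c(sum(probs[paths[, n] == 0]), sum(probs[paths[, n] == 1])) / Z
  }, numeric(2)))
  xi_sum <- matrix(0, 2, 2)
  if (N > 1) {
    for (n in seq_len(N - 1)) {
      for (i in 0:1) {
        for (j in 0:1) {
          xi_sum[i + 1, j + 1] <- xi_sum[i + 1, j + 1] +
            sum(probs[paths[, n] == i & paths[, n + 1] == j]) / Z
        }
      }
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, log_lik = log(Z))
}

# AUC by explicit comparison of every positive-negative pair, ties 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random valid two-state HMM parameters.
random_params <- function() {
  d <- runif(2, 0.05, 0.95)
  u <- runif(1, 0.05, 0.95)
  list(pi = c(u, 1 - u),
       A = matrix(c(d[1], 1 - d[1], 1 - d[2], d[2]), 2, 2, byrow = TRUE))
}

# Simulate binary observations from a symmetric-Bernoulli two-state HMM.
simulate_hmm_obs <- function(n, A, p_correct, pi = c(0.5, 0.5)) {
  s <- integer(n)
  s[1] <- rbinom(1, 1, pi[2])
  for (k in seq_len(n - 1)) {
    s[k + 1] <- rbinom(1, 1, A[s[k] + 1, 2])
  }
  o <- ifelse(runif(n) < p_correct, s, 1L - s)
  list(states = s, obs = as.integer(o))
}

# Bin-count fixture: one site, balanced libraries, baseline mean 100 with
# the treated IP count set per bin (vector y1).
make_site_counts <- function(y1, site_id = "s1", base = 100L) {
  L <- length(y1)
  data.frame(site_id = site_id, bin_index = seq_len(L) - 1L,
             x0 = rep(base, L), y0 = rep(base, L),
             x1 = rep(base, L), y1 = as.integer(y1),
             stringsAsFactors = FALSE)
}

balanced_sizes <- function() lib_sizes(1e8, 1e8, 1e8, 1e8)
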