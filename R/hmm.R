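# Two-state HMM engine: scaled forward-backward, posterior decoding and
# Baum-Welch EM with either an estimated symmetric Bernoulli emission
# (binary observations) or a fixed per-bin emission likelihood matrix.

EMIS_CLIP <- 1e-10
P_CORRECT_MIN <- 0.5
P_CORRECT_MAX <- 1 - 1e-6

validate_hmm_params <- function(pi, A) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  if (length(pi) != 2L || anyNA(pi) || any(pi < 0) || any(pi > 1) ||
      abs(sum(pi) - 1) > 1e-12) {
    stop("pi must be a length-2 probability vector summing to 1",
         call. = FALSE)
  }
  if (!all(dim(A) == c(2L, 2L)) || anyNA(A) || any(A < 0) || any(A > 1) ||
      any(abs(rowSums(A) - 1) > 1e-12)) {
    stop("A must be a 2x2 row-stochastic matrix", call. = FALSE)
  }
  list(pi = pi, A = A)
}

#' Clip emission likelihoods away from 0 and 1
#'
#' @param x Numeric vector or matrix of likelihoods.
#' @return `x` clipped to `[1e-10, 1 - 1e-10]`.
#' @export
clip_emission <- function(x) {
  pmin(pmax(x, EMIS_CLIP), 1 - EMIS_CLIP)
}

#' Emission likelihood matrix for binary observations
#'
#' Symmetric Bernoulli emission: a hidden state is observed correctly with
#' probability `p_correct` and flipped otherwise, giving
#' `B[i, j] = p` for `i == j` and `1 - p` otherwise.
#'
#' @param obs Integer vector over {0, 1}.
#' @param p_correct Probability in `[0.5, 1)` that the observation matches
#'   the hidden state.
#' @return An `N x 2` matrix of likelihoods, column `i` for hidden state
#'   `i - 1`.
#' @export
bernoulli_emission <- function(obs, p_correct) {
  if (any(!obs %in% c(0L, 1L))) {
    stop("observations must be binary (0/1)", call. = FALSE)
  }
  cbind(ifelse(obs == 0L, p_correct, 1 - p_correct),
        ifelse(obs == 1L, p_correct, 1 - p_correct))
}

#' Random starting parameters for Baum-Welch
#'
#' Defaults used throughout the package: uniform initial distribution,
#' transition diagonal drawn from U(0.6, 0.95), Bernoulli correctness
#' probability drawn from U(0.7, 0.95). Drawn from the current RNG stream;
#' callers seed once per run for reproducibility.
#'
#' @return A list with elements `pi`, `A`, `p_correct`.
#' @export
random_hmm_init <- function() {
  d <- runif(2, 0.6, 0.95)
  list(pi = c(0.5, 0.5),
       A = matrix(c(d[1], 1 - d[1], 1 - d[2], d[2]), 2, 2, byrow = TRUE),
       p_correct = runif(1, 0.7, 0.95))
}

#' Scaled forward-backward posterior decoding
#'
#' Computes per-bin posterior state probabilities, summed two-slice
#' posteriors and the log-likelihood of a two-state HMM by the scaled
#' forward-backward recursions (per-step normalisation, numerically stable
#' on long chains).
#'
#' @param pi Length-2 initial state distribution.
#' @param A 2x2 row-stochastic transition matrix.
#' @param emission `N x 2` matrix of per-bin emission likelihoods
#'   (strictly positive; see [clip_emission()]), or a list
#'   `list(obs =, p_correct =)` for the Bernoulli case.
#' @param full_xi If `TRUE`, also return the per-step two-slice posteriors
#'   as an `(N-1) x 4` matrix with columns `00, 01, 10, 11`.
#'
#' @return A list with `gamma` (`N x 2` posterior, rows sum to 1),
#'   `posterior` (`gamma[, 2]`, the per-bin probability of the
#'   differential methylation state), `xi_sum` (2x2), `log_lik`, and
#'   optionally `xi`.
#' @examples
#' fb <- forward_backward(c(0.5, 0.5),
#'                        matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'                        list(obs = c(0L, 1L, 1L, 0L), p_correct = 0.9))
#' fb$posterior
#' @export
forward_backward <- function(pi, A, emission, full_xi = FALSE) {
  prm <- validate_hmm_params(pi, A)
  if (is.list(emission) && !is.data.frame(emission)) {
    emission <- bernoulli_emission(emission$obs, emission$p_correct)
  }
  emission <- as.matrix(emission)
  if (ncol(emission) != 2L || anyNA(emission) || any(emission <= 0)) {
    stop("emission must be an N x 2 matrix of positive likelihoods",
         call. = FALSE)
  }
  out <- .fb_kernel(prm$pi, prm$A, emission, isTRUE(full_xi))
  out$posterior <- out$gamma[, 2L]
  out
}

#' E-step-only posterior decoding at fixed parameters
#'
#' Identical to [forward_backward()]; named for its role in the FastFHC
#' strategy, where pooled parameters are estimated once and only the
#' E-step is run per site.
#'
#' @inheritParams forward_backward
#' @return See [forward_backward()].
#' @export
estep_only <- function(pi, A, emission) {
  forward_backward(pi, A, emission)
}

#' Baum-Welch EM for the two-state HMM
#'
#' Fits the HMM by expectation-maximisation. Two emission modes:
#' * binary observations (`obs` given): the symmetric Bernoulli
#'   correctness probability is re-estimated each M-step as the
#'   posterior-weighted agreement rate and projected onto
#'   `[0.5, 1 - 1e-6]`, pinning state 1 as the state that agrees with
#'   observed calls (FHB);
#' * fixed emissions (`emission` given): the `N x 2` likelihood matrix is
#'   held fixed and only `pi` and `A` are re-estimated (FHC / pooled
#'   estimation).
#'
#' M-step updates: `pi <- gamma[1, ]`, `A[i, ] <- xi_sum[i, ] /
#' sum(xi_sum[i, ])` (rows with no posterior mass keep their previous
#' values). Iteration stops when the relative log-likelihood change falls
#' below `tol` or after `max_iter` M-steps; `tol = Inf` performs no
#' updates and returns the initial parameters with their posterior.
#'
#' @param obs Binary observation vector (Bernoulli mode), or `NULL`.
#' @param emission Fixed `N x 2` emission likelihood matrix, or `NULL`.
#' @param init Starting parameters: list with `pi`, `A` and (Bernoulli
#'   mode) `p_correct`; `NULL` draws [random_hmm_init()].
#' @param max_iter Maximum number of EM iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param seed Optional integer seed for the random initialisation.
#'
#' @return A list with `pi`, `A`, `p_correct` (or `NULL`), `posterior`,
#'   `gamma`, `log_lik` (the trace over iterations, nondecreasing),
#'   `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' obs <- as.integer(runif(200) < 0.3)
#' fit <- baum_welch(obs = obs, seed = 1)
#' fit$pi; fit$A; fit$p_correct
#' @export
baum_welch <- function(obs = NULL, emission = NULL, init = NULL,
                       max_iter = 100, tol = 1e-6, seed = NULL) {
  bernoulli <- is.null(emission)
  if (bernoulli) {
    if (is.null(obs)) stop("supply 'obs' or 'emission'", call. = FALSE)
    obs <- as.integer(obs)
    if (length(obs) < 2L) {
      stop("chain too short for transition estimation (need >= 2 bins)",
           call. = FALSE)
    }
    n <- length(obs)
  } else {
    emission <- clip_emission(as.matrix(emission))
    n <- nrow(emission)
    if (n < 2L) {
      stop("chain too short for transition estimation (need >= 2 bins)",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- random_hmm_init()
  pi <- init$pi
  A <- init$A
  p_correct <- if (bernoulli) {
    min(max(init$p_correct, P_CORRECT_MIN), P_CORRECT_MAX)
  } else {
    NULL
  }
  validate_hmm_params(pi, A)

  emis <- function() {
    if (bernoulli) bernoulli_emission(obs, p_correct) else emission
  }
  fb <- forward_backward(pi, A, emis())
  ll_trace <- fb$log_lik
  iter <- 0L
  converged <- FALSE
  if (is.infinite(tol)) max_iter <- 0L
  while (iter < max_iter) {
    # M-step
    g1 <- fb$gamma[1L, ]
    pi <- g1 / sum(g1)
    rs <- rowSums(fb$xi_sum)
    for (i in 1:2) {
      if (rs[i] > 0) A[i, ] <- fb$xi_sum[i, ] / rs[i]
    }
    if (bernoulli) {
      agree <- sum(fb$gamma[cbind(seq_len(n), obs + 1L)]) / n
      p_correct <- min(max(agree, P_CORRECT_MIN), P_CORRECT_MAX)
    }
    fb <- forward_backward(pi, A, emis())
    ll_trace <- c(ll_trace, fb$log_lik)
    iter <- iter + 1L
    m <- length(ll_trace)
    if (abs(ll_trace[m] - ll_trace[m - 1L]) <=
        tol * max(1, abs(ll_trace[m - 1L]))) {
      converged <- TRUE
      break
    }
  }
  list(pi = pi, A = A, p_correct = p_correct,
       posterior = fb$posterior, gamma = fb$gamma,
       log_lik = ll_trace, iterations = iter, converged = converged)
}
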