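# The three FET-HMM smoothing strategies. Each turns per-bin rescaled
# Fisher's exact test results into a per-bin posterior probability of the
# differential methylation state (DMS) by a two-state HMM:
#   FHB     binary FDR calls observed through a Bernoulli channel,
#           full Baum-Welch per site;
#   FHC     p-value-derived fixed emissions, EM on pi and A only, per site;
#   FastFHC pooled single-pass pi/A estimate from binary calls genome-wide,
#           then a single E-step per site with p-value emissions.

#' Binarize FDR values into observed differential calls
#'
#' @param fdr Numeric vector of BH-adjusted p-values.
#' @param threshold FDR cut-off in (0, 1); a bin is called (1) when its
#'   FDR is strictly below the threshold.
#' @return Integer vector over {0, 1}.
#' @export
binarize_fdr <- function(fdr, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  as.integer(fdr < threshold)
}

#' Fixed emission matrix from per-bin p-values
#'
#' A bin's p-value approximates its likelihood under the null (state 0)
#' and `1 - p` its likelihood under the differential state (state 1); rows
#' are clipped away from 0 and 1 for numerical stability.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return An `N x 2` likelihood matrix with rows `(p, 1 - p)`.
#' @export
build_emission_from_pvalues <- function(p) {
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  cbind(clip_emission(p), clip_emission(1 - p))
}

#' Pooled HMM parameters from binary calls across all sites
#'
#' Single-pass estimate used by FastFHC: the initial distribution is the
#' genome-wide fraction of called bins, and the transition matrix counts
#' within-site transitions only (never across site boundaries), smoothed
#' by an additive pseudocount.
#'
#' @param obs_by_site List of binary vectors, one per site, in site order.
#' @param pseudocount Additive count on each transition cell (default 1)
#'   so that rows stay proper when a state is never visited.
#' @return A list with `pi` (length 2) and `A` (2x2 row-stochastic).
#' @export
estimate_pooled_params <- function(obs_by_site, pseudocount = 1) {
  obs_by_site <- lapply(obs_by_site, as.integer)
  n_bins <- sum(lengths(obs_by_site))
  if (n_bins == 0L) stop("no bins to pool", call. = FALSE)
  frac <- sum(unlist(obs_by_site)) / n_bins
  counts <- matrix(0, 2, 2)
  for (o in obs_by_site) {
    L <- length(o)
    if (L < 2L) next
    from <- o[-L] + 1L
    to <- o[-1L] + 1L
    for (k in seq_len(L - 1L)) {
      counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  A <- matrix(0, 2, 2)
  for (i in 1:2) {
    tot <- sum(counts[i, ]) + 2 * pseudocount
    A[i, ] <- if (tot > 0) (counts[i, ] + pseudocount) / tot else c(0.5, 0.5)
  }
  list(pi = c(1 - frac, frac), A = A)
}

split_by_site <- function(df) {
  split(df, factor(df$site_id, levels = unique(df$site_id)))
}

# EM-based smoothing shared by FHB and FHC. `res` is the output of
# test_bins(); returns res plus posterior/em_fallback columns and the
# fitted per-site parameters.
.em_strategy <- function(res, mode = c("fhb", "fhc"), fdr_threshold = 0.05,
                         min_bins_for_em = 5, max_iter = 100, tol = 1e-6) {
  mode <- match.arg(mode)
  sites <- split_by_site(res)
  posterior <- numeric(nrow(res))
  fallback <- logical(nrow(res))
  params <- vector("list", length(sites))
  names(params) <- names(sites)
  offset <- 0L
  for (k in seq_along(sites)) {
    s <- sites[[k]]
    L <- nrow(s)
    idx <- offset + seq_len(L)
    offset <- offset + L
    if (L < max(min_bins_for_em, 2L)) {
      posterior[idx] <- 1 - s$p_value
      fallback[idx] <- TRUE
      next
    }
    fit <- if (mode == "fhb") {
      baum_welch(obs = binarize_fdr(s$fdr, fdr_threshold),
                 max_iter = max_iter, tol = tol)
    } else {
      baum_welch(emission = build_emission_from_pvalues(s$p_value),
                 max_iter = max_iter, tol = tol)
    }
    posterior[idx] <- fit$posterior
    params[[k]] <- fit[c("pi", "A", "p_correct", "iterations", "converged")]
  }
  res$posterior <- posterior
  res$em_fallback <- fallback
  list(bins = res, params = params)
}

.fastfhc_strategy <- function(res, fdr_threshold = 0.05,
                              transition_pseudocount = 1) {
  sites <- split_by_site(res)
  obs <- lapply(sites, function(s) binarize_fdr(s$fdr, fdr_threshold))
  pooled <- estimate_pooled_params(obs, pseudocount = transition_pseudocount)
  posterior <- unlist(lapply(sites, function(s) {
    estep_only(pooled$pi, pooled$A,
               build_emission_from_pvalues(s$p_value))$posterior
  }), use.names = FALSE)
  res$posterior <- posterior
  res$em_fallback <- FALSE
  list(bins = res, params = pooled)
}

#' FHB: binary-observation Baum-Welch smoothing
#'
#' Runs [test_bins()], binarizes the genome-wide FDR at `fdr_threshold`,
#' and fits a two-state HMM with symmetric Bernoulli emissions per site by
#' Baum-Welch. The posterior probability of the differential state is
#' reported per bin. Sites with fewer than `min_bins_for_em` bins skip EM
#' and report `1 - p_value` (flagged in `em_fallback`).
#'
#' @param counts Bin-count table (see [test_bins()]).
#' @param sizes Library sizes, see [lib_sizes()].
#' @param fdr_threshold FDR cut-off for binarization (default 0.05).
#' @param min_bins_for_em Minimum chain length for EM (default 5).
#' @param max_iter,tol Baum-Welch controls, see [baum_welch()].
#' @param seed Optional seed governing the random EM initialisations.
#' @param pseudocount Additive pseudocount for the exact test (default 0).
#'
#' @return A list with `bins` (the test results plus `posterior` and
#'   `em_fallback` columns) and `params` (fitted per-site parameters).
#' @export
run_fhb <- function(counts, sizes, fdr_threshold = 0.05,
                    min_bins_for_em = 5, max_iter = 100, tol = 1e-6,
                    seed = NULL, pseudocount = 0) {
  res <- test_bins(counts, sizes, pseudocount = pseudocount)
  if (!is.null(seed)) set.seed(seed)
  .em_strategy(res, "fhb", fdr_threshold, min_bins_for_em, max_iter, tol)
}

#' FHC: p-value-emission smoothing with per-site EM
#'
#' Runs [test_bins()], builds the fixed per-bin emission matrix
#' `(p, 1 - p)` from the raw p-values, and fits the initial distribution
#' and transition matrix per site by EM (the emission matrix is not
#' re-estimated). Avoids the information loss of binarization.
#'
#' @inheritParams run_fhb
#' @return As [run_fhb()].
#' @export
run_fhc <- function(counts, sizes, min_bins_for_em = 5, max_iter = 100,
                    tol = 1e-6, seed = NULL, pseudocount = 0) {
  res <- test_bins(counts, sizes, pseudocount = pseudocount)
  if (!is.null(seed)) set.seed(seed)
  .em_strategy(res, "fhc", min_bins_for_em = min_bins_for_em,
               max_iter = max_iter, tol = tol)
}

#' FastFHC: pooled single-pass estimation with per-site E-step
#'
#' Runs [test_bins()], binarizes the FDR genome-wide, estimates the
#' initial distribution and transition matrix once from all sites in a
#' single pass ([estimate_pooled_params()]), then computes the posterior
#' per site by a single E-step with p-value emissions. No EM iteration, so
#' it scales to genome-sized inputs and stays robust on short sites.
#'
#' @inheritParams run_fhb
#' @param transition_pseudocount Additive smoothing on pooled transition
#'   counts (default 1).
#' @return A list with `bins` and `params` (the pooled `pi` and `A`).
#' @export
run_fastfhc <- function(counts, sizes, fdr_threshold = 0.05,
                        transition_pseudocount = 1, pseudocount = 0) {
  res <- test_bins(counts, sizes, pseudocount = pseudocount)
  .fastfhc_strategy(res, fdr_threshold, transition_pseudocount)
}

#' Merge posterior calls into differentially methylated regions
#'
#' Bins whose posterior meets the cut-off are marked as differential;
#' maximal runs of consecutive marked bins within a site are merged into
#' DMR intervals. Direction is the sign of the summed per-bin log2 odds
#' ratios over the interval (positive = hypermethylated in treated).
#'
#' @param bins Per-bin results with `site_id`, `bin_index`, `posterior`,
#'   `p_value`, `log2_or` columns (as returned in `$bins` by the strategy
#'   runners); optional `chrom`, `start`, `end`, `strand` are propagated.
#' @param cutoff Posterior cut-off in (0, 1), default 0.9.
#'
#' @return A data frame of DMRs: `site_id`, `dmr_id`, `bin_start`,
#'   `bin_end`, `n_bins`, `mean_posterior`, `min_posterior`, `best_p`,
#'   `direction`, and genomic coordinates when available.
#' @export
call_dmrs <- function(bins, cutoff = 0.9) {
  if (cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  }
  has_coords <- all(c("chrom", "start", "end") %in% names(bins))
  out <- list()
  for (s in split_by_site(bins)) {
    marked <- s$posterior >= cutoff
    if (!any(marked)) next
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in seq_along(runs)) {
      i0 <- starts[runs[j]]
      i1 <- ends[runs[j]]
      seg <- s[i0:i1, , drop = FALSE]
      lor <- sum(pmax(pmin(seg$log2_or, 20), -20))
      rec <- data.frame(
        site_id = s$site_id[1], dmr_id = j,
        bin_start = seg$bin_index[1],
        bin_end = seg$bin_index[nrow(seg)],
        n_bins = nrow(seg),
        mean_posterior = mean(seg$posterior),
        min_posterior = min(seg$posterior),
        best_p = min(seg$p_value),
        direction = if (lor > 0) "hyper" else if (lor < 0) "hypo" else "none",
        stringsAsFactors = FALSE)
      if (has_coords) {
        rec$chrom <- as.character(seg$chrom[1])
        rec$start <- seg$start[1]
        rec$end <- seg$end[nrow(seg)]
        rec$strand <- if ("strand" %in% names(seg)) {
          as.character(seg$strand[1])
        } else {
          "."
        }
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) {
    cols <- data.frame(site_id = character(), dmr_id = integer(),
                       bin_start = integer(), bin_end = integer(),
                       n_bins = integer(), mean_posterior = numeric(),
                       min_posterior = numeric(), best_p = numeric(),
                       direction = character(), stringsAsFactors = FALSE)
    return(cols)
  }
  do.call(rbind, out)
}

#' Run a FET-HMM strategy and call DMRs
#'
#' Convenience wrapper dispatching to [run_fhb()], [run_fhc()] or
#' [run_fastfhc()] and merging the posterior track into DMR calls.
#'
#' @inheritParams run_fhb
#' @param strategy One of `"fhc"` (default), `"fhb"`, `"fastfhc"`.
#' @param posterior_cutoff Posterior cut-off for DMR calling (default 0.9).
#' @param ... Further arguments passed to the strategy runner.
#' @return A list with `bins`, `params`, `dmrs`.
#' @export
detect_dmrs <- function(counts, sizes, strategy = c("fhc", "fhb", "fastfhc"),
                        posterior_cutoff = 0.9, seed = NULL, ...) {
  strategy <- match.arg(strategy)
  fit <- switch(strategy,
                fhb = run_fhb(counts, sizes, seed = seed, ...),
                fhc = run_fhc(counts, sizes, seed = seed, ...),
                fastfhc = run_fastfhc(counts, sizes, ...))
  fit$dmrs <- call_dmrs(fit$bins, cutoff = posterior_cutoff)
  fit
}
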