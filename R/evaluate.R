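# Bin-level ROC/AUC evaluation and the factor-sweep experiment harness.

#' Bin-level AUC of a score against ground-truth states
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic
#' normalised by the number of positive-negative pairs, with ties counted
#' one half.
#'
#' @param scores Numeric per-bin scores (posterior for the HMM
#'   strategies, `1 - p` for the raw test).
#' @param labels Ground-truth labels over {0, 1}; both classes must be
#'   present.
#' @return The AUC, a number in \[0, 1\].
#' @examples
#' compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(!labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Factor-sweep AUC experiment
#'
#' Sweeps one generative or analysis factor over a set of levels,
#' simulating `n_datasets` datasets per level and scoring each method by
#' bin-level AUC. Factors:
#' * `"threshold"`: the FDR cut-off used by FHB/FastFHC binarization;
#' * `"transition"`: the self-transition probability of the hidden-state
#'   chain generating the truth;
#' * `"depth"`: all four sequencing depths;
#' * `"unbalanced_depth"`: the treated IP depth only, others unchanged.
#'
#' @param factor One of `"threshold"`, `"transition"`, `"depth"`,
#'   `"unbalanced_depth"`.
#' @param levels Numeric vector of factor levels.
#' @param n_datasets Datasets per level (default 10).
#' @param cfg Base simulation configuration.
#' @param seed Master seed; per-dataset seeds are derived from it and are
#'   shared across levels so levels differ only through the factor.
#' @param methods Methods to score.
#' @param fdr_threshold Baseline FDR cut-off (overridden by the
#'   `"threshold"` factor).
#'
#' @return A tidy data frame: `factor`, `level`, `dataset`, `method`,
#'   `auc`.
#' @export
sweep_auc <- function(factor = c("threshold", "transition", "depth",
                                 "unbalanced_depth"),
                      levels, n_datasets = 10, cfg = sim_config(),
                      seed = 1,
                      methods = c("raw", "fhb", "fhc", "fastfhc"),
                      fdr_threshold = 0.05) {
  factor <- match.arg(factor)
  stopifnot(length(levels) >= 1L)
  set.seed(seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  rows <- list()
  for (lv in levels) {
    cfg_lv <- cfg
    thr <- fdr_threshold
    if (factor == "threshold") {
      thr <- lv
    } else if (factor == "transition") {
      cfg_lv$A_sim <- matrix(c(lv, 1 - lv, 1 - lv, lv), 2, byrow = TRUE)
    } else if (factor == "depth") {
      cfg_lv$lib_sizes <- lib_sizes(lv, lv, lv, lv)
    } else if (factor == "unbalanced_depth") {
      s <- cfg$lib_sizes
      cfg_lv$lib_sizes <- lib_sizes(s[["n0"]], s[["n1"]], s[["m0"]], lv)
    }
    for (k in seq_len(n_datasets)) {
      d <- simulate_dataset(cfg_lv, seed = dataset_seeds[k])
      scores <- score_methods(d, methods, fdr_threshold = thr)
      for (m in methods) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = factor, level = lv, dataset = k, method = m,
          auc = compute_auc(scores[[m]], d$truth$state),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
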