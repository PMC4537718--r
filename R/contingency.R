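#' Library sizes of the four MeRIP-Seq samples
#'
#' Sequencing depths of the four libraries entering a two-condition
#' comparison: input and IP under the untreated (control) and treated
#' conditions.
#'
#' @param n0 Depth of the untreated input library.
#' @param n1 Depth of the treated input library.
#' @param m0 Depth of the untreated IP library.
#' @param m1 Depth of the treated IP library.
#'
#' @return A named numeric vector of class `"lib_sizes"` with elements
#'   `n0`, `n1`, `m0`, `m1`.
#' @examples
#' lib_sizes(1e8, 1e8, 1e8, 1e8)
#' @export
lib_sizes <- function(n0, n1, m0, m1) {
  s <- c(n0 = as.numeric(n0), n1 = as.numeric(n1),
         m0 = as.numeric(m0), m1 = as.numeric(m1))
  if (length(s) != 4L || anyNA(s) || any(!is.finite(s)) || any(s <= 0)) {
    stop("library sizes must be four strictly positive finite numbers",
         call. = FALSE)
  }
  structure(s, class = "lib_sizes")
}

as_lib_sizes <- function(sizes) {
  if (inherits(sizes, "lib_sizes")) return(sizes)
  s <- unname(as.numeric(sizes))
  if (length(s) != 4L) {
    stop("expected four library sizes (n0, n1, m0, m1)", call. = FALSE)
  }
  lib_sizes(s[1], s[2], s[3], s[4])
}

#' Rescale one sample so the library sizes balance
#'
#' A conditional 2x2 test of equal methylation proportions is exact only
#' when `N1 * M0 == N0 * M1`. Balance is established by rescaling a single
#' sample: the treated IP library is given the effective depth
#' `M1' = N1 * M0 / N0` and its counts are scaled accordingly
#' (`y1' = round(y1 * M1' / M1)`), leaving the other three samples
#' untouched.
#'
#' @param counts A data frame (or list) with non-negative integer count
#'   vectors `x0`, `y0`, `x1`, `y1` (untreated input, untreated IP,
#'   treated input, treated IP).
#' @param sizes Library sizes, see [lib_sizes()].
#'
#' @return A list with elements `counts` (the rescaled counts, same shape),
#'   `sizes` (the effective, balanced library sizes) and `rho`
#'   (`(N0*M1)/(N1*M0)`, the imbalance factor that was removed).
#' @examples
#' rescale_counts(data.frame(x0 = 10, y0 = 10, x1 = 10, y1 = 40),
#'                lib_sizes(1e8, 1e8, 1e8, 2e8))
#' @export
rescale_counts <- function(counts, sizes) {
  sizes <- as_lib_sizes(sizes)
  check_counts(counts)
  m1_new <- sizes[["n1"]] * sizes[["m0"]] / sizes[["n0"]]
  rho <- sizes[["m1"]] / m1_new
  y1 <- pmax(0, round(counts$y1 * m1_new / sizes[["m1"]]))
  out <- counts
  out$y1 <- y1
  eff <- lib_sizes(sizes[["n0"]], sizes[["n1"]], sizes[["m0"]], m1_new)
  list(counts = out, sizes = eff, rho = rho)
}

check_counts <- function(counts) {
  for (nm in c("x0", "y0", "x1", "y1")) {
    v <- counts[[nm]]
    if (is.null(v)) stop("counts must contain column '", nm, "'", call. = FALSE)
    if (anyNA(v) || any(v < 0)) {
      stop("counts in '", nm, "' must be non-negative and non-missing",
           call. = FALSE)
    }
    if (any(abs(v - round(v)) > 1e-6)) {
      stop("counts in '", nm, "' must be integers", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Two-tailed rescaled hypergeometric test per bin (rhtest)
#'
#' After library balancing, and conditional on the per-condition totals,
#' the untreated input count of a bin follows a hypergeometric
#' distribution under the null hypothesis of equal methylation
#' proportions. The two-tailed p-value sums the probabilities of all
#' outcomes whose likelihood does not exceed that of the observed table
#' (minimum-likelihood rule, with a relative tolerance of 1e-7 on the mass
#' comparison, as in conventional exact-test implementations).
#'
#' Counts must already be balanced (see [rescale_counts()]); use
#' [test_bins()] for the full rescale-test-adjust pipeline.
#'
#' @param x0,y0,x1,y1 Non-negative integer count vectors: untreated input,
#'   untreated IP, treated input, treated IP. Recycled to a common length.
#'
#' @return Numeric vector of two-tailed p-values in (0, 1]. An all-zero
#'   table yields p = 1.
#' @examples
#' rhtest(5, 5, 5, 5)       # perfectly balanced: p = 1
#' rhtest(3, 1, 1, 3)
#' @export
rhtest <- function(x0, y0, x1, y1) {
  n <- max(length(x0), length(y0), length(x1), length(y1))
  x0 <- round(rep_len(as.numeric(x0), n))
  y0 <- round(rep_len(as.numeric(y0), n))
  x1 <- round(rep_len(as.numeric(x1), n))
  y1 <- round(rep_len(as.numeric(y1), n))
  if (any(c(x0, y0, x1, y1) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  N <- x0 + y0 + x1 + y1
  ndraw <- x0 + y0
  K <- x0 + x1
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (N[i] == 0) {
      p[i] <- 1
      next
    }
    lo <- max(0, K[i] - (N[i] - ndraw[i]))
    hi <- min(K[i], ndraw[i])
    supp <- lo:hi
    d <- dhyper(supp, K[i], N[i] - K[i], ndraw[i])
    p_obs <- d[x0[i] - lo + 1L]
    # extreme tables can underflow the observed mass to 0; keep p in (0, 1]
    p[i] <- min(1, max(sum(d[d <= p_obs * (1 + 1e-7)]), 1e-300))
  }
  p
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard BH step-up adjustment, applied genome-wide across all bins of
#' all sites in one pass so that the three smoothing strategies share one
#' FDR scale.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of BH-adjusted p-values (monotone, capped at 1);
#'   empty input gives an empty result.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Per-bin differential methylation tests for a bin-count table
#'
#' Applies library rescaling, the two-tailed rescaled hypergeometric test
#' and genome-wide BH adjustment to every bin of a bin-count table,
#' preserving site grouping and bin order.
#'
#' @param counts A bin-count table: data frame with columns `site_id`,
#'   `bin_index`, `x0`, `y0`, `x1`, `y1` (optional `chrom`, `start`, `end`,
#'   `strand` are carried through).
#' @param sizes Library sizes, see [lib_sizes()].
#' @param pseudocount Additive pseudocount applied to all four counts
#'   before testing (default 0; the model specifies none).
#'
#' @return The input data frame with columns `p_value`, `fdr`, `log2_or`
#'   (log2 odds ratio, positive = hypermethylated in the treated
#'   condition; `Inf`/`-Inf` for zero cells, 0 when uninformative) and
#'   `degenerate` (all four rescaled counts zero).
#' @examples
#' counts <- data.frame(site_id = "s1", bin_index = 0:1,
#'                      x0 = c(100, 100), y0 = c(100, 100),
#'                      x1 = c(100, 100), y1 = c(100, 420))
#' test_bins(counts, lib_sizes(1e8, 1e8, 1e8, 1e8))
#' @export
test_bins <- function(counts, sizes, pseudocount = 0) {
  if (is.null(counts$site_id)) {
    stop("counts must contain a 'site_id' column", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  r <- rescale_counts(counts, sizes)
  x0 <- r$counts$x0 + pseudocount
  y0 <- r$counts$y0 + pseudocount
  x1 <- r$counts$x1 + pseudocount
  y1 <- r$counts$y1 + pseudocount
  degenerate <- (r$counts$x0 + r$counts$y0 + r$counts$x1 + r$counts$y1) == 0
  p <- rhtest(x0, y0, x1, y1)
  p[degenerate] <- 1
  # log2 odds ratio of (IP/input) between conditions on the balanced counts
  lor <- log2(y1) + log2(x0) - log2(x1) - log2(y0)
  lor[is.nan(lor)] <- 0
  lor[degenerate] <- 0
  out <- counts
  out$p_value <- p
  out$fdr <- bh_fdr(p)
  out$log2_or <- lor
  out$degenerate <- degenerate
  out
}
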