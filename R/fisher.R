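#' Exact Fisher test for r x c contingency tables
#'
#' Two-sided exact test under the fixed-margins hypergeometric model: the
#' p-value is the total probability of all tables whose probability does
#' not exceed that of the observed table (the convention matching standard
#' exact-test output). The exact method enumerates all tables with the
#' observed margins (depth-first with column-remainder bounds, compiled);
#' the Monte-Carlo method samples tables with fixed margins via
#' [stats::r2dtable()] and reports the proportion at or below the observed
#' probability.
#'
#' All-zero rows and columns are dropped before testing.
#'
#' @param counts non-negative integer matrix of counts.
#' @param method `"exact"` or `"montecarlo"`.
#' @param mc_reps Monte-Carlo replicates (>= 1e5 recommended).
#' @param seed seed for the Monte-Carlo method.
#' @return list with `p.value`, `method`, and for Monte-Carlo the standard
#'   error of the estimate.
#' @export
fisher_exact_rxc <- function(counts, method = c("exact", "montecarlo"),
                             mc_reps = 1e5, seed = 1L) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty contingency table")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)

  if (method == "exact") {
    # crude enumeration bound: compositions of each row over the columns
    log_bound <- sum(lchoose(rs + ncol(counts) - 1, ncol(counts) - 1))
    if (log_bound > log(1e11))
      stop("exact enumeration infeasible for these margins; use method = \"montecarlo\"")
    p <- fisher_exact_rxc_cpp(counts)
    return(list(p.value = min(1, p), method = "exact"))
  }

  if (mc_reps < 1e3) stop("mc_reps too small")
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  lp_obs <- log_const - sum(lgamma(counts + 1))
  hits <- 0; done <- 0
  with_seed(seed, {
    while (done < mc_reps) {
      k <- min(1e5, mc_reps - done)
      lp <- table_log_prob_cpp(stats::r2dtable(k, rs, cs), log_const)
      hits <- hits + sum(lp <= lp_obs + 1e-7)
      done <- done + k
    }
  })
  p <- hits / mc_reps
  list(p.value = p, method = "montecarlo",
       se = sqrt(p * (1 - p) / mc_reps), mc_reps = mc_reps)
}

#' Breathing-pattern frequency table by recumbency
#'
#' Counts recordings per recumbency x BrP category. Recordings labelled
#' `"mixed"` are excluded from the table (they are reported separately by
#' the pipeline summary).
#'
#' @param labels character vector of per-recording labels
#'   (`"BrP1".."BrP4"` or `"mixed"`).
#' @param recumbency character vector of the same length.
#' @return integer matrix, rows = recumbencies (in first-appearance order),
#'   columns = `BrP1..BrP4`.
#' @export
brp_frequency_table <- function(labels, recumbency) {
  stopifnot(length(labels) == length(recumbency))
  keep <- labels != "mixed"
  labels <- factor(labels[keep], levels = paste0("BrP", 1:4))
  recumbency <- factor(recumbency[keep], levels = unique(recumbency))
  tab <- table(recumbency, labels)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Per-recumbency descriptive summary
#'
#' Group means with t-based 95% confidence intervals for every numeric
#' variable, by recumbency. Groups of size one get a mean with `NA`
#' interval bounds.
#'
#' @param df data.frame with a `recumbency` column and numeric variable
#'   columns (typically one row per recording of per-recording means).
#' @param conf confidence level.
#' @return data.frame with columns `recumbency`, `variable`, `mean`, `lo`,
#'   `hi`, `n`.
#' @export
summarize_recordings <- function(df, conf = 0.95) {
  stopifnot("recumbency" %in% names(df))
  vars <- names(df)[vapply(df, is.numeric, logical(1L))]
  out <- list()
  for (g in unique(df$recumbency)) {
    sub <- df[df$recumbency == g, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]; n <- sum(!is.na(x)); m <- mean(x, na.rm = TRUE)
      if (n >= 2L) {
        hw <- stats::qt(1 - (1 - conf) / 2, n - 1L) * stats::sd(x, na.rm = TRUE) / sqrt(n)
        lo <- m - hw; hi <- m + hw
      } else lo <- hi <- NA_real_
      out[[length(out) + 1L]] <- data.frame(recumbency = g, variable = v,
                                            mean = m, lo = lo, hi = hi, n = n)
    }
  }
  do.call(rbind, out)
}
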