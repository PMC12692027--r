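#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p-values sorted ascending, the adjusted value at
#' rank i is `min over j >= i of (p_(j) * m / j)`, capped at 1 and restored
#' to input order. Controls the false discovery rate across the m tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return the adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    data_error("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Simple two-condition differential expression on log2 counts
#'
#' A deliberately plain screen used to exercise the FDR-filtering contract on
#' synthetic data (it is not a count-model fit): per feature, the log2 fold
#' change is the difference of mean `log2(count + 1)` between condition 1 and
#' condition 0, the p-value comes from a Welch two-sample t test on the same
#' transformed values, and the FDR is the Benjamini-Hochberg adjustment
#' across all features of the table. A feature with zero variance in both
#' groups gets p = 1 when the group means agree and p = 0 otherwise.
#'
#' @param counts a counts data frame (`feature_id` + one column per sample).
#' @param condition 0/1 vector, one entry per sample column, at least two
#'   samples per condition.
#' @return a DE table: `feature_id`, `log2fc`, `p`, `fdr`, `sign`.
#' @export
naive_de <- function(counts, condition) {
  samples <- setdiff(names(counts), "feature_id")
  condition <- as.integer(condition)
  if (length(condition) != length(samples)) {
    config_error("condition must have one entry per sample column")
  }
  if (sum(condition == 0L) < 2L || sum(condition == 1L) < 2L) {
    config_error("naive_de needs at least 2 samples per condition")
  }
  l <- log2(as.matrix(counts[, samples, drop = FALSE]) + 1)
  i1 <- condition == 1L
  i0 <- !i1
  n1 <- sum(i1)
  n0 <- sum(i0)
  m1 <- rowMeans(l[, i1, drop = FALSE])
  m0 <- rowMeans(l[, i0, drop = FALSE])
  v1 <- apply(l[, i1, drop = FALSE], 1L, stats::var)
  v0 <- apply(l[, i0, drop = FALSE], 1L, stats::var)
  log2fc <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  tstat <- log2fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(log2fc[zero] == 0, 1, 0)
  out <- data.frame(feature_id = counts$feature_id, log2fc = log2fc,
                    p = p, fdr = bh_adjust(p), stringsAsFactors = FALSE)
  out$sign <- ifelse(out$log2fc > 0, "+", ifelse(out$log2fc < 0, "-", NA))
  rownames(out) <- NULL
  out
}

#' Read a counts table
#'
#' TSV with a `feature_id` column followed by one numeric column per sample.
#'
#' @param path path to the TSV.
#' @return the counts data frame.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) data_error(sprintf("counts table not found: %s", path))
  counts <- read_tsv(path)
  if (!"feature_id" %in% names(counts)) {
    data_error(sprintf("counts table lacks a feature_id column: %s", path))
  }
  samples <- setdiff(names(counts), "feature_id")
  if (length(samples) == 0L || !all(vapply(counts[samples], is.numeric, TRUE))) {
    data_error(sprintf("counts table needs numeric sample columns: %s", path))
  }
  if (any(as.matrix(counts[samples]) < 0)) {
    data_error(sprintf("negative counts in table: %s", path))
  }
  counts
}
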