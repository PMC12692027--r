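#' Sum per-feature counts across samples
#'
#' Collapses a counts table (column `feature_id` followed by one numeric
#' column per sample) to one total per feature.
#'
#' @param counts a counts data frame.
#' @return a named numeric vector of per-feature totals.
#' @export
total_feature_counts <- function(counts) {
  stopifnot("feature_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "feature_id"), drop = FALSE])
  setNames(rowSums(m), counts$feature_id)
}

#' Aggregate promoter and enhancer expression per TAD
#'
#' Sums feature counts within each TAD (using a unique feature-to-TAD
#' assignment, so totals are conserved) and applies the `log2(x +
#' pseudocount)` transform. Only TADs containing at least one assigned
#' promoter AND at least one assigned enhancer are returned; unassigned
#' features are ignored.
#'
#' @param prom_counts,enh_counts named numeric vectors of per-feature counts
#'   (see [total_feature_counts()]).
#' @param prom_tads,enh_tads named character vectors from
#'   [assign_to_tads()].
#' @param pseudocount added before the log2 transform, default 1.
#' @return a data frame with `tad_id`, feature counts `n_prom`/`n_enh`,
#'   `prom_sum`, `enh_sum`, `prom_log2`, `enh_log2`.
#' @export
aggregate_by_tad <- function(prom_counts, enh_counts, prom_tads, enh_tads,
                             pseudocount = 1) {
  if (any(prom_counts < 0) || any(enh_counts < 0)) {
    data_error("negative read counts are not allowed")
  }
  stopifnot(pseudocount > 0)
  sum_by <- function(counts, assignment) {
    tad <- assignment[names(counts)]
    keep <- !is.na(tad)
    s <- tapply(counts[keep], tad[keep], sum)
    n <- tapply(counts[keep], tad[keep], length)
    list(sum = s, n = n)
  }
  p <- sum_by(prom_counts, prom_tads)
  e <- sum_by(enh_counts, enh_tads)
  shared <- intersect(names(p$sum), names(e$sum))
  data.frame(
    tad_id = shared,
    n_prom = as.integer(p$n[shared]), n_enh = as.integer(e$n[shared]),
    prom_sum = as.numeric(p$sum[shared]), enh_sum = as.numeric(e$sum[shared]),
    prom_log2 = log2(as.numeric(p$sum[shared]) + pseudocount),
    enh_log2 = log2(as.numeric(e$sum[shared]) + pseudocount),
    stringsAsFactors = FALSE)
}

# the correlation/regression battery on an (x, y) point cloud
battery <- function(x, y, pairing, n_label = length(x)) {
  n <- length(x)
  out <- list(n_tads = n, pairing = pairing,
              pearson_r = NA_real_, pearson_p = NA_real_,
              spearman_rho = NA_real_, spearman_p = NA_real_,
              kendall_tau = NA_real_, kendall_p = NA_real_,
              slr_slope = NA_real_, slr_intercept = NA_real_,
              theilsen_slope = NA_real_, theilsen_intercept = NA_real_,
              degenerate = FALSE, diagnostic = NULL,
              data = data.frame(enh_log2 = x, prom_log2 = y))
  if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out$degenerate <- TRUE
    out$diagnostic <- if (n < 2L) "fewer than 2 points" else
      "zero variance in x or y"
    return(structure(out, class = "tad_association"))
  }
  out$pearson_r <- cor(x, y)
  out$spearman_rho <- cor(x, y, method = "spearman")
  out$kendall_tau <- cor(x, y, method = "kendall")
  if (n >= 3L) {
    # two-sided p-values: t transform on n-2 df for Pearson; Pearson on
    # average ranks (t approximation) for Spearman; tau-b with the
    # tie-corrected normal approximation for Kendall
    out$pearson_p <- cor.test(x, y)$p.value
    out$spearman_p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))$p.value
    out$kendall_p <- suppressWarnings(
      cor.test(x, y, method = "kendall", exact = FALSE))$p.value
  }
  sl <- coef(lm(y ~ x))
  out$slr_intercept <- unname(sl[1L])
  out$slr_slope <- unname(sl[2L])
  ts <- theil_sen(x, y)
  out$theilsen_intercept <- ts$coefficients[[1L]]
  out$theilsen_slope <- ts$coefficients[[2L]]
  structure(out, class = "tad_association")
}

#' Correlation and regression battery on TAD aggregates
#'
#' Relates TAD-aggregated enhancer expression (x axis) to TAD-aggregated
#' promoter expression (y axis), both on the log2 scale, with Pearson's r,
#' Spearman's rho, Kendall's tau-b, a least-squares line, and the robust
#' Theil-Sen line. P-values test the null of zero correlation (two-sided)
#' and require at least 3 TADs; with fewer they are reported missing. Zero
#' variance on either axis yields missing coefficients with a diagnostic.
#'
#' @param agg a TAD aggregate data frame ([aggregate_by_tad()]).
#' @return an object of class `tad_association`; see also
#'   [adjacent_tad_null()], [coef.tad_association()],
#'   [plot.tad_association()].
#' @export
tad_association <- function(agg) {
  battery(agg$enh_log2, agg$prom_log2, pairing = "same")
}

#' Adjacent-TAD shifted null
#'
#' Re-runs the association battery after pairing each TAD's enhancer
#' aggregate with the promoter aggregate of the NEXT TAD on the same
#' chromosome (coordinate order; the last usable TAD of each chromosome is
#' dropped, and there is no cross-chromosome or wrap-around pairing). If the
#' apparent same-TAD association were independent of TAD boundaries, this
#' shifted pairing would show it too; a flat shifted correlation supports the
#' boundaries being real.
#'
#' @param agg a TAD aggregate data frame ([aggregate_by_tad()]).
#' @param tads the TAD set the aggregates were computed against; supplies
#'   the per-chromosome coordinate order.
#' @return a `tad_association` with `pairing = "adjacent"`.
#' @export
adjacent_tad_null <- function(agg, tads) {
  ids <- names(tads)[names(tads) %in% agg$tad_id]
  chrom <- as.character(seqnames(tads))[match(ids, names(tads))]
  xs <- ys <- numeric(0)
  enh <- setNames(agg$enh_log2, agg$tad_id)
  prom <- setNames(agg$prom_log2, agg$tad_id)
  for (chr in unique(chrom)) {
    seq_ids <- ids[chrom == chr]
    if (length(seq_ids) >= 2L) {
      k <- seq_len(length(seq_ids) - 1L)
      xs <- c(xs, enh[seq_ids[k]])
      ys <- c(ys, prom[seq_ids[k + 1L]])
    }
  }
  if (length(xs) < 3L) {
    data_error("adjacent-TAD null needs at least 3 shifted pairs")
  }
  battery(unname(xs), unname(ys), pairing = "adjacent")
}

fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-300) return("<1e-300")
  format(p, digits = 3)
}

#' @export
print.tad_association <- function(x, ...) {
  cat(sprintf("TAD-level enhancer-promoter association (%s-TAD pairing)\n",
              x$pairing))
  cat(sprintf("  n = %d TAD%s\n", x$n_tads, if (x$n_tads == 1) "" else "s"))
  if (x$degenerate) {
    cat(sprintf("  degenerate input: %s\n", x$diagnostic))
    return(invisible(x))
  }
  cat(sprintf("  Pearson  r   = %8.4f   P(r!=0)   = %s\n",
              x$pearson_r, fmt_p(x$pearson_p)))
  cat(sprintf("  Spearman rho = %8.4f   P(rho!=0) = %s\n",
              x$spearman_rho, fmt_p(x$spearman_p)))
  cat(sprintf("  Kendall  tau = %8.4f   P(tau!=0) = %s\n",
              x$kendall_tau, fmt_p(x$kendall_p)))
  cat(sprintf("  SLR:       slope %8.4f, intercept %8.4f\n",
              x$slr_slope, x$slr_intercept))
  cat(sprintf("  Theil-Sen: slope %8.4f, intercept %8.4f\n",
              x$theilsen_slope, x$theilsen_intercept))
  invisible(x)
}

#' Coefficients of a TAD association battery
#'
#' @param object a `tad_association`.
#' @param ... unused.
#' @return a named numeric vector with the ten battery statistics.
#' @export
#' @method coef tad_association
coef.tad_association <- function(object, ...) {
  c(pearson_r = object$pearson_r, pearson_p = object$pearson_p,
    spearman_rho = object$spearman_rho, spearman_p = object$spearman_p,
    kendall_tau = object$kendall_tau, kendall_p = object$kendall_p,
    slr_slope = object$slr_slope, slr_intercept = object$slr_intercept,
    theilsen_slope = object$theilsen_slope,
    theilsen_intercept = object$theilsen_intercept)
}

#' @export
#' @method as.data.frame tad_association
as.data.frame.tad_association <- function(x, ...) {
  cbind(data.frame(pairing = x$pairing, n_tads = x$n_tads),
        as.data.frame(as.list(coef(x))))
}

#' Scatter plot of TAD aggregates with both regression lines
#'
#' Enhancer aggregate (log2) on the x axis, promoter aggregate (log2) on the
#' y axis; the least-squares line in red, the Theil-Sen line in blue.
#'
#' @param x a `tad_association`.
#' @param ... forwarded to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
#' @method plot tad_association
plot.tad_association <- function(x, ...) {
  graphics::plot(x$data$enh_log2, x$data$prom_log2, pch = 16,
                 col = "grey25",
                 xlab = "aggregated enhancer expression (log2)",
                 ylab = "aggregated promoter expression (log2)",
                 main = sprintf("%s-TAD pairing (n = %d)", x$pairing,
                                x$n_tads), ...)
  if (!x$degenerate) {
    graphics::abline(x$slr_intercept, x$slr_slope, col = "red", lwd = 2)
    graphics::abline(x$theilsen_intercept, x$theilsen_slope, col = "blue",
                     lwd = 2)
    graphics::legend("topleft", legend = c("SLR", "Theil-Sen"),
                     col = c("red", "blue"), lwd = 2, bty = "n")
  }
  invisible(x)
}
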