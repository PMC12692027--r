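#' Read a differential-expression table
#'
#' Expects a TSV with header columns `feature_id`, `log2fc`, `fdr` (extra
#' columns are kept). Validated with [validate_de_table()].
#'
#' @param path path to a TSV file.
#' @return a validated data frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) data_error(sprintf("DE table not found: %s", path))
  validate_de_table(read_tsv(path))
}

#' Validate a differential-expression table
#'
#' Checks the `feature_id`/`log2fc`/`fdr` columns, id uniqueness, the FDR
#' range, and rejects the contradictory case `log2fc == 0` with
#' `fdr < 0.05` (a significant feature must have a direction). Adds a
#' derived `sign` column: `"+"` for `log2fc > 0`, `"-"` for `log2fc < 0`,
#' `NA` at exactly zero.
#'
#' @param de a data frame.
#' @param fdr_threshold threshold used for the contradiction check.
#' @return the data frame with a `sign` column.
#' @export
validate_de_table <- function(de, fdr_threshold = 0.05) {
  need <- c("feature_id", "log2fc", "fdr")
  miss <- setdiff(need, names(de))
  if (length(miss)) {
    data_error(sprintf("DE table lacks column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(de$feature_id)) {
    data_error(sprintf("duplicate feature id in DE table: %s",
                       de$feature_id[anyDuplicated(de$feature_id)]))
  }
  if (any(is.na(de$fdr)) || any(de$fdr < 0 | de$fdr > 1)) {
    data_error("DE table fdr values must lie in [0, 1]")
  }
  if (any(de$log2fc == 0 & de$fdr < fdr_threshold)) {
    data_error("DE table has log2fc == 0 with significant fdr (contradictory)")
  }
  de$sign <- ifelse(de$log2fc > 0, "+", ifelse(de$log2fc < 0, "-", NA))
  de
}

# doubled midpoint of an interval in BED coordinates: (start + end) stays
# integral, so the 500 kb boundary is compared exactly, never through a .5
# floating-point midpoint
midpoint2 <- function(gr) (start(gr) - 1) + end(gr)

empty_pairs <- function(tad = FALSE) {
  df <- data.frame(promoter_id = character(0), enhancer_id = character(0),
                   stringsAsFactors = FALSE)
  if (tad) df$tad_id <- character(0)
  df$distance <- numeric(0)
  df
}

#' Enumerate promoter-enhancer pairs by linear proximity
#'
#' All same-chromosome pairs whose midpoint-to-midpoint distance does not
#' exceed `max_distance` (inclusive boundary). Midpoints are compared in
#' doubled-integer arithmetic, so the boundary is exact.
#'
#' @param promoters,enhancers named `GRanges`.
#' @param max_distance maximum separation in bases (default 500 kb).
#' @return a data frame with `promoter_id`, `enhancer_id`, `distance`.
#' @export
pairs_by_proximity <- function(promoters, enhancers, max_distance = 500000) {
  stopifnot(max_distance > 0)
  mp <- midpoint2(promoters)
  me <- midpoint2(enhancers)
  cp <- as.character(seqnames(promoters))
  ce <- as.character(seqnames(enhancers))
  res <- list()
  for (chr in intersect(unique(cp), unique(ce))) {
    ip <- which(cp == chr)
    ie <- which(ce == chr)
    d2 <- abs(outer(mp[ip], me[ie], "-"))
    ok <- which(d2 <= 2 * max_distance, arr.ind = TRUE)
    if (nrow(ok)) {
      res[[chr]] <- data.frame(
        promoter_id = names(promoters)[ip[ok[, 1L]]],
        enhancer_id = names(enhancers)[ie[ok[, 2L]]],
        distance = d2[ok] / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_pairs())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$promoter_id, out$enhancer_id), , drop = FALSE]
}

#' Enumerate promoter-enhancer pairs co-localised in a TAD
#'
#' Pairs whose members are both assigned (largest-overlap rule,
#' [assign_to_tads()]) to the same TAD. Features outside every TAD generate
#' no pairs.
#'
#' @param promoters,enhancers named `GRanges`.
#' @param tads a TAD set ([as_tad_set()]).
#' @return a data frame with `promoter_id`, `enhancer_id`, `tad_id`,
#'   `distance` (midpoint separation in bases).
#' @export
pairs_by_tad <- function(promoters, enhancers, tads) {
  ap <- assign_to_tads(promoters, tads)
  ae <- assign_to_tads(enhancers, tads)
  mp <- setNames(midpoint2(promoters), names(promoters))
  me <- setNames(midpoint2(enhancers), names(enhancers))
  pt <- split(names(ap)[!is.na(ap)], ap[!is.na(ap)])
  et <- split(names(ae)[!is.na(ae)], ae[!is.na(ae)])
  shared <- intersect(names(pt), names(et))
  if (!length(shared)) return(empty_pairs(tad = TRUE))
  res <- lapply(shared, function(t) {
    g <- expand.grid(promoter_id = pt[[t]], enhancer_id = et[[t]],
                     stringsAsFactors = FALSE)
    g$tad_id <- t
    g$distance <- abs(mp[g$promoter_id] - me[g$enhancer_id]) / 2
    g
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$tad_id, out$promoter_id, out$enhancer_id), , drop = FALSE]
}

#' Retain differentially expressed pairs and classify their sign pattern
#'
#' Keeps pairs where both members pass the FDR cut (strictly below
#' `fdr_threshold`), and labels each kept pair with its sign pattern,
#' promoter sign first: `"++"`, `"+-"`, `"-+"`, `"--"`. Pairs with a member
#' missing from its DE table are dropped.
#'
#' @param pairs a pair data frame ([pairs_by_tad()] or
#'   [pairs_by_proximity()]).
#' @param de_prom,de_enh DE tables ([validate_de_table()] applied
#'   internally).
#' @param fdr_threshold significance cut (strict `<`), default 0.05.
#' @return the retained pairs with `pattern`, `prom_log2fc`, `enh_log2fc`.
#' @export
filter_differential <- function(pairs, de_prom, de_enh, fdr_threshold = 0.05) {
  de_prom <- validate_de_table(de_prom, fdr_threshold)
  de_enh <- validate_de_table(de_enh, fdr_threshold)
  ip <- match(pairs$promoter_id, de_prom$feature_id)
  ie <- match(pairs$enhancer_id, de_enh$feature_id)
  keep <- !is.na(ip) & !is.na(ie) &
    de_prom$fdr[ip] < fdr_threshold & de_enh$fdr[ie] < fdr_threshold
  out <- pairs[keep, , drop = FALSE]
  out$prom_log2fc <- de_prom$log2fc[ip[keep]]
  out$enh_log2fc <- de_enh$log2fc[ie[keep]]
  out$pattern <- paste0(de_prom$sign[ip[keep]], de_enh$sign[ie[keep]])
  rownames(out) <- NULL
  out
}

#' Pairs stable across all tissues
#'
#' Intersects per-tissue filtered pair lists on the key
#' (`promoter_id`, `enhancer_id`), regardless of the per-tissue pattern, and
#' reports each tissue's pattern for the surviving pairs.
#'
#' @param per_tissue_pairs a named list (tissue -> filtered pair data frame).
#' @return a data frame with the pair key columns plus one
#'   `pattern_<tissue>` column per tissue.
#' @export
stable_pairs <- function(per_tissue_pairs) {
  if (length(per_tissue_pairs) < 2L) {
    config_error("stable_pairs needs at least two tissues")
  }
  if (is.null(names(per_tissue_pairs)) || any(!nzchar(names(per_tissue_pairs)))) {
    config_error("per_tissue_pairs must be a named list of tissues")
  }
  keys <- lapply(per_tissue_pairs, function(df) {
    paste(df$promoter_id, df$enhancer_id, sep = "\r")
  })
  common <- Reduce(intersect, keys)
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(
    promoter_id = vapply(parts, `[[`, "", 1L),
    enhancer_id = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  for (t in names(per_tissue_pairs)) {
    m <- match(common, keys[[t]])
    out[[paste0("pattern_", t)]] <- per_tissue_pairs[[t]]$pattern[m]
  }
  out[order(out$promoter_id, out$enhancer_id), , drop = FALSE]
}
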