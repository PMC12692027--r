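#' Validate a GRanges as a TAD set and assign ordinal ids
#'
#' A TAD set is a sorted, per-chromosome pairwise disjoint interval set.
#' Ids are regenerated as `"<prefix>_<chrom>_<k>"` with `k` the coordinate
#' rank of the TAD on its chromosome, so id order mirrors genome order.
#'
#' @param gr a `GRanges` of candidate TAD intervals.
#' @param prefix id prefix, default `"TAD"`.
#' @return a sorted, disjoint, named `GRanges`.
#' @export
as_tad_set <- function(gr, prefix = "TAD") {
  stopifnot(is(gr, "GRanges"))
  gr <- sort(sortSeqlevels(gr), ignore.strand = TRUE)
  if (!isDisjoint(gr, ignore.strand = TRUE)) {
    data_error("TAD set is not disjoint: overlapping TADs on one chromosome")
  }
  if (length(gr) > 0L) {
    k <- stats::ave(seq_along(gr), as.character(seqnames(gr)), FUN = seq_along)
    names(gr) <- sprintf("%s_%s_%d", prefix, as.character(seqnames(gr)), k)
  }
  gr
}

#' Build a consensus TAD set from two parent TAD sets
#'
#' With `mode = "intersect"` (default) the consensus holds one interval per
#' maximal pairwise-overlap region between an interval of `a` and an interval
#' of `b`; since each parent is disjoint, the result is disjoint. With
#' `mode = "merge_chained"`, overlap regions deriving from the same parent-a
#' TAD are merged into a single consensus interval spanning from the first to
#' the last such region (one blood-cell TAD overlapping several fibroblast
#' TADs yields one consensus TAD). Ids are regenerated; contributing parent
#' ids are retained in `mcols` for traceability.
#'
#' @param a,b TAD sets (validated with [as_tad_set()] internally).
#' @param mode `"intersect"` or `"merge_chained"`.
#' @return a TAD set `GRanges` with `parent_a`/`parent_b` metadata columns.
#' @export
build_consensus <- function(a, b, mode = c("intersect", "merge_chained")) {
  mode <- match.arg(mode)
  a <- as_tad_set(a, prefix = "A")
  b <- as_tad_set(b, prefix = "B")
  h <- harmonize_seqlevels(a, b)
  a <- h$a
  b <- h$b
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(as_tad_set(GRanges(), prefix = "TAD"))
  }
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  regions <- GRanges(seqnames(a)[qh],
                     IRanges(pmax(start(a)[qh], start(b)[sh]),
                             pmin(end(a)[qh], end(b)[sh])))
  if (mode == "intersect") {
    cons <- regions
    pa <- names(a)[qh]
    pb <- names(b)[sh]
  } else {
    grp <- split(seq_along(regions), qh)
    cons <- GRanges(
      vapply(grp, function(i) as.character(seqnames(regions))[i[1L]], ""),
      IRanges(vapply(grp, function(i) min(start(regions)[i]), 0L),
              vapply(grp, function(i) max(end(regions)[i]), 0L)))
    pa <- names(a)[as.integer(names(grp))]
    pb <- vapply(grp, function(i) paste(unique(names(b)[sh[i]]),
                                        collapse = ","), "")
  }
  ord <- order(as.integer(factor(as.character(seqnames(cons)),
                                 levels = seqlevels(sortSeqlevels(cons)))),
               start(cons), end(cons))
  cons <- cons[ord]
  mcols(cons)$parent_a <- pa[ord]
  mcols(cons)$parent_b <- pb[ord]
  as_tad_set(cons, prefix = "TAD")
}

#' Count tissue-specific TADs between two sets
#'
#' A TAD of `a` is a-specific when it shares zero bases with every TAD of `b`
#' (one overlapping base disqualifies), and symmetrically.
#'
#' @param a,b TAD sets.
#' @return a list with `n_a_only`, `n_b_only`, `a_only`, `b_only` (id vectors).
#' @export
tissue_specific <- function(a, b) {
  a <- as_tad_set(a, prefix = "A")
  b <- as_tad_set(b, prefix = "B")
  h <- harmonize_seqlevels(a, b)
  ca <- countOverlaps(h$a, h$b, ignore.strand = TRUE)
  cb <- countOverlaps(h$b, h$a, ignore.strand = TRUE)
  list(n_a_only = sum(ca == 0L), n_b_only = sum(cb == 0L),
       a_only = names(a)[ca == 0L], b_only = names(b)[cb == 0L])
}

#' Summarise a consensus construction
#'
#' Assembles parent counts, consensus count, tissue-specific counts and the
#' interval Jaccard statistic into one record (the layout of the usual
#' TAD-set comparison table).
#'
#' @param a,b parent TAD sets.
#' @param mode consensus mode, see [build_consensus()].
#' @return an object of class `consensus_report`.
#' @export
consensus_report <- function(a, b, mode = c("intersect", "merge_chained")) {
  mode <- match.arg(mode)
  cons <- build_consensus(a, b, mode = mode)
  ts <- tissue_specific(a, b)
  structure(list(
    n_parent_a = length(a),
    n_parent_b = length(b),
    n_consensus = length(cons),
    n_a_only = ts$n_a_only,
    n_b_only = ts$n_b_only,
    jaccard = interval_jaccard(a, b),
    mode = mode,
    consensus = cons
  ), class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Consensus TAD report (mode:", x$mode, ")\n")
  cat(sprintf("  %-22s %6d\n", "parent A intervals", x$n_parent_a))
  cat(sprintf("  %-22s %6d\n", "parent B intervals", x$n_parent_b))
  cat(sprintf("  %-22s %6d\n", "consensus intervals", x$n_consensus))
  cat(sprintf("  %-22s %6d\n", "A-only TADs", x$n_a_only))
  cat(sprintf("  %-22s %6d\n", "B-only TADs", x$n_b_only))
  cat(sprintf("  %-22s %6.3f\n", "Jaccard", x$jaccard))
  invisible(x)
}

#' @export
#' @method as.data.frame consensus_report
as.data.frame.consensus_report <- function(x, ...) {
  data.frame(n_parent_a = x$n_parent_a, n_parent_b = x$n_parent_b,
             n_consensus = x$n_consensus, n_a_only = x$n_a_only,
             n_b_only = x$n_b_only, jaccard = x$jaccard, mode = x$mode)
}
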