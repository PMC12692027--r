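#' Read a BED3/BED6 file into a GRanges
#'
#' Parses a BED file (0-based half-open coordinates) into a 1-based closed
#' [GenomicRanges::GRanges]. Track, browser and comment (`#`) lines are
#' skipped. The optional 4th column supplies feature ids; missing or `"."`
#' names are auto-assigned as `"<chrom>:<start>-<end>"` (BED coordinates).
#' The optional 6th column supplies strand (`+`, `-`; anything else becomes
#' `*`). The result is normalised: sorted by chromosome then (start, end),
#' with unique ids.
#'
#' @param path path to an existing BED file.
#' @return a named, sorted `GRanges`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tfeat1", p)
#' read_bed(p)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) data_error(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(normalize_intervals(GRanges()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    data_error(sprintf("BED parse error at line %d: fewer than 3 fields",
                       idx[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad)) {
    data_error(sprintf("BED parse error at line %d: non-integer coordinates",
                       idx[which(bad)[1L]]))
  }
  if (any(s < 0)) {
    data_error(sprintf("BED parse error at line %d: negative start",
                       idx[which(s < 0)[1L]]))
  }
  if (any(s >= e)) {
    data_error(sprintf("BED parse error at line %d: start >= end",
                       idx[which(s >= e)[1L]]))
  }
  ids <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  ids[ids == "." | !nzchar(ids)] <- NA_character_
  str <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  str[!str %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = str)
  auto <- auto_ids(gr)
  names(gr) <- ifelse(is.na(ids), auto, ids)
  normalize_intervals(gr)
}

#' Write a GRanges to a BED6 file
#'
#' Emits `chrom, start, end, id, 0, strand` with 0-based half-open
#' coordinates; unstranded intervals get `"."` in the strand column.
#' `read_bed(write_bed(x))` round-trips coordinates and ids exactly.
#'
#' @param gr a named `GRanges` (normalised or not; written as-is, in order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0L) {
    ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE)
    if (!isTRUE(ok)) data_error(sprintf("cannot write BED file: %s", path))
    return(invisible(path))
  }
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   name = if (is.null(names(gr))) auto_ids(gr) else names(gr),
                   score = 0L,
                   strand = str)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) data_error(sprintf("cannot write BED file: %s", path))
  invisible(path)
}

# put two GRanges on a shared seqlevel universe so overlap machinery never
# complains about disjoint chromosome sets (a legitimate input here)
harmonize_seqlevels <- function(a, b) {
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  list(a = a, b = b)
}

auto_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Normalise an interval set
#'
#' Sorts intervals by chromosome (natural seqlevel order) then by
#' (start, end), assigns auto ids where names are missing, and enforces id
#' uniqueness.
#'
#' @param gr a `GRanges`.
#' @return the sorted, named `GRanges`.
#' @export
normalize_intervals <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(names(gr))) names(gr) <- auto_ids(gr)
  if (anyDuplicated(names(gr))) {
    data_error(sprintf("duplicate interval id: %s",
                       names(gr)[anyDuplicated(names(gr))]))
  }
  gr <- sortSeqlevels(gr)
  sort(gr, ignore.strand = TRUE)
}

#' Merge overlapping and bookended intervals
#'
#' Collapses an interval set to the minimal set of maximal intervals covering
#' the same bases, per chromosome. Bookended intervals (end of one equals
#' start of the next in BED coordinates) are merged, matching default
#' `bedtools merge` behaviour. Idempotent; strand is ignored.
#'
#' @param gr a `GRanges`.
#' @return a sorted, disjoint `GRanges` with auto-assigned ids.
#' @export
merge_overlapping <- function(gr) {
  m <- reduce(sortSeqlevels(gr), ignore.strand = TRUE)
  m <- sort(m)
  names(m) <- auto_ids(m)
  m
}

#' Pairwise overlap in bases between parallel intervals
#'
#' For two `GRanges` of equal length (or either of length 1, recycled),
#' returns the number of shared bases for each aligned pair; 0 when the
#' chromosomes differ or the intervals do not intersect.
#'
#' @param a,b `GRanges` objects of equal length (or length 1).
#' @return an integer vector of overlap widths in bases.
#' @export
overlap_bases <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  if (n == 0L) return(integer(0))
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  ov
}

#' Jaccard statistic between two interval sets
#'
#' Both sets are merged internally; the statistic is the number of bases in
#' the intersection of the merged covers divided by the number of bases in
#' their union. An empty union yields 0.
#'
#' @param a,b `GRanges` objects.
#' @return a single numeric in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  am <- reduce(sortSeqlevels(a), ignore.strand = TRUE)
  bm <- reduce(sortSeqlevels(b), ignore.strand = TRUE)
  lv <- union(seqlevels(am), seqlevels(bm))
  seqlevels(am) <- lv
  seqlevels(bm) <- lv
  uni <- GenomicRanges::union(am, bm, ignore.strand = TRUE)
  u <- sum(as.numeric(width(uni)))
  if (u == 0) return(0)
  int <- GenomicRanges::intersect(am, bm, ignore.strand = TRUE)
  sum(as.numeric(width(int))) / u
}

#' Assign features to TADs by largest overlap
#'
#' Each feature overlapping at least one base of a TAD is assigned to the TAD
#' with which it shares the most bases; ties go to the TAD with the lower
#' start coordinate. Features overlapping no TAD are unassigned (`NA`). Every
#' feature maps to at most one TAD, so per-TAD aggregation conserves totals
#' (a feature straddling a boundary is counted once, not once per TAD).
#'
#' @param features a named `GRanges` of features.
#' @param tads a named `GRanges` of TADs (see [as_tad_set()]).
#' @return a named character vector: feature id -> TAD id or `NA`.
#' @export
assign_to_tads <- function(features, tads) {
  out <- setNames(rep(NA_character_, length(features)), names(features))
  if (length(features) == 0L || length(tads) == 0L) return(out)
  h <- harmonize_seqlevels(features, tads)
  hits <- findOverlaps(h$a, h$b, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  ov <- pmin(end(features)[qh], end(tads)[sh]) -
    pmax(start(features)[qh], start(tads)[sh]) + 1L
  ord <- order(qh, -ov, start(tads)[sh])
  first <- ord[!duplicated(qh[ord])]
  out[qh[first]] <- names(tads)[sh[first]]
  out
}
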