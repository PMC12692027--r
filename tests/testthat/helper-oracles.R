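# Brute-force oracles, independent of the package implementation. All per-base
# reasoning works on BED (0-based half-open) coordinates over a small toy
# genome so membership can be enumerated literally.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# quick GRanges constructor from BED coordinates
gr_bed <- function(chrom, start, end, id = NULL, strand = "*") {
  g <- GRanges(chrom, IRanges(start + 1, end), strand = strand)
  names(g) <- if (is.null(id)) {
    sprintf("%s:%d-%d", chrom, start, end)
  } else {
    id
  }
  g
}

# per-base cover of an interval set: list chrom -> logical vector over
# positions 0..(genome_size-1)
oracle_cover <- function(gr, genome_size, chroms) {
  cov <- lapply(setNames(chroms, chroms),
                function(ch) logical(genome_size))
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    pos <- (start(gr)[i] - 1):(end(gr)[i] - 1)  # BED positions
    cov[[ch]][pos + 1] <- TRUE
  }
  cov
}

# merged intervals recovered from a per-base cover (runs of TRUE)
oracle_merge <- function(gr, genome_size, chroms) {
  cov <- oracle_cover(gr, genome_size, chroms)
  out <- list()
  for (ch in chroms) {
    r <- rle(cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths   # BED starts
    k <- which(r$values)
    if (length(k)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[k], end = ends[k])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, out)
}

oracle_jaccard <- function(a, b, genome_size, chroms) {
  ca <- oracle_cover(a, genome_size, chroms)
  cb <- oracle_cover(b, genome_size, chroms)
  inter <- sum(vapply(chroms, function(ch) sum(ca[[ch]] & cb[[ch]]), 0))
  uni <- sum(vapply(chroms, function(ch) sum(ca[[ch]] | cb[[ch]]), 0))
  if (uni == 0) 0 else inter / uni
}

# per-base pairwise overlap between two single intervals
oracle_overlap_bases <- function(a, b) {
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(0L)
  pa <- (start(a) - 1):(end(a) - 1)
  pb <- (start(b) - 1):(end(b) - 1)
  length(intersect(pa, pb))
}

# exhaustive largest-overlap assignment (ties -> lower start)
oracle_assign <- function(features, tads) {
  out <- setNames(rep(NA_character_, length(features)), names(features))
  for (i in seq_along(features)) {
    best <- NA_character_
    best_ov <- 0L
    best_start <- Inf
    for (j in seq_along(tads)) {
      ov <- oracle_overlap_bases(features[i], tads[j])
      if (ov > best_ov || (ov > 0L && ov == best_ov &&
                           start(tads)[j] < best_start)) {
        best <- names(tads)[j]
        best_ov <- ov
        best_start <- start(tads)[j]
      }
    }
    out[i] <- best
  }
  out
}

# all-pairs-median Theil-Sen by explicit double loop
oracle_theil_sen <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y - slope * x))
}

# BH step-up by the defining formula: q_i = min over j with rank >= rank_i
# of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q[order(o)]
}

# correlation battery by first principles for a small point set
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  nc <- 0L
  nd <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_slr <- function(x, y) {
  # normal equations
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# random interval set over a toy genome (possibly overlapping intervals)
random_interval_set <- function(n, genome_size = 10000, chroms = c("chrA", "chrB")) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- sample.int(genome_size - 1, n, replace = TRUE) - 1L
  len <- sample.int(500, n, replace = TRUE)
  e <- pmin(s + len, genome_size)
  g <- GRanges(chrom, IRanges(s + 1, e))
  names(g) <- sprintf("iv%d", seq_len(n))
  g
}

# random DISJOINT interval set: alternate segments between random breakpoints
random_disjoint_set <- function(genome_size = 10000, chroms = c("chrA", "chrB"),
                                max_cuts = 12) {
  parts <- lapply(chroms, function(ch) {
    cuts <- sort(unique(sample.int(genome_size - 1, sample(2:max_cuts, 1))))
    bounds <- c(0L, cuts, genome_size)
    keep <- which(seq_len(length(bounds) - 1) %% 2 == 1)
    data.frame(chrom = ch, start = bounds[keep], end = bounds[keep + 1])
  })
  df <- do.call(rbind, parts)
  out <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  names(out) <- sprintf("tad%d", seq_along(out))
  out
}
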