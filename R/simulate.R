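#' Configuration for the synthetic TAD-genome generator
#'
#' Defines the ground-truth model behind [simulate_tad_genome()]: TADs tile
#' each chromosome end to end; promoters (100 bp) and enhancers (400 bp) are
#' placed uniformly at random inside their TAD without overlapping; the
#' count of feature f in sample s is
#' `round(2 ^ (b_f + a_t + g_f * c_s + eps_fs))` with per-TAD activity
#' `a_t ~ N(0, tad_activity_sd^2)` shared by all features of TAD t,
#' per-feature baseline `b_f ~ N(feature_baseline_mean,
#' feature_baseline_sd^2)`, sample noise `eps ~ N(0, noise_sd^2)`, and a
#' condition effect `g_f` of `+-effect_size` applied TAD-wise: a fraction
#' `de_fraction` of TADs draws one sign pattern (promoter sign, enhancer
#' sign) from `pattern_mixture`, and every promoter/enhancer of that TAD
#' inherits the corresponding signed effect. All log quantities are in
#' log2 units.
#'
#' @param n_chromosomes number of chromosomes.
#' @param tads_per_chromosome TADs tiling each chromosome.
#' @param tad_length TAD length in bases.
#' @param promoters_per_tad,enhancers_per_tad scalar or length-2 range.
#' @param tad_activity_sd sd of the shared per-TAD activity (log2 units).
#' @param feature_baseline_mean,feature_baseline_sd per-feature baseline
#'   distribution (log2 units).
#' @param noise_sd per-feature, per-sample noise sd (log2 units).
#' @param n_samples_per_condition samples in each of the two conditions.
#' @param de_fraction fraction of TADs carrying a condition effect.
#' @param pattern_mixture probabilities of the `++`, `+-`, `-+`, `--`
#'   patterns, summing to 1.
#' @param effect_size condition effect magnitude (log2 units, >= 0).
#' @param seed RNG seed making the simulation reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 3,
                       tads_per_chromosome = 10,
                       tad_length = 1e6,
                       promoters_per_tad = 5,
                       enhancers_per_tad = 5,
                       tad_activity_sd = 1,
                       feature_baseline_mean = 4,
                       feature_baseline_sd = 1,
                       noise_sd = 0.5,
                       n_samples_per_condition = 6,
                       de_fraction = 0.5,
                       pattern_mixture = c(pp = 0.7, pm = 0.2,
                                           mp = 0.05, mm = 0.05),
                       effect_size = 2,
                       seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              tads_per_chromosome = as.integer(tads_per_chromosome),
              tad_length = as.numeric(tad_length),
              promoters_per_tad = promoters_per_tad,
              enhancers_per_tad = enhancers_per_tad,
              tad_activity_sd = tad_activity_sd,
              feature_baseline_mean = feature_baseline_mean,
              feature_baseline_sd = feature_baseline_sd,
              noise_sd = noise_sd,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              de_fraction = de_fraction,
              pattern_mixture = pattern_mixture,
              effect_size = effect_size,
              seed = as.integer(seed))
  if (cfg$n_chromosomes < 1L || cfg$tads_per_chromosome < 1L)
    config_error("need at least one chromosome and one TAD per chromosome")
  if (cfg$tad_length <= 0) config_error("tad_length must be positive")
  if (abs(sum(cfg$pattern_mixture) - 1) > 1e-12)
    config_error("pattern_mixture must sum to 1")
  if (length(cfg$pattern_mixture) != 4L || any(cfg$pattern_mixture < 0))
    config_error("pattern_mixture must be 4 non-negative probabilities")
  if (any(c(cfg$tad_activity_sd, cfg$feature_baseline_sd, cfg$noise_sd) < 0))
    config_error("standard deviations must be non-negative")
  if (cfg$effect_size < 0) config_error("effect_size must be non-negative")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    config_error("de_fraction must lie in [0, 1]")
  if (cfg$n_samples_per_condition < 1L)
    config_error("need at least one sample per condition")
  structure(cfg, class = "sim_config")
}

PROMOTER_WIDTH <- 100L
ENHANCER_WIDTH <- 400L
PATTERNS <- c(pp = "++", pm = "+-", mp = "-+", mm = "--")

draw_per_tad <- function(spec, n_tads) {
  if (length(spec) == 1L) rep(as.integer(spec), n_tads)
  else sample(seq.int(spec[1L], spec[2L]), n_tads, replace = TRUE)
}

# uniform non-overlapping placement of widths inside [lo, hi] (BED coords),
# bounded rejection
place_features <- function(lo, hi, widths, max_attempts = 1000L) {
  starts <- integer(length(widths))
  ends <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      span <- hi - lo - w + 1
      if (span < 1) break
      s <- lo + sample.int(span, 1L) - 1L
      if (i == 1L || all(s + w <= starts[seq_len(i - 1L)] |
                         s >= ends[seq_len(i - 1L)])) {
        starts[i] <- s
        ends[i] <- s + w
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      config_error("feature placement failed: TAD too small for the requested features")
    }
  }
  list(start = starts, end = ends)
}

#' Simulate a TAD-structured genome with known ground truth
#'
#' Generates TADs, promoter and enhancer intervals, per-sample count tables
#' for both feature classes, and the ground truth (per-TAD activity,
#' per-feature baseline and condition effect, per-TAD sign pattern) under
#' the model documented in [sim_config()]. Bit-reproducible for a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @return a list: `tads` (TAD-set `GRanges`), `promoters`, `enhancers`
#'   (named `GRanges`), `prom_counts`, `enh_counts` (data frames:
#'   `feature_id` + one column per sample), `condition` (0/1 per sample),
#'   `truth` (list of `tads` and `features` data frames), `config`.
#' @export
simulate_tad_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$tad_length
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  n_tads <- config$n_chromosomes * config$tads_per_chromosome
  tad_chrom <- rep(chroms, each = config$tads_per_chromosome)
  k <- rep(seq_len(config$tads_per_chromosome), config$n_chromosomes)
  tad_start <- (k - 1) * L           # BED coords
  tad_end <- k * L
  tads <- as_tad_set(GRanges(tad_chrom, IRanges(tad_start + 1, tad_end)))
  tad_ids <- names(tads)

  np <- draw_per_tad(config$promoters_per_tad, n_tads)
  ne <- draw_per_tad(config$enhancers_per_tad, n_tads)

  # truth: shared activity and TAD-wise condition pattern
  a_t <- rnorm(n_tads, 0, config$tad_activity_sd)
  n_de <- round(config$de_fraction * n_tads)
  de_tads <- if (n_de > 0) sort(sample.int(n_tads, n_de)) else integer(0)
  pattern <- rep(NA_character_, n_tads)
  if (length(de_tads)) {
    pattern[de_tads] <- sample(PATTERNS, length(de_tads), replace = TRUE,
                               prob = config$pattern_mixture)
  }

  p_list <- vector("list", n_tads)
  e_list <- vector("list", n_tads)
  for (t in seq_len(n_tads)) {
    widths <- c(rep(PROMOTER_WIDTH, np[t]), rep(ENHANCER_WIDTH, ne[t]))
    pos <- place_features(tad_start[t], tad_end[t], widths)
    ip <- seq_len(np[t])
    ie <- np[t] + seq_len(ne[t])
    p_list[[t]] <- data.frame(
      chrom = tad_chrom[t], start = pos$start[ip], end = pos$end[ip],
      id = sprintf("P_%s_%d", tad_ids[t], ip), tad = t,
      stringsAsFactors = FALSE)
    e_list[[t]] <- data.frame(
      chrom = tad_chrom[t], start = pos$start[ie], end = pos$end[ie],
      id = sprintf("E_%s_%d", tad_ids[t], seq_len(ne[t])), tad = t,
      stringsAsFactors = FALSE)
  }
  pdf <- do.call(rbind, p_list)
  edf <- do.call(rbind, e_list)

  sign_of <- function(ch) ifelse(ch == "+", 1, -1)
  g_for <- function(df, side) {
    pat <- pattern[df$tad]
    out <- rep(0, nrow(df))
    has <- !is.na(pat)
    ch <- substr(pat[has], side, side)
    out[has] <- sign_of(ch) * config$effect_size
    out
  }
  g_p <- g_for(pdf, 1L)
  g_e <- g_for(edf, 2L)
  b_p <- rnorm(nrow(pdf), config$feature_baseline_mean,
               config$feature_baseline_sd)
  b_e <- rnorm(nrow(edf), config$feature_baseline_mean,
               config$feature_baseline_sd)

  ns <- config$n_samples_per_condition
  condition <- rep(c(0L, 1L), each = ns)
  samples <- c(sprintf("slow_%d", seq_len(ns)), sprintf("fast_%d", seq_len(ns)))

  counts_for <- function(b, g, tad_of) {
    mu <- outer(b + a_t[tad_of], rep(1, 2 * ns)) +
      outer(g, condition) +
      matrix(rnorm(length(b) * 2 * ns, 0, config$noise_sd),
             nrow = length(b))
    round(2^mu)
  }
  cp <- counts_for(b_p, g_p, pdf$tad)
  ce <- counts_for(b_e, g_e, edf$tad)
  colnames(cp) <- colnames(ce) <- samples

  mk_gr <- function(df) {
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
    names(gr) <- df$id
    normalize_intervals(gr)
  }

  list(
    tads = tads,
    promoters = mk_gr(pdf),
    enhancers = mk_gr(edf),
    prom_counts = data.frame(feature_id = pdf$id, cp, check.names = FALSE,
                             stringsAsFactors = FALSE),
    enh_counts = data.frame(feature_id = edf$id, ce, check.names = FALSE,
                            stringsAsFactors = FALSE),
    condition = setNames(condition, samples),
    truth = list(
      tads = data.frame(tad_id = tad_ids, activity = a_t, pattern = pattern,
                        stringsAsFactors = FALSE),
      features = data.frame(
        feature_id = c(pdf$id, edf$id),
        type = rep(c("promoter", "enhancer"), c(nrow(pdf), nrow(edf))),
        tad_id = tad_ids[c(pdf$tad, edf$tad)],
        baseline = c(b_p, b_e),
        effect = c(g_p, g_e),
        stringsAsFactors = FALSE)),
    config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits `tads.bed`, `promoters.bed`, `enhancers.bed`, `prom_counts.tsv`,
#' `enh_counts.tsv`, `condition.tsv`, `truth_tads.tsv`,
#' `truth_features.tsv`.
#'
#' @param sim a result of [simulate_tad_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(sim$tads, file.path(dir, "tads.bed"))
  write_bed(sim$promoters, file.path(dir, "promoters.bed"))
  write_bed(sim$enhancers, file.path(dir, "enhancers.bed"))
  write_tsv(sim$prom_counts, file.path(dir, "prom_counts.tsv"))
  write_tsv(sim$enh_counts, file.path(dir, "enh_counts.tsv"))
  write_tsv(data.frame(sample = names(sim$condition),
                       condition = sim$condition),
            file.path(dir, "condition.tsv"))
  write_tsv(sim$truth$tads, file.path(dir, "truth_tads.tsv"))
  write_tsv(sim$truth$features, file.path(dir, "truth_features.tsv"))
  invisible(dir)
}
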