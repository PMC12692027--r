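#' Tabulate differentially expressed features per TAD
#'
#' Joins a DE table with a TAD assignment, keeping features that pass the FDR
#' cut and are assigned to a TAD.
#'
#' @param de a DE table ([validate_de_table()] applied internally).
#' @param assignment named character vector from [assign_to_tads()].
#' @param fdr_threshold significance cut (strict `<`), default 0.05.
#' @return a data frame with `tad_id`, `feature_id`, `sign`, `log2fc`.
#' @export
de_features_by_tad <- function(de, assignment, fdr_threshold = 0.05) {
  de <- validate_de_table(de, fdr_threshold)
  tad <- assignment[de$feature_id]
  keep <- !is.na(tad) & de$fdr < fdr_threshold
  data.frame(tad_id = unname(tad[keep]), feature_id = de$feature_id[keep],
             sign = de$sign[keep], log2fc = de$log2fc[keep],
             stringsAsFactors = FALSE)
}

#' Count sign-pattern interaction classes per TAD
#'
#' Within a TAD carrying p differentially expressed promoters and e
#' differentially expressed enhancers, every promoter is paired with every
#' enhancer, so the interaction total is the product p * e, and the four
#' class counts are products of the per-direction counts:
#' `c_pp = n_prom_up * n_enh_up`, etc. (promoter sign first). Only TADs with
#' at least one DE promoter and one DE enhancer produce a record. All
#' arithmetic is exact integer work.
#'
#' @param prom_by_tad,enh_by_tad data frames from [de_features_by_tad()].
#' @return a data frame with per-TAD direction counts, the four class counts
#'   `c_pp`, `c_pm`, `c_mp`, `c_mm`, and `total`.
#' @export
count_tad_patterns <- function(prom_by_tad, enh_by_tad) {
  count_signs <- function(df) {
    up <- tapply(df$sign == "+", df$tad_id, sum)
    dn <- tapply(df$sign == "-", df$tad_id, sum)
    data.frame(tad_id = names(up), up = as.integer(up), down = as.integer(dn),
               stringsAsFactors = FALSE)
  }
  empty <- data.frame(tad_id = character(0),
                      n_prom_up = integer(0), n_prom_down = integer(0),
                      n_enh_up = integer(0), n_enh_down = integer(0),
                      c_pp = integer(0), c_pm = integer(0),
                      c_mp = integer(0), c_mm = integer(0),
                      total = integer(0), stringsAsFactors = FALSE)
  if (nrow(prom_by_tad) == 0L || nrow(enh_by_tad) == 0L) return(empty)
  p <- count_signs(prom_by_tad)
  e <- count_signs(enh_by_tad)
  shared <- intersect(p$tad_id, e$tad_id)
  if (!length(shared)) return(empty)
  p <- p[match(shared, p$tad_id), ]
  e <- e[match(shared, e$tad_id), ]
  out <- data.frame(
    tad_id = shared,
    n_prom_up = p$up, n_prom_down = p$down,
    n_enh_up = e$up, n_enh_down = e$down,
    c_pp = p$up * e$up, c_pm = p$up * e$down,
    c_mp = p$down * e$up, c_mm = p$down * e$down,
    stringsAsFactors = FALSE)
  out$total <- out$c_pp + out$c_pm + out$c_mp + out$c_mm
  out[order(out$tad_id), , drop = FALSE]
}

#' Tissue-level interaction profile
#'
#' Sums the four sign-pattern class counts over all TADs of a tissue and
#' normalises the grand total to 1 to obtain class proportions. A zero grand
#' total yields zero proportions and sets the `flagged` field.
#'
#' @param counts per-TAD pattern counts ([count_tad_patterns()]).
#' @param tissue tissue name carried into the profile.
#' @return an object of class `tissue_profile`: tissue, total, class counts
#'   `n_pp`..`n_mm`, proportions `p_pp`..`p_mm`, `flagged`.
#' @export
tissue_profile <- function(counts, tissue = "tissue") {
  n <- c(pp = sum(counts$c_pp), pm = sum(counts$c_pm),
         mp = sum(counts$c_mp), mm = sum(counts$c_mm))
  total <- sum(n)
  p <- if (total > 0) n / total else c(pp = 0, pm = 0, mp = 0, mm = 0)
  structure(list(tissue = tissue, total = total,
                 n_pp = unname(n["pp"]), n_pm = unname(n["pm"]),
                 n_mp = unname(n["mp"]), n_mm = unname(n["mm"]),
                 p_pp = unname(p["pp"]), p_pm = unname(p["pm"]),
                 p_mp = unname(p["mp"]), p_mm = unname(p["mm"]),
                 flagged = total == 0),
            class = "tissue_profile")
}

#' Tissue profile straight from a filtered pair table
#'
#' Equivalent to [tissue_profile()] on [count_tad_patterns()]: because every
#' DE promoter is paired with every DE enhancer of its TAD, the number of
#' pairs of each pattern equals the per-TAD product summed over TADs.
#'
#' @param pairs a filtered pair data frame with a `pattern` column.
#' @param tissue tissue name.
#' @return a `tissue_profile`.
#' @export
tissue_profile_from_pairs <- function(pairs, tissue = "tissue") {
  n <- vapply(c(pp = "++", pm = "+-", mp = "-+", mm = "--"),
              function(p) sum(pairs$pattern == p), 0L)
  total <- sum(n)
  p <- if (total > 0) n / total else c(pp = 0, pm = 0, mp = 0, mm = 0)
  structure(list(tissue = tissue, total = total,
                 n_pp = unname(n["pp"]), n_pm = unname(n["pm"]),
                 n_mp = unname(n["mp"]), n_mm = unname(n["mm"]),
                 p_pp = unname(p["pp"]), p_pm = unname(p["pm"]),
                 p_mp = unname(p["mp"]), p_mm = unname(p["mm"]),
                 flagged = total == 0),
            class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("Tissue interaction profile: %s\n", x$tissue))
  cat(sprintf("  total interactions: %d%s\n", x$total,
              if (x$flagged) "  (no qualifying TADs)" else ""))
  cat(sprintf("  %-4s %8s %8s\n", "", "count", "prop"))
  for (cl in c("pp", "pm", "mp", "mm")) {
    lab <- chartr("pm", "+-", cl)
    cat(sprintf("  %-4s %8d %8.4f\n", lab,
                x[[paste0("n_", cl)]], x[[paste0("p_", cl)]]))
  }
  invisible(x)
}

#' @export
#' @method as.data.frame tissue_profile
as.data.frame.tissue_profile <- function(x, ...) {
  data.frame(tissue = x$tissue, total = x$total,
             n_pp = x$n_pp, n_pm = x$n_pm, n_mp = x$n_mp, n_mm = x$n_mm,
             p_pp = x$p_pp, p_pm = x$p_pm, p_mp = x$p_mp, p_mm = x$p_mm)
}

#' Identify consolidated TADs
#'
#' A consolidated TAD is one whose differentially expressed promoters all
#' share one direction of change and whose differentially expressed enhancers
#' all share one direction; exactly one of the four class counts is then
#' nonzero. `promoter_only = TRUE` relaxes the enhancer condition (the
#' enhancer side of the label becomes `"."` when enhancer signs are mixed).
#'
#' @param counts per-TAD pattern counts ([count_tad_patterns()]).
#' @param promoter_only require uniformity of promoter signs only.
#' @return the consolidated subset of `counts` with a `label` column
#'   (promoter sign then enhancer sign).
#' @export
consolidated_tads <- function(counts, promoter_only = FALSE) {
  if (nrow(counts) == 0L) {
    counts$label <- character(0)
    return(counts)
  }
  prom_uni <- counts$n_prom_up == 0L | counts$n_prom_down == 0L
  enh_uni <- counts$n_enh_up == 0L | counts$n_enh_down == 0L
  keep <- prom_uni & (promoter_only | enh_uni)
  out <- counts[keep, , drop = FALSE]
  ps <- ifelse(out$n_prom_up > 0L, "+", "-")
  es <- ifelse(out$n_enh_up > 0L & out$n_enh_down == 0L, "+",
               ifelse(out$n_enh_down > 0L & out$n_enh_up == 0L, "-", "."))
  out$label <- paste0(ps, es)
  rownames(out) <- NULL
  out
}

#' Interaction classes restricted to annotated promoters
#'
#' Recomputes the per-TAD class products counting only promoters whose mapped
#' gene belongs to an annotation set (e.g. transcription factors or
#' cofactors), and reports the number of distinct annotated DE genes along
#' with the four class totals. Features absent from `id_map` default to
#' unannotated.
#'
#' @param prom_by_tad,enh_by_tad data frames from [de_features_by_tad()].
#' @param annotation character vector of annotated gene ids (non-empty).
#' @param id_map optional named character vector mapping promoter feature ids
#'   to gene ids; by default feature ids are used as gene ids.
#' @return a list: `n_genes`, `c_pp`, `c_pm`, `c_mp`, `c_mm`, `total`.
#' @export
annotated_subset_profile <- function(prom_by_tad, enh_by_tad, annotation,
                                     id_map = NULL) {
  if (length(annotation) == 0L) {
    config_error("annotation set must be non-empty")
  }
  gene <- if (is.null(id_map)) prom_by_tad$feature_id else
    unname(id_map[prom_by_tad$feature_id])
  keep <- !is.na(gene) & gene %in% annotation
  sub <- prom_by_tad[keep, , drop = FALSE]
  counts <- count_tad_patterns(sub, enh_by_tad)
  list(n_genes = length(unique(gene[keep])),
       c_pp = sum(counts$c_pp), c_pm = sum(counts$c_pm),
       c_mp = sum(counts$c_mp), c_mm = sum(counts$c_mm),
       total = sum(counts$total))
}
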