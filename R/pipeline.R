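#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Required keys: `promoters`,
#' `enhancers` (BED), `prom_counts`, `enh_counts` (TSV), `condition` (TSV
#' with `sample` and `condition` columns, or an inline 0/1 vector), and
#' either `tads` (one BED) or both `tads_a` and `tads_b` (two parent sets to
#' combine into a consensus). `tissues` is a named map of tissue ->
#' `{de_prom, de_enh}` DE-table paths; when omitted, DE tables are computed
#' from the counts with [naive_de()] for a single tissue named
#' `"condition_effect"`. Defaults: `fdr = 0.05`, `max_distance = 500000`,
#' `pseudocount = 1`, `consensus_mode = "intersect"`, `adjacent_null = TRUE`,
#' `seed = 1`. Unknown keys draw a warning; missing paths and out-of-range
#' thresholds are errors.
#'
#' @param x a YAML path or a list.
#' @return a validated `tadlink_config` list.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_error(sprintf("config file not found: %s", x))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) config_error("config must be a YAML file or a list")
  known <- c("tads", "tads_a", "tads_b", "promoters", "enhancers",
             "prom_counts", "enh_counts", "condition", "tissues",
             "fdr", "max_distance", "pseudocount", "consensus_mode",
             "adjacent_null", "seed", "out_dir")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    warning(sprintf("unknown config key(s) ignored: %s",
                    paste(unknown, collapse = ", ")))
  }
  defaults <- list(fdr = 0.05, max_distance = 500000, pseudocount = 1,
                   consensus_mode = "intersect", adjacent_null = TRUE,
                   seed = 1L)
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  required <- c("promoters", "enhancers", "prom_counts", "enh_counts")
  miss <- required[vapply(required, function(k) is.null(x[[k]]), TRUE)]
  if (length(miss)) {
    config_error(sprintf("config missing required key(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (is.null(x$tads) && (is.null(x$tads_a) || is.null(x$tads_b))) {
    config_error("config needs either 'tads' or both 'tads_a' and 'tads_b'")
  }
  if (x$fdr <= 0 || x$fdr > 1) config_error("fdr must lie in (0, 1]")
  if (x$max_distance <= 0) config_error("max_distance must be positive")
  if (x$pseudocount <= 0) config_error("pseudocount must be positive")
  if (!x$consensus_mode %in% c("intersect", "merge_chained")) {
    config_error("consensus_mode must be 'intersect' or 'merge_chained'")
  }
  paths <- c("tads", "tads_a", "tads_b", "promoters", "enhancers",
             "prom_counts", "enh_counts")
  for (k in paths) {
    if (!is.null(x[[k]]) && !file.exists(x[[k]])) {
      config_error(sprintf("config key '%s': file not found: %s", k, x[[k]]))
    }
  }
  if (is.character(x$condition) && !file.exists(x$condition)) {
    config_error(sprintf("config key 'condition': file not found: %s",
                         x$condition))
  }
  if (!is.null(x$tissues)) {
    if (is.null(names(x$tissues)) || any(!nzchar(names(x$tissues)))) {
      config_error("tissues must be a named map")
    }
    for (t in names(x$tissues)) {
      for (k in c("de_prom", "de_enh")) {
        f <- x$tissues[[t]][[k]]
        if (is.null(f)) {
          config_error(sprintf("tissue '%s' missing key '%s'", t, k))
        }
        if (!file.exists(f)) {
          config_error(sprintf("tissue '%s' %s: file not found: %s", t, k, f))
        }
      }
    }
  }
  structure(x, class = "tadlink_config")
}

read_condition <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- read_tsv(x)
    setNames(as.integer(df$condition), df$sample)
  } else {
    as.integer(x)
  }
}

#' Run the full TAD-constrained enhancer-promoter analysis
#'
#' Stages: consensus-TAD construction (when two parent sets are given) ->
#' feature-to-TAD assignment -> per-tissue pair enumeration and
#' differential-expression filtering -> per-tissue sign-pattern profile ->
#' TAD-aggregated correlation battery with the adjacent-TAD null ->
#' cross-tissue stable pairs. All intermediate tables are written to
#' `out_dir` as TSV/BED; the run is deterministic given the inputs and seed.
#'
#' @param config a [validate_config()] result, config list, or YAML path.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return a `tadlink_report` list: `consensus` (or `NULL`),
#'   `profiles`, `associations`, `stable`, `tads`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "tadlink_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% config_error("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "tadlink_config_error") ||
          inherits(e, "tadlink_data_error")) {
        e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
        stop(e)
      }
      data_error(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  cons_rep <- NULL
  if (!is.null(config$tads)) {
    tads <- stage("consensus", as_tad_set(read_bed(config$tads)))
  } else {
    cons_rep <- stage("consensus", {
      a <- read_bed(config$tads_a)
      b <- read_bed(config$tads_b)
      consensus_report(a, b, mode = config$consensus_mode)
    })
    write_bed(cons_rep$consensus, file.path(out_dir, "consensus.bed"))
    write_tsv(as.data.frame(cons_rep),
              file.path(out_dir, "consensus_report.tsv"))
    tads <- cons_rep$consensus
  }
  message(sprintf("TAD set: %d TADs", length(tads)))

  promoters <- stage("load_features", read_bed(config$promoters))
  enhancers <- stage("load_features", read_bed(config$enhancers))
  ap <- assign_to_tads(promoters, tads)
  ae <- assign_to_tads(enhancers, tads)
  message(sprintf("features: %d promoters (%d in TADs), %d enhancers (%d in TADs)",
                  length(promoters), sum(!is.na(ap)),
                  length(enhancers), sum(!is.na(ae))))

  prom_counts <- stage("load_counts", read_counts_table(config$prom_counts))
  enh_counts <- stage("load_counts", read_counts_table(config$enh_counts))

  tissues <- stage("load_de", {
    if (!is.null(config$tissues)) {
      lapply(config$tissues, function(t) {
        list(de_prom = read_de_table(t$de_prom),
             de_enh = read_de_table(t$de_enh))
      })
    } else {
      cond <- read_condition(config$condition)
      list(condition_effect = list(
        de_prom = naive_de(prom_counts, cond),
        de_enh = naive_de(enh_counts, cond)))
    }
  })

  all_pairs <- pairs_by_tad(promoters, enhancers, tads)
  message(sprintf("candidate same-TAD pairs: %d", nrow(all_pairs)))

  profiles <- list()
  filtered <- list()
  for (t in names(tissues)) {
    f <- stage(paste0("pairs_", t), {
      filter_differential(all_pairs, tissues[[t]]$de_prom,
                          tissues[[t]]$de_enh, config$fdr)
    })
    write_tsv(f, file.path(out_dir, sprintf("pairs_%s.tsv", t)))
    message(sprintf("tissue %s: %d DE-filtered pairs", t, nrow(f)))
    filtered[[t]] <- f
    profiles[[t]] <- tissue_profile_from_pairs(f, tissue = t)
  }
  write_tsv(do.call(rbind, lapply(profiles, as.data.frame)),
            file.path(out_dir, "profiles.tsv"))

  assoc <- stage("correlation", {
    agg <- aggregate_by_tad(total_feature_counts(prom_counts),
                            total_feature_counts(enh_counts),
                            ap, ae, pseudocount = config$pseudocount)
    same <- tad_association(agg)
    res <- list(same = same)
    if (isTRUE(config$adjacent_null)) {
      res$adjacent <- adjacent_tad_null(agg, tads)
    }
    write_tsv(agg, file.path(out_dir, "scatter.tsv"))
    res
  })
  write_tsv(do.call(rbind, lapply(assoc, as.data.frame)),
            file.path(out_dir, "association.tsv"))

  stable <- NULL
  if (length(filtered) >= 2L) {
    stable <- stable_pairs(filtered)
    write_tsv(stable, file.path(out_dir, "stable_pairs.tsv"))
    message(sprintf("stable pairs across %d tissues: %d",
                    length(filtered), nrow(stable)))
  }

  report <- structure(list(
    consensus = cons_rep,
    profiles = profiles,
    associations = assoc,
    stable = stable,
    tads = tads,
    provenance = list(
      package = "tadlink",
      version = as.character(utils::packageVersion("tadlink")),
      seed = config$seed,
      fdr = config$fdr, max_distance = config$max_distance,
      pseudocount = config$pseudocount,
      consensus_mode = config$consensus_mode)
  ), class = "tadlink_report")
  yaml::write_yaml(report_summary(report), file.path(out_dir, "report.yaml"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_summary <- function(report) {
  list(
    provenance = report$provenance,
    n_tads = length(report$tads),
    consensus = if (is.null(report$consensus)) NULL else
      as.list(as.data.frame(report$consensus)),
    tissues = lapply(report$profiles, function(p)
      as.list(as.data.frame(p))),
    associations = lapply(report$associations, function(a)
      as.list(as.data.frame(a))),
    n_stable_pairs = if (is.null(report$stable)) NULL else nrow(report$stable))
}

#' @export
print.tadlink_report <- function(x, ...) {
  cat("tadlink pipeline report\n")
  cat(sprintf("  TADs: %d\n", length(x$tads)))
  if (!is.null(x$consensus)) print(x$consensus)
  for (p in x$profiles) print(p)
  for (a in x$associations) print(a)
  if (!is.null(x$stable)) {
    cat(sprintf("  stable pairs across tissues: %d\n", nrow(x$stable)))
  }
  invisible(x)
}
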