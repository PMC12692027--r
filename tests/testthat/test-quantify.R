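# worked example: one TAD with promoters {+,+,-} and enhancers {+,+}
worked_prom <- data.frame(tad_id = "t1", feature_id = c("P1", "P2", "P3"),
                          sign = c("+", "+", "-"), log2fc = c(1, 2, -1),
                          stringsAsFactors = FALSE)
worked_enh <- data.frame(tad_id = "t1", feature_id = c("E1", "E2"),
                         sign = c("+", "+"), log2fc = c(1, 0.5),
                         stringsAsFactors = FALSE)

test_that("count_tad_patterns computes exact per-class products", {
  got <- count_tad_patterns(worked_prom, worked_enh)
  expect_equal(got$total, 6)
  expect_equal(got$c_pp, 4)
  expect_equal(got$c_mp, 2)
  expect_equal(got$c_pm, 0)
  expect_equal(got$c_mm, 0)
  # single up promoter and up enhancer
  got <- count_tad_patterns(worked_prom[1, ], worked_enh[1, ])
  expect_equal(unlist(got[c("c_pp", "c_pm", "c_mp", "c_mm")]),
               c(c_pp = 1, c_pm = 0, c_mp = 0, c_mm = 0))
  # a TAD with DE promoters but no DE enhancers yields no record
  got <- count_tad_patterns(worked_prom, worked_enh[0, ])
  expect_equal(nrow(got), 0)
})

test_that("class counts sum to the promoter x enhancer product on random configs", {
  set.seed(41)
  for (i in 1:50) {
    n_tads <- sample(1:8, 1)
    prom <- do.call(rbind, lapply(seq_len(n_tads), function(t) {
      k <- sample(1:6, 1)
      data.frame(tad_id = sprintf("t%d", t),
                 feature_id = sprintf("P%d_%d", t, 1:k),
                 sign = sample(c("+", "-"), k, replace = TRUE),
                 log2fc = 1, stringsAsFactors = FALSE)
    }))
    enh <- do.call(rbind, lapply(seq_len(n_tads), function(t) {
      k <- sample(0:5, 1)
      if (k == 0) return(NULL)
      data.frame(tad_id = sprintf("t%d", t),
                 feature_id = sprintf("E%d_%d", t, 1:k),
                 sign = sample(c("+", "-"), k, replace = TRUE),
                 log2fc = 1, stringsAsFactors = FALSE)
    }))
    if (is.null(enh)) next
    counts <- count_tad_patterns(prom, enh)
    expect_equal(counts$c_pp + counts$c_pm + counts$c_mp + counts$c_mm,
                 (counts$n_prom_up + counts$n_prom_down) *
                   (counts$n_enh_up + counts$n_enh_down))
    prof <- tissue_profile(counts)
    if (prof$total > 0) {
      expect_equal(prof$p_pp + prof$p_pm + prof$p_mp + prof$p_mm, 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("tissue_profile normalises, adds across TADs, and flags empties", {
  counts <- count_tad_patterns(worked_prom, worked_enh)
  prof <- tissue_profile(counts, tissue = "brain")
  expect_equal(prof$total, 6)
  expect_equal(prof$p_pp, 2 / 3)
  expect_equal(prof$p_mp, 1 / 3)
  # two TADs with totals 6 and 4 -> tissue total 10
  prom2 <- worked_prom; prom2$tad_id <- "t2"; prom2 <- prom2[1:2, ]
  enh2 <- worked_enh; enh2$tad_id <- "t2"
  counts2 <- count_tad_patterns(rbind(worked_prom, prom2),
                                rbind(worked_enh, enh2))
  expect_equal(tissue_profile(counts2)$total, 10)
  # empty input flagged, proportions zero
  empty <- tissue_profile(counts[0, ])
  expect_true(empty$flagged)
  expect_equal(empty$p_pp, 0)
})

test_that("consolidated_tads requires sign uniformity on both sides", {
  # promoters {+,+}, enhancers {+} -> consolidated "++"
  prom <- data.frame(tad_id = "t", feature_id = c("P1", "P2"),
                     sign = c("+", "+"), log2fc = 1, stringsAsFactors = FALSE)
  enh <- data.frame(tad_id = "t", feature_id = "E1", sign = "+", log2fc = 1,
                    stringsAsFactors = FALSE)
  got <- consolidated_tads(count_tad_patterns(prom, enh))
  expect_equal(got$label, "++")
  expect_equal(sum(got[, c("c_pp", "c_pm", "c_mp", "c_mm")] > 0), 1)
  # mixed promoter signs are not consolidated
  prom$sign <- c("+", "-")
  expect_equal(nrow(consolidated_tads(count_tad_patterns(prom, enh))), 0)
  # the 3-promoter/2-enhancer worked example is not consolidated either
  expect_equal(nrow(consolidated_tads(count_tad_patterns(worked_prom,
                                                         worked_enh))), 0)
  # mixed-enhancer TAD admitted under the promoter-only relaxation
  prom$sign <- c("+", "+")
  enh2 <- rbind(enh, data.frame(tad_id = "t", feature_id = "E2", sign = "-",
                                log2fc = -1))
  expect_equal(nrow(consolidated_tads(count_tad_patterns(prom, enh2))), 0)
  relaxed <- consolidated_tads(count_tad_patterns(prom, enh2),
                               promoter_only = TRUE)
  expect_equal(relaxed$label, "+.")
})

test_that("consolidated_tads is invariant under feature order", {
  set.seed(42)
  prom <- data.frame(tad_id = rep(c("t1", "t2"), each = 3),
                     feature_id = sprintf("P%d", 1:6),
                     sign = c("+", "+", "+", "-", "+", "-"), log2fc = 1,
                     stringsAsFactors = FALSE)
  enh <- data.frame(tad_id = rep(c("t1", "t2"), each = 2),
                    feature_id = sprintf("E%d", 1:4),
                    sign = c("-", "-", "+", "+"), log2fc = 1,
                    stringsAsFactors = FALSE)
  a <- consolidated_tads(count_tad_patterns(prom, enh))
  perm <- sample(nrow(prom))
  b <- consolidated_tads(count_tad_patterns(prom[perm, ], enh[rev(seq_len(nrow(enh))), ]))
  expect_equal(a, b)
})

test_that("annotated_subset_profile restricts products to annotated promoters", {
  # none annotated -> zeros; all annotated -> equals the full profile
  none <- annotated_subset_profile(worked_prom, worked_enh,
                                   annotation = "GENE_X")
  expect_equal(none$total, 0)
  expect_equal(none$n_genes, 0)
  all_ann <- annotated_subset_profile(worked_prom, worked_enh,
                                      annotation = worked_prom$feature_id)
  full <- tissue_profile(count_tad_patterns(worked_prom, worked_enh))
  expect_equal(all_ann$c_pp, full$n_pp)
  expect_equal(all_ann$c_mp, full$n_mp)
  expect_equal(all_ann$total, full$total)
  # only the down promoter annotated (through an id -> gene map)
  map <- c(P3 = "TF_GENE")
  got <- annotated_subset_profile(worked_prom, worked_enh,
                                  annotation = "TF_GENE", id_map = map)
  expect_equal(got$c_mp, 2)
  expect_equal(got$total, 2)
  expect_equal(got$n_genes, 1)
  expect_error(annotated_subset_profile(worked_prom, worked_enh,
                                        annotation = character(0)),
               "non-empty")
})

test_that("pair-count route equals the product route", {
  sim <- simulate_tad_genome(sim_config(n_chromosomes = 2,
                                        tads_per_chromosome = 8,
                                        tad_length = 5e4, de_fraction = 1,
                                        seed = 9))
  de_p <- naive_de(sim$prom_counts, sim$condition)
  de_e <- naive_de(sim$enh_counts, sim$condition)
  ap <- assign_to_tads(sim$promoters, sim$tads)
  ae <- assign_to_tads(sim$enhancers, sim$tads)
  via_products <- tissue_profile(count_tad_patterns(
    de_features_by_tad(de_p, ap), de_features_by_tad(de_e, ae)))
  pairs <- filter_differential(pairs_by_tad(sim$promoters, sim$enhancers,
                                            sim$tads), de_p, de_e)
  via_pairs <- tissue_profile_from_pairs(pairs)
  expect_equal(via_products$total, via_pairs$total)
  for (cl in c("n_pp", "n_pm", "n_mp", "n_mm")) {
    expect_equal(via_products[[cl]], via_pairs[[cl]])
  }
})
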