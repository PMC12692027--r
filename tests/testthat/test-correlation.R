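test_that("aggregate_by_tad sums counts and applies the pseudocount at transform", {
  counts_p <- c(P1 = 10, P2 = 20, P3 = 5)
  counts_e <- c(E1 = 7)
  assign_p <- c(P1 = "t1", P2 = "t1", P3 = NA)
  assign_e <- c(E1 = "t1")
  agg <- aggregate_by_tad(counts_p, counts_e, assign_p, assign_e)
  expect_equal(agg$prom_sum, 30)
  expect_equal(agg$prom_log2, log2(31))
  expect_equal(agg$enh_log2, log2(8))
  # a TAD with promoters but no enhancers is excluded
  assign_p2 <- c(P1 = "t1", P2 = "t2", P3 = NA)
  agg <- aggregate_by_tad(counts_p, counts_e, assign_p2, assign_e)
  expect_equal(agg$tad_id, "t1")
  # zero counts anchor at log2(pseudocount)
  agg <- aggregate_by_tad(c(P1 = 0), c(E1 = 0), c(P1 = "t"), c(E1 = "t"))
  expect_equal(agg$prom_log2, 0)
  expect_error(aggregate_by_tad(c(P1 = -1), counts_e, assign_p, assign_e),
               "negative")
})

test_that("aggregation conserves total assigned counts", {
  sim <- simulate_tad_genome(sim_config(n_chromosomes = 2,
                                        tads_per_chromosome = 10,
                                        tad_length = 1e5, seed = 5))
  cp <- total_feature_counts(sim$prom_counts)
  ce <- total_feature_counts(sim$enh_counts)
  ap <- assign_to_tads(sim$promoters, sim$tads)
  ae <- assign_to_tads(sim$enhancers, sim$tads)
  agg <- aggregate_by_tad(cp, ce, ap, ae)
  expect_equal(sum(agg$prom_sum) + sum(cp[is.na(ap[names(cp)])]), sum(cp))
  expect_equal(sum(agg$enh_sum) + sum(ce[is.na(ae[names(ce)])]), sum(ce))
})

test_that("theil_sen reproduces the worked examples exactly", {
  fit <- theil_sen(c(0, 1, 2), c(0, 2, 4))
  expect_equal(unname(coef(fit)), c(0, 2))
  # pairwise slopes {1, 5, 9} -> slope 5; residual median -> intercept 0
  fit <- theil_sen(c(0, 1, 2), c(0, 1, 10))
  expect_equal(unname(coef(fit)), c(0, 5))
  expect_equal(residuals(fit), c(0, -4, 0))
  expect_equal(predict(fit, c(3, 4)), c(15, 20))
  # invariant under point reordering
  set.seed(51)
  x <- rnorm(15); y <- rnorm(15)
  p <- sample(15)
  expect_equal(coef(theil_sen(x, y)), coef(theil_sen(x[p], y[p])))
  expect_error(theil_sen(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("theil_sen equals the all-pairs-median oracle on random data", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(2:30, 1)
    x <- round(rnorm(n), 2)
    y <- round(2 * x + rnorm(n), 2)
    if (length(unique(x)) < 2) next
    ref <- oracle_theil_sen(x, y)
    fit <- theil_sen(x, y)
    expect_identical(unname(coef(fit)), c(ref$intercept, ref$slope))
  }
})

test_that("theil_sen shrugs off gross outliers on a noiseless line", {
  x <- 1:12
  y <- 3 * x + 1
  y[c(2, 7, 11)] <- c(500, -200, 999)  # floor(12/4) = 3 outliers
  fit <- theil_sen(x, y)
  expect_equal(unname(coef(fit)[2]), 3)
})

test_that("the battery recovers perfect positive and negative relations", {
  agg <- data.frame(tad_id = sprintf("t%d", 1:10), enh_log2 = 1:10,
                    prom_log2 = 1:10)
  a <- tad_association(agg)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$spearman_rho, 1)
  expect_equal(a$kendall_tau, 1)
  expect_equal(a$slr_slope, 1)
  expect_equal(a$theilsen_slope, 1)
  agg$prom_log2 <- -agg$prom_log2
  b <- tad_association(agg)
  expect_equal(unname(coef(b)[c("pearson_r", "spearman_rho", "kendall_tau")]),
               c(-1, -1, -1))
  # linear maps of x leave pearson at 1
  agg$prom_log2 <- 5 + 0.25 * agg$enh_log2
  expect_equal(tad_association(agg)$pearson_r, 1)
})

test_that("battery statistics match first-principles oracles on a 5-point set", {
  x <- c(1, 2, 2, 4, 7)
  y <- c(2, 1, 5, 4, 9)
  agg <- data.frame(tad_id = sprintf("t%d", 1:5), enh_log2 = x, prom_log2 = y)
  a <- tad_association(agg)
  pe <- oracle_pearson(x, y)
  sp <- oracle_spearman(x, y)
  sl <- oracle_slr(x, y)
  ts <- oracle_theil_sen(x, y)
  expect_equal(a$pearson_r, pe$r)
  expect_equal(a$pearson_p, pe$p)
  expect_equal(a$spearman_rho, sp$r)
  expect_equal(a$spearman_p, sp$p)
  expect_equal(a$kendall_tau, oracle_kendall_taub(x, y))
  expect_equal(a$slr_slope, sl$slope)
  expect_equal(a$slr_intercept, sl$intercept)
  expect_equal(a$theilsen_slope, ts$slope)
  expect_equal(a$theilsen_intercept, ts$intercept)
  expect_true(all(abs(coef(a)[c("pearson_r", "spearman_rho",
                                "kendall_tau")]) <= 1))
})

test_that("degenerate and small inputs are reported, not computed", {
  agg <- data.frame(tad_id = c("a", "b"), enh_log2 = c(1, 2),
                    prom_log2 = c(3, 4))
  a <- tad_association(agg)
  expect_true(is.na(a$pearson_p))   # p undefined below 3 points
  expect_equal(a$pearson_r, 1)
  flat <- data.frame(tad_id = sprintf("t%d", 1:5), enh_log2 = rep(2, 5),
                     prom_log2 = rnorm(5))
  d <- tad_association(flat)
  expect_true(d$degenerate)
  expect_true(is.na(d$pearson_r))
})

test_that("adjacent_tad_null shifts within chromosomes without wrapping", {
  tads <- as_tad_set(gr_bed(rep(c("chr1", "chr2"), c(3, 2)),
                            c(0, 1000, 2000, 0, 1000),
                            c(1000, 2000, 3000, 1000, 2000)))
  agg <- data.frame(tad_id = names(tads),
                    enh_log2 = c(1, 2, 3, 10, 20),
                    prom_log2 = c(5, 6, 7, 50, 60))
  null <- adjacent_tad_null(agg, tads)
  # chr1: (e1,p2), (e2,p3); chr2: (e4,p5) -> 3 shifted pairs
  expect_equal(null$n_tads, 3)
  expect_equal(null$data$enh_log2, c(1, 2, 10))
  expect_equal(null$data$prom_log2, c(6, 7, 60))
  # two chromosomes with 2 usable TADs each -> 2 pairs -> insufficient
  expect_error(adjacent_tad_null(agg[c(1, 2, 4, 5), ], tads), "at least 3")
})

test_that("shared TAD activity induces same-TAD but not adjacent correlation", {
  sim <- simulate_tad_genome(sim_config(n_chromosomes = 3,
                                        tads_per_chromosome = 25,
                                        tad_length = 1e5,
                                        tad_activity_sd = 1, noise_sd = 0.5,
                                        de_fraction = 0,
                                        n_samples_per_condition = 1,
                                        seed = 53))
  ap <- assign_to_tads(sim$promoters, sim$tads)
  ae <- assign_to_tads(sim$enhancers, sim$tads)
  agg <- aggregate_by_tad(total_feature_counts(sim$prom_counts),
                          total_feature_counts(sim$enh_counts), ap, ae)
  same <- tad_association(agg)
  null <- adjacent_tad_null(agg, sim$tads)
  expect_gt(same$pearson_r, 0.4)
  expect_lt(same$pearson_p, 1e-4)
  expect_gt(same$pearson_r, abs(null$pearson_r))
})
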