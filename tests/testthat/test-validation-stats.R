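test_that("delta-Ct averages technical duplicates and subtracts housekeeping", {
  rec <- tibble::tibble(
    experiment = "E1", replicate = 1, condition = "growth_control",
    amplicon = rep(c("target_wildtype", "housekeeping"), each = 2),
    timepoint = 48, tech_rep = c(1, 2, 1, 2),
    ct = c(28.1, 27.9, 20.2, 19.8))
  d <- delta_ct(rec)
  expect_equal(nrow(d), 1)
  expect_equal(d$delta_ct, 8)  # 28 - 20
  # equal Cts -> 0
  rec0 <- dplyr::mutate(rec, ct = 21)
  expect_equal(delta_ct(rec0)$delta_ct, 0)
  # a sample missing its housekeeping Ct is excluded with a warning
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, replicate = 2))
  rec_miss <- rec2[!(rec2$replicate == 2 & rec2$amplicon == "housekeeping"), ]
  expect_warning(d2 <- delta_ct(rec_miss), "housekeeping")
  expect_equal(nrow(d2), 1)
  expect_equal(d2$replicate, 1)
  # batch equals elementwise subtraction
  tab <- simulate_ct(seed = 3)
  d3 <- delta_ct(tab)
  avg <- stats::aggregate(ct ~ experiment + replicate + condition + amplicon,
                          tab, mean)
  one <- d3[1, ]
  t_ct <- avg$ct[avg$experiment == one$experiment & avg$replicate == one$replicate &
                   avg$condition == one$condition & avg$amplicon == one$amplicon]
  h_ct <- avg$ct[avg$experiment == one$experiment & avg$replicate == one$replicate &
                   avg$condition == one$condition & avg$amplicon == "housekeeping"]
  expect_equal(one$delta_ct, t_ct - h_ct)
})

toy_dct <- function(target_shift = 0, base = c(1, 2, 3)) {
  # three replicates per condition in one experiment, housekeeping-corrected
  tidyr::expand_grid(experiment = "E1", replicate = 1:3,
                     condition = c("growth_control", "transfection_control",
                                   "sirna_target", "sirna_scrambled")) |>
    dplyr::mutate(timepoint = 48, amplicon = "target_wildtype",
                  delta_ct = base[replicate] +
                    ifelse(condition == "sirna_target", target_shift, 0))
}

test_that("nested delta-delta-Ct enumerates all nine combinations", {
  d <- toy_dct(target_shift = -1)
  r <- ddct_nested(d, "sirna_target", "target_wildtype")
  expect_equal(nrow(r), 9)
  # hand enumeration: ddct[i,j] = (base_i - 1) - base_j - mean(base_i - base_j)
  # mean Dharmafect effect over its own 9 combos is 0 here (same baselines)
  hand <- outer(c(0, 1, 2) - 1, c(0, 1, 2), `-`)
  expect_setequal(round(r$ddct, 9), round(as.vector(hand), 9))
  # identical delta-Cts everywhere -> all zero
  flat <- toy_dct(0, base = rep(2, 3))
  expect_true(all(ddct_nested(flat, "sirna_target",
                              "target_wildtype")$ddct == 0))
  # uniform planted shift -> all nine equal the shift
  shifted <- toy_dct(-1.2, base = rep(2, 3))
  expect_true(all(abs(ddct_nested(shifted, "sirna_target",
                                  "target_wildtype")$ddct - (-1.2)) < 1e-12))
})

test_that("ddct is invariant to adding a constant to one amplicon's Ct values", {
  tab <- simulate_ct(seed = 11)
  shift <- dplyr::mutate(tab, ct = ct + ifelse(amplicon == "target_wildtype", 5, 0))
  r1 <- ddct_nested(delta_ct(tab), "sirna_target", "target_wildtype")
  r2 <- ddct_nested(delta_ct(shift), "sirna_target", "target_wildtype")
  expect_equal(r1$ddct, r2$ddct, tolerance = 1e-9)
})

test_that("experiments below the validity threshold are excluded", {
  d <- toy_dct(-1)
  d <- d[!(d$condition == "sirna_target" & d$replicate > 1), ]
  expect_message(r <- ddct_nested(d, "sirna_target", "target_wildtype"),
                 "excluded")
  expect_equal(nrow(r), 0)
  # min_valid = 2 keeps a 2-replicate design
  d2 <- toy_dct(-1)
  d2 <- d2[!(d2$condition == "sirna_target" & d2$replicate > 2), ]
  r2 <- ddct_nested(d2, "sirna_target", "target_wildtype")
  expect_equal(nrow(r2), 6)  # 2 cases x 3 controls
})

test_that("the unrelated subset is a disjoint matching pooled across experiments", {
  tab <- simulate_ct(seed = 21)
  r <- ddct_nested(delta_ct(tab), "sirna_target", "target_wildtype")
  u <- unrelated_subset(r)
  expect_equal(u$n, 9)  # 3 per experiment x 3 experiments
  per_exp <- split(u$subset, u$subset$experiment)
  for (ex in per_exp) {
    expect_equal(anyDuplicated(ex$case_replicate), 0)
    expect_equal(anyDuplicated(ex$ref_replicate), 0)
    expect_equal(nrow(ex), 3)
  }
  # all-zero values give p = 1
  r0 <- ddct_nested(toy_dct(0), "sirna_target", "target_wildtype")
  expect_equal(unrelated_subset(r0)$p_value, 1)
  # a seeded random matching is also disjoint and reproducible
  u1 <- unrelated_subset(r, matching = "random", seed = 4)
  u2 <- unrelated_subset(r, matching = "random", seed = 4)
  expect_equal(u1$subset, u2$subset)
})

test_that("a planted knockdown is recovered and detected by the rank test", {
  # planted effect: sirna effect -1.2 relative to growth control
  reps <- sapply(1:40, function(s) {
    tab <- simulate_ct(seed = 100 + s)
    r <- ddct_nested(delta_ct(tab), "sirna_target", "target_wildtype")
    u <- unrelated_subset(r)
    c(mean(u$subset$ddct), u$p_value)
  })
  est <- mean(reps[1, ])
  se <- sd(reps[1, ]) / sqrt(ncol(reps))
  expect_lt(abs(est - (-1.2)), 3 * se + 0.02)
  # power at alpha = 0.1 for a shift of ~1.5x the delta-delta-Ct noise SD
  # (plate noise 0.15 propagates to ~0.32 on each nested difference)
  ps <- vapply(1:200, function(s) {
    t2 <- simulate_ct(effects = c(growth_control = 0, transfection_control = 0.3,
                                  sirna_target = -0.48, sirna_scrambled = 0.3),
                      seed = 5000 + s)
    unrelated_subset(ddct_nested(delta_ct(t2), "sirna_target",
                                 "target_wildtype"))$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.1), 0.8)
})

test_that("exact Wilcoxon signed-rank matches brute-force enumeration for n <= 8", {
  set.seed(61)
  for (n in c(5, 8)) {
    x <- round(rnorm(n), 2)
    while (any(x == 0) || anyDuplicated(abs(x))) x <- round(rnorm(n), 2)
    p_pkg <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE)$p.value)
    # brute force: all 2^n sign assignments of the ranks
    r <- rank(abs(x))
    v_obs <- sum(r[x > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    v_all <- as.matrix(signs) %*% r
    p_brute <- mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4))
    expect_equal(p_pkg, p_brute, tolerance = 1e-12)
  }
})

test_that("band-intensity comparison normalizes by isotype and is exact", {
  tab <- tidyr::expand_grid(experiment_id = paste0("X", 1:3),
                            allele = c("C", "T"),
                            antibody = c("specific", "isotype_control")) |>
    dplyr::mutate(intensity = c(10, 10, 30, 10,
                                12, 10, 33, 10,
                                11, 10, 28, 10))
  r <- compare_band_intensities(tab)
  # complete separation at n = 3 vs 3: exact two-sided p = 2 / choose(6,3)
  expect_equal(r$p_value, 0.1)
  expect_equal(sort(unique(r$normalized$allele)), c("C", "T"))
  # identical normalized sets -> p = 1
  tab_eq <- dplyr::mutate(tab, intensity = rep(c(10, 10), 6))
  expect_equal(compare_band_intensities(tab_eq)$p_value, 1)
  # zero isotype control excludes the experiment (then too few remain)
  tab_z <- tab
  tab_z$intensity[tab_z$experiment_id == "X1" &
                    tab_z$antibody == "isotype_control"] <- 0
  expect_error(suppressWarnings(compare_band_intensities(tab_z)), ">= 3")
})

test_that("exact U test matches brute-force enumeration for small n", {
  set.seed(62)
  g1 <- c(1.3, 2.1, 0.4); g2 <- c(2.9, 3.3, 1.7, 2.2)
  p_pkg <- stats::wilcox.test(g1, g2, exact = TRUE)$p.value
  pool <- c(g1, g2)
  combs <- utils::combn(7, 3)
  r_obs <- sum(rank(pool)[1:3])
  r_all <- apply(combs, 2, function(idx) sum(rank(pool)[idx]))
  mu <- 3 * 8 / 2
  p_brute <- mean(abs(r_all - mu) >= abs(r_obs - mu))
  expect_equal(p_pkg, p_brute, tolerance = 1e-12)
})

test_that("Ct tables round-trip through the TSV reader", {
  tab <- simulate_ct(seed = 31)
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, f)
  back <- read_ct_table(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$ct, tab$ct)
  expect_error(read_ct_table(c("experiment\treplicate\tcondition\tamplicon\tct",
                               "E1\t1\tgrowth_control\thousekeeping\t-3")),
               "positive")
})
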