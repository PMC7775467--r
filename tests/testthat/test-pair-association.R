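test_that("LR statistic is ~0 for identical groups and large for contrasting ones", {
  x <- two_marker_cohort(60, freqs = c(0.4, 0.2, 0.2, 0.2), seed = 21)
  ids <- x$individuals$id
  expect_lt(lr_statistic(x, ids[1:30], ids[1:30], c("m1", "m2")), 1e-6)
  # contrasting haplotype pools (0.8 vs 0.2 on AB) at n = 50 per group
  a <- two_marker_cohort(50, freqs = c(0.8, 0.1, 0.05, 0.05), seed = 22)
  b <- two_marker_cohort(50, freqs = c(0.2, 0.1, 0.05, 0.65), seed = 23)
  b$individuals$id <- paste0("b", b$individuals$id)
  b$genotypes$individual_id <- paste0("b", b$genotypes$individual_id)
  merged <- cohort(a$markers,
                   dplyr::bind_rows(a$individuals, b$individuals),
                   dplyr::bind_rows(a$genotypes, b$genotypes))
  expect_gt(lr_statistic(merged, a$individuals$id, b$individuals$id,
                         c("m1", "m2")), 20)
})

test_that("single-marker LR equals the multinomial G-statistic on allele counts", {
  set.seed(30)
  g_counts <- function(x, ids) {
    gm <- genotype_matrix(x, "m1", ids)
    tabulate(c(gm$a1, gm$a2), 2)
  }
  x <- two_marker_cohort(80, freqs = c(0.55, 0.15, 0.2, 0.1), seed = 31)
  ids <- x$individuals$id
  g1 <- ids[1:40]; g2 <- ids[41:80]
  lr <- lr_statistic(x, g1, g2, "m1")
  # G = 2 * sum obs * log(obs / exp), groups vs pooled allele counts
  o1 <- g_counts(x, g1); o2 <- g_counts(x, g2); op <- o1 + o2
  gstat <- 2 * sum(
    o1[o1 > 0] * log(o1[o1 > 0] / (sum(o1) * (op / sum(op))[o1 > 0])),
    o2[o2 > 0] * log(o2[o2 > 0] / (sum(o2) * (op / sum(op))[o2 > 0])))
  expect_equal(lr, gstat, tolerance = 1e-4)
})

test_that("monomorphic marker yields statistic 0 with a warning", {
  x <- hap_homozygote_cohort(c(AB = 20, Ab = 0, aB = 0, ab = 0))
  expect_warning(s <- lr_statistic(x, x$individuals$id[1:10],
                                   x$individuals$id[11:20], c("m1", "m2")),
                 "monomorphic")
  expect_equal(s, 0)
})

make_null_pairs <- function(seed, n_fam = 40) {
  sim <- simulate_cohort(sim_params(seed = seed, n_families = n_fam,
                                    beta_interaction = 0))
  pairs <- sib_pairs_of(sim)
  pairs$group <- rep(c("g1", "g2"), length.out = nrow(pairs))
  list(cohort = sim$cohort, pairs = pairs)
}

test_that("permutation p-values use the add-one estimator and respect the seed", {
  np <- make_null_pairs(41)
  a1 <- permutation_pvalue(np$cohort, np$pairs, c("rs152730", "rs152745"),
                           n_perm = 99, seed = 5)
  a2 <- permutation_pvalue(np$cohort, np$pairs, c("rs152730", "rs152745"),
                           n_perm = 99, seed = 5)
  expect_equal(a1$results, a2$results)
  expect_gte(a1$results$p_raw, 1 / 100)
  # p_raw is invariant to interchanging the two group labels
  swapped <- np$pairs
  swapped$group <- ifelse(swapped$group == "g1", "g2", "g1")
  a3 <- permutation_pvalue(np$cohort, swapped, c("rs152730", "rs152745"),
                           n_perm = 99, seed = 5)
  expect_equal(a3$results$p_raw, a1$results$p_raw)
})

test_that("a statistic constant under relabelling gives p = 1", {
  # all-identical genotypes: statistic is 0 for every relabelling
  y <- hap_homozygote_cohort(c(AB = 40, Ab = 0, aB = 0, ab = 0))
  pairs_y <- tibble::tibble(family_id = paste0("f", 1:20),
                            sib1_id = y$individuals$id[1:20],
                            sib2_id = y$individuals$id[21:40],
                            group = rep(c("g1", "g2"), each = 10))
  suppressWarnings(a <- permutation_pvalue(y, pairs_y, c("m1", "m2"),
                                           n_perm = 50, seed = 2))
  expect_equal(a$results$p_raw, 1)
})

test_that("within-pair swaps only exchange labels, never pair membership", {
  np <- make_null_pairs(43)
  pairs <- tibble::tibble(mild_id = np$pairs$sib1_id,
                          severe_id = np$pairs$sib2_id)
  a <- haplotype_association(np$cohort, pairs, list(c("rs152730", "rs152745")),
                             scheme = "within_pair_swap", n_perm = 50, seed = 9)
  expect_s3_class(a, "hap_assoc")
  # structural property of the scheme itself
  flip <- c(TRUE, FALSE)[rep(1:2, length.out = nrow(pairs))]
  sp <- sibhap:::split_ids(pairs, "within_pair_swap", flip)
  expect_setequal(c(sp$g1, sp$g2), c(pairs$mild_id, pairs$severe_id))
  expect_equal(sort(c(sp$g1[1], sp$g2[1])),
               sort(c(pairs$mild_id[1], pairs$severe_id[1])))
})

test_that("min-p correction: single combination and duplicates give p_corr = p_raw", {
  np <- make_null_pairs(44)
  one <- haplotype_association(np$cohort, np$pairs,
                               list(c("rs152730", "rs152745")),
                               n_perm = 99, seed = 7, correct = TRUE)
  expect_equal(one$results$p_corr, one$results$p_raw)
  dup <- haplotype_association(np$cohort, np$pairs,
                               list(c("rs152730", "rs152745"),
                                    c("rs152730", "rs152745")),
                               n_perm = 99, seed = 7)
  expect_equal(dup$results$p_corr, dup$results$p_raw, tolerance = 0.021)
  expect_true(all(dup$results$p_corr >= dup$results$p_raw))
})

test_that("min-p correction approaches the Sidak form for independent markers", {
  devs <- sapply(1:4, function(r) {
    sim <- simulate_cohort(sim_params(seed = 100 + r, n_families = 30,
                                      beta_interaction = 0, n_filler = 0))
    # three unlinked markers: two cis SNPs far apart in the pool plus the
    # trans marker segregate near-independently only for trans; build
    # fully independent markers instead by resampling genotypes
    x <- sim$cohort
    set.seed(200 + r)
    g <- x$genotypes
    for (m in c("rs152730", "rs63982", "trans1")) {
      sel <- g$marker_id == m
      g$a1[sel] <- sample(g$a1[sel]); g$a2[sel] <- sample(g$a2[sel])
    }
    x <- cohort(x$markers, x$individuals, g)
    pairs <- sib_pairs_of(sim)
    pairs$group <- rep(c("g1", "g2"), length.out = nrow(pairs))
    a <- haplotype_association(x, pairs,
                               list("rs152730", "rs63982", "trans1"),
                               n_perm = 400, seed = 300 + r)
    sidak <- 1 - (1 - a$results$p_raw)^3
    a$results$p_corr - pmin(1, sidak)
  })
  expect_lt(mean(abs(devs)), 0.06)
})

test_that("TDT counts transmissions correctly and has power at ratio 0.7", {
  # deterministic counting checks on a hand-built trio
  mk <- tibble::tibble(id = "m", chrom = "1", position = 1L,
                       alleles = list(c("A", "a")), kind = "snp")
  trio <- function(fa, mo, kid) {
    ind <- tibble::tibble(id = c("F", "M", "K"), family_id = "f1",
                          father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"),
                          role = c("founder", "founder", "offspring"))
    gen <- tibble::tibble(individual_id = c("F", "M", "K"), marker_id = "m",
                          a1 = c(fa[1], mo[1], kid[1]),
                          a2 = c(fa[2], mo[2], kid[2]))
    cohort(mk, ind, gen)
  }
  # het father transmits A (child A/A, mother A/A): b = 1
  r <- tdt(trio(c(1L, 2L), c(1L, 1L), c(1L, 1L)), "m")
  expect_equal(c(r$b, r$c), c(1L, 0L))
  # both parents het, child het: one transmission each way
  r <- tdt(trio(c(1L, 2L), c(1L, 2L), c(1L, 2L)), "m")
  expect_equal(c(r$b, r$c), c(1L, 1L))
  expect_equal(r$chi_square, 0)
  expect_equal(r$p, 1)
  # b = 10, c = 0 -> chi2 = 10
  expect_equal((10 - 0)^2 / 10, 10)

  # power: 100 families with both parents het, transmission ratio 0.7
  sim_tdt <- function(seed) {
    set.seed(seed)
    n <- 100
    ind <- purrr::map_dfr(seq_len(n), function(f) tibble::tibble(
      id = paste0("f", f, c("F", "M", "K")), family_id = paste0("f", f),
      father_id = c(NA, NA, paste0("f", f, "F")),
      mother_id = c(NA, NA, paste0("f", f, "M")),
      role = c("founder", "founder", "offspring")))
    kid_a <- function() ifelse(runif(n) < 0.7, 1L, 2L)
    gen <- dplyr::bind_rows(
      tibble::tibble(individual_id = ind$id[ind$role == "founder"],
                     marker_id = "m", a1 = 1L, a2 = 2L),
      tibble::tibble(individual_id = ind$id[ind$role == "offspring"],
                     marker_id = "m", a1 = kid_a(), a2 = kid_a()))
    tdt(cohort(mk, ind, gen), "m")$p
  }
  power <- mean(vapply(1:60, sim_tdt, numeric(1)) < 0.05)
  expect_gt(power, 0.8)
})

test_that("signal localization merges runs of adjacent significant segments", {
  segs <- tibble::tibble(
    left = c("rs152730", "rs152745", "rs152740", "rsX"),
    right = c("rs152745", "rs152740", "rsX", "rsY"),
    p_raw = c(0.0075, 0.00869, 0.4, 0.2))
  fr <- localize_signal(segs, alpha = 0.05)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$left, "rs152730")
  expect_equal(fr$right, "rs152740")
  expect_equal(fr$n_segments, 2L)
  # two separated significant runs stay separate
  segs2 <- segs
  segs2$p_raw <- c(0.01, 0.5, 0.01, 0.9)
  expect_equal(nrow(localize_signal(segs2)), 2)
  # nothing significant -> empty
  expect_equal(nrow(localize_signal(segs, alpha = 0.001)), 0)
})

test_that("tidy and glance summarize association objects", {
  np <- make_null_pairs(45)
  a <- permutation_pvalue(np$cohort, np$pairs, c("rs152730", "rs152745"),
                          n_perm = 20, seed = 3)
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(nrow(glance(a)), 1)
  expect_s3_class(autoplot(a, np$cohort), "ggplot")
})

test_that("intrapair within-pair-swap test holds its size under the null", {
  ps <- vapply(1:150, function(s) {
    sim <- simulate_cohort(sim_params(seed = 7000 + s, n_families = 30,
                                      beta_interaction = 0))
    pairs <- sib_pairs_of(sim)
    # arbitrary mild/severe labelling, independent of genotype
    pairs <- tibble::tibble(mild_id = pairs$sib1_id, severe_id = pairs$sib2_id)
    a <- haplotype_association(sim$cohort, pairs,
                               list(c("rs152730", "rs152745")),
                               scheme = "within_pair_swap",
                               n_perm = 200, seed = 7500 + s)
    a$results$p_raw
  }, numeric(1))
  for (alpha in c(0.01, 0.05)) {
    rate <- mean(ps <= alpha)
    half <- 1.96 * sqrt(alpha * (1 - alpha) / 150)
    expect_gte(rate, max(0, alpha - half - 0.005))
    expect_lte(rate, alpha + half + 0.005)
  }
})
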