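test_that("EM equals direct counting when there is no phase ambiguity", {
  x <- hap_homozygote_cohort(c(AB = 40, Ab = 10, aB = 10, ab = 40))
  ft <- em_haplotype_frequencies(x, c("m1", "m2"))
  expect_true(ft$converged)
  expect_equal(ft$table$frequency[match(c("AB", "Ab", "aB", "ab"),
                                        ft$table$haplotype)],
               c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-8)
  expect_equal(sum(ft$table$frequency), 1, tolerance = 1e-9)
})

test_that("a lone double heterozygote splits its explanations 0.5/0.5", {
  x <- two_marker_cohort(1, seed = 1)
  g <- x$genotypes
  g$a1 <- c(1L, 1L); g$a2 <- c(2L, 2L)  # het at both markers
  x <- cohort(x$markers, x$individuals, g)
  ft <- em_haplotype_frequencies(x, c("m1", "m2"))
  el <- explanation_lists(x, ft)
  expect_equal(nrow(el), 2)
  expect_equal(sort(el$weight), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM recovers known frequencies at n = 200 and beats a 0.01-step grid", {
  truth <- c(0.5, 0.3, 0.15, 0.05)
  # recovery: a single n = 200 draw carries binomial noise of SD ~ 0.025 on
  # the common haplotype, so the +/- 0.03 recovery check is applied to the
  # mean estimate over 5 replicate cohorts (the grid oracle below runs on one)
  est5 <- sapply(1:5, function(s) {
    xs <- two_marker_cohort(200, freqs = truth, seed = 10 + s)
    fts <- em_haplotype_frequencies(xs, c("m1", "m2"))
    fts$table$frequency[match(c("AB", "Ab", "aB", "ab"), fts$table$haplotype)]
  })
  expect_lt(max(abs(rowMeans(est5) - truth)), 0.03)
  x <- two_marker_cohort(200, freqs = truth, seed = 11)
  ft <- em_haplotype_frequencies(x, c("m1", "m2"))
  # grid-search oracle over the simplex at 0.01 resolution, using an
  # independently coded genotype likelihood
  grid <- expand.grid(f1 = seq(0, 1, 0.01), f2 = seq(0, 1, 0.01),
                      f3 = seq(0, 1, 0.01))
  grid <- grid[grid$f1 + grid$f2 + grid$f3 <= 1, ]
  # evaluating all ~1.7e5 points via the direct likelihood is feasible when
  # vectorized over the nine genotype classes
  gm <- genotype_matrix(x, c("m1", "m2"))
  cls <- paste(pmin(gm$a1[, 1], gm$a2[, 1]), pmax(gm$a1[, 1], gm$a2[, 1]),
               pmin(gm$a1[, 2], gm$a2[, 2]), pmax(gm$a1[, 2], gm$a2[, 2]))
  tab <- table(cls)
  f1 <- grid$f1; f2 <- grid$f2; f3 <- grid$f3; f4 <- 1 - f1 - f2 - f3
  p_class <- list(
    "1 1 1 1" = f1^2, "1 1 1 2" = 2 * f1 * f2, "1 1 2 2" = f2^2,
    "1 2 1 1" = 2 * f1 * f3, "1 2 1 2" = 2 * (f1 * f4 + f2 * f3),
    "1 2 2 2" = 2 * f2 * f4,
    "2 2 1 1" = f3^2, "2 2 1 2" = 2 * f3 * f4, "2 2 2 2" = f4^2)
  ll_grid <- Reduce(`+`, lapply(names(tab), function(k)
    tab[[k]] * log(pmax(p_class[[k]], 1e-300))))
  expect_gte(ft$log_likelihood, max(ll_grid) - 1e-6)
})

test_that("log-likelihood is non-decreasing and consistency improves with n", {
  truth <- c(0.45, 0.25, 0.2, 0.1)
  rmse <- vapply(c(100, 1000), function(n) {
    x <- two_marker_cohort(n, freqs = truth, seed = n)
    ft <- em_haplotype_frequencies(x, c("m1", "m2"))
    est <- ft$table$frequency[match(c("AB", "Ab", "aB", "ab"), ft$table$haplotype)]
    sqrt(mean((est - truth)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.03)
})

test_that("explanation weights follow f(h1) f(h2) with heterozygote doubling", {
  # double heterozygote under fixed frequencies (0.4, 0.1, 0.1, 0.4):
  # cis pair weight 0.4*0.4*2, trans pair 0.1*0.1*2 -> 16/17 vs 1/17
  x <- hap_homozygote_cohort(c(AB = 4, Ab = 1, aB = 1, ab = 4))
  prior <- em_haplotype_frequencies(x, c("m1", "m2"))
  y <- two_marker_cohort(1, seed = 2)
  g <- y$genotypes; g$a1 <- c(1L, 1L); g$a2 <- c(2L, 2L)
  y <- cohort(y$markers, y$individuals, g)
  el <- explanation_lists(y, prior)
  w <- el$weight[order(el$hap1)]
  expect_equal(sort(w, decreasing = TRUE), c(16 / 17, 1 / 17), tolerance = 1e-6)
})

test_that("training-set mode keeps prior frequencies fixed", {
  x <- hap_homozygote_cohort(c(AB = 40, Ab = 10, aB = 10, ab = 40))
  prior <- em_haplotype_frequencies(x, c("m1", "m2"))
  y <- two_marker_cohort(50, freqs = c(0.05, 0.05, 0.45, 0.45), seed = 3)
  ft <- em_haplotype_frequencies(y, c("m1", "m2"), prior = prior)
  expect_equal(ft$iterations, 0L)
  expect_equal(ft$table$frequency[match(prior$table$haplotype, ft$table$haplotype)],
               prior$table$frequency)
})

test_that("fully missing individual enumerates all completions with unit weight", {
  markers <- tibble::tibble(id = "m1", chrom = "1", position = 1L,
                            alleles = list(c("A", "a")), kind = "snp")
  ind <- tibble::tibble(id = c("obs1", "obs2", "mis"), family_id = c("f1", "f2", "f3"),
                        father_id = NA_character_, mother_id = NA_character_,
                        role = "founder")
  gen <- tibble::tibble(individual_id = c("obs1", "obs2", "mis"),
                        marker_id = "m1",
                        a1 = c(1L, 1L, NA), a2 = c(1L, 2L, NA))
  x <- cohort(markers, ind, gen)
  ft <- em_haplotype_frequencies(x, "m1")
  el <- explanation_lists(x, ft)
  mis <- el[el$individual_id == "mis", ]
  expect_lte(nrow(mis), 3)
  expect_equal(sum(mis$weight), 1, tolerance = 1e-9)
})

test_that("informative markers use strict MAF > threshold, multiallelic via max allele", {
  mk <- tibble::tibble(
    id = c("half", "sixty", "tri"), chrom = "1", position = c(1L, 2L, 3L),
    alleles = list(c("A", "a"), c("A", "a"), c("A", "B", "C")),
    kind = c("snp", "snp", "microsatellite"))
  n <- 10
  ind <- tibble::tibble(id = paste0("i", 1:n), family_id = paste0("i", 1:n),
                        father_id = NA_character_, mother_id = NA_character_,
                        role = "founder")
  gen <- dplyr::bind_rows(
    tibble::tibble(individual_id = ind$id, marker_id = "half",
                   a1 = rep(1:2, 5), a2 = rep(2:1, 5)),          # 0.5 / 0.5
    tibble::tibble(individual_id = ind$id, marker_id = "sixty",
                   a1 = c(rep(1L, 7), 2L, 2L, 2L),
                   a2 = c(rep(1L, 5), rep(2L, 5))),               # 0.6 / 0.4
    tibble::tibble(individual_id = ind$id, marker_id = "tri",
                   a1 = rep(1:2, 5), a2 = c(rep(3L, 4), rep(1L, 6))))
  x <- cohort(mk, ind, gen)
  inf <- informative_markers(x, maf_threshold = 0.4)
  expect_true("half" %in% inf)
  expect_false("sixty" %in% inf)  # MAF exactly 0.4 is not informative
  # tri allele counts: A 11, B 5, C 4 of 20 -> MAF = 1 - 0.55 = 0.45
  expect_true("tri" %in% inf)
})

test_that("D and D' match the closed-form worked example and edge cases", {
  # haplotype frequencies (AB 0.4, Ab 0.1, aB 0.1, ab 0.4):
  # D = 0.4 - 0.25 = 0.15, Dmax = 0.25, D' = 0.6
  x <- hap_homozygote_cohort(c(AB = 40, Ab = 10, aB = 10, ab = 40))
  ld <- d_prime(x, "m1", "m2")
  expect_equal(ld$D, 0.15, tolerance = 1e-6)
  expect_equal(ld$D_prime, 0.6, tolerance = 1e-6)
  # complete LD
  y <- hap_homozygote_cohort(c(AB = 30, Ab = 0, aB = 0, ab = 20))
  expect_equal(d_prime(y, "m1", "m2")$D_prime, 1, tolerance = 1e-6)
  # monomorphic marker is an error
  z <- hap_homozygote_cohort(c(AB = 30, Ab = 0, aB = 20, ab = 0))
  expect_error(d_prime(z, "m1", "m2"), "monomorphic")
})

test_that("independent markers show near-zero D' at n = 2000", {
  x <- two_marker_cohort(2000, freqs = c(0.25, 0.25, 0.25, 0.25), seed = 17)
  expect_lt(d_prime(x, "m1", "m2")$D_prime, 0.1)
})

test_that("blocks chain adjacent markers with D' above threshold", {
  sim <- simulate_cohort(sim_params(seed = 4, n_families = 150))
  cis <- setdiff(sim$cohort$markers$id, "trans1")
  bl <- define_blocks(sim$cohort, cis, threshold = 0.8)
  expect_true(all(bl$start <= bl$end))
  expect_equal(sum(bl$n_markers), length(cis))
  # the preset pool has only 5 of 32 possible haplotypes, so adjacent D'
  # is high and the panel should chain into few blocks
  expect_lte(nrow(bl), 3)
})
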