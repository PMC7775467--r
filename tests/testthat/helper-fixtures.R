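# Shared fixture builders; all synthetic, built in code.

# Minimal two-SNP nuclear-family PED/MAP text (one family, two sibs).
tiny_ped <- function() {
  c("FAM1 DAD 0 0 1 0 A G C C",
    "FAM1 MOM 0 0 2 0 A A C T",
    "FAM1 KID1 DAD MOM 1 2 A A C C",
    "FAM1 KID2 DAD MOM 2 1 A G C T")
}
tiny_map <- function() c("16 rsA 1000", "16 rsB 2000")

# Cohort whose haplotype frequencies are exact by construction: every
# individual is homozygous for one two-marker haplotype, so EM equals
# direct counting.
hap_homozygote_cohort <- function(counts = c(AB = 40, Ab = 10, aB = 10, ab = 40)) {
  haps <- list(AB = c(1L, 1L), Ab = c(1L, 2L), aB = c(2L, 1L), ab = c(2L, 2L))
  hap_of <- rep(names(counts), counts)
  ids <- paste0(hap_of, unlist(lapply(counts, seq_len)))
  markers <- tibble::tibble(
    id = c("m1", "m2"), chrom = "1", position = c(100L, 200L),
    alleles = list(c("A", "a"), c("B", "b")), kind = "snp")
  individuals <- tibble::tibble(id = ids, family_id = ids,
                                father_id = NA_character_,
                                mother_id = NA_character_, role = "founder")
  genotypes <- dplyr::bind_rows(
    tibble::tibble(individual_id = ids, marker_id = "m1",
                   a1 = vapply(hap_of, function(h) haps[[h]][1], integer(1)),
                   a2 = vapply(hap_of, function(h) haps[[h]][1], integer(1))),
    tibble::tibble(individual_id = ids, marker_id = "m2",
                   a1 = vapply(hap_of, function(h) haps[[h]][2], integer(1)),
                   a2 = vapply(hap_of, function(h) haps[[h]][2], integer(1))))
  cohort(markers, individuals, genotypes)
}

# Unrelated individuals drawn from given two-marker haplotype frequencies
# (random pairing of chromosomes), for EM recovery tests.
two_marker_cohort <- function(n, freqs = c(0.5, 0.3, 0.15, 0.05), seed = 1) {
  set.seed(seed)
  haps <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  h1 <- sample.int(4, n, replace = TRUE, prob = freqs)
  h2 <- sample.int(4, n, replace = TRUE, prob = freqs)
  ids <- paste0("i", seq_len(n))
  markers <- tibble::tibble(
    id = c("m1", "m2"), chrom = "1", position = c(100L, 200L),
    alleles = list(c("A", "a"), c("B", "b")), kind = "snp")
  individuals <- tibble::tibble(id = ids, family_id = ids,
                                father_id = NA_character_,
                                mother_id = NA_character_, role = "founder")
  genotypes <- dplyr::bind_rows(
    tibble::tibble(individual_id = ids, marker_id = "m1",
                   a1 = haps[h1, 1], a2 = haps[h2, 1]),
    tibble::tibble(individual_id = ids, marker_id = "m2",
                   a1 = haps[h1, 2], a2 = haps[h2, 2]))
  cohort(markers, individuals, genotypes)
}

# Sibling pairs table (one per family) from a simulated cohort.
sib_pairs_of <- function(sim) {
  sibs <- sim$cohort$individuals[sim$cohort$individuals$role == "offspring", ]
  sibs |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(sib1_id = id[1], sib2_id = id[2], .groups = "drop")
}

# Log-likelihood of two-marker haplotype frequencies for unphased genotype
# data, evaluated directly from genotype class counts (independent of the
# package's EM internals). freqs order: AB, Ab, aB, ab.
ll_two_marker <- function(x, freqs) {
  gm <- genotype_matrix(x, c("m1", "m2"))
  key <- paste(pmin(gm$a1[, 1], gm$a2[, 1]), pmax(gm$a1[, 1], gm$a2[, 1]),
               pmin(gm$a1[, 2], gm$a2[, 2]), pmax(gm$a1[, 2], gm$a2[, 2]))
  f <- freqs
  p_of <- function(k) {
    # probability of an unphased two-marker genotype under given freqs
    g <- as.integer(strsplit(k, " ")[[1]])
    hap <- function(a, b) c(AB = 1, Ab = 2, aB = 3, ab = 4)[[paste0(
      c("A", "a")[a], c("B", "b")[b])]]
    total <- 0
    for (x1 in unique(list(c(g[1], g[2]), c(g[2], g[1])))) {
      for (x2 in unique(list(c(g[3], g[4]), c(g[4], g[3])))) {
        h1 <- hap(x1[1], x2[1]); h2 <- hap(x1[2], x2[2])
        total <- total + f[h1] * f[h2]
      }
    }
    total
  }
  tab <- table(key)
  sum(tab * log(vapply(names(tab), p_of, numeric(1))))
}
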