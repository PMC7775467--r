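# Internal genotype-class machinery -----------------------------------------
#
# EM cost is made independent of cohort size by collapsing individuals into
# distinct multilocus genotype classes and enumerating each class's compatible
# ordered haplotype completions once. Haplotypes are coded in mixed radix over
# the marker subset (panel order, allele-index order), which makes the
# lexicographic tie-break deterministic.

hap_code <- function(alleles_mat, radix) as.vector(alleles_mat %*% radix) + 1L

decode_hap <- function(code, n_alleles) {
  m <- length(n_alleles)
  out <- integer(m)
  x <- code - 1L
  for (j in rev(seq_len(m))) {
    out[j] <- x %% n_alleles[j] + 1L
    x <- x %/% n_alleles[j]
  }
  out
}

hap_label <- function(allele_idx, allele_labels) {
  lab <- vapply(seq_along(allele_idx),
                function(j) allele_labels[[j]][allele_idx[j]], character(1))
  sep <- if (all(nchar(unlist(allele_labels)) == 1)) "" else "-"
  paste(lab, collapse = sep)
}

# Enumerate compatible ordered haplotype pairs for one genotype class.
# gt is a 2 x m matrix of allele indices (NA = missing call at that marker).
enumerate_pairs <- function(gt, n_alleles) {
  m <- ncol(gt)
  opts <- vector("list", m)
  for (j in seq_len(m)) {
    a <- gt[1, j]; b <- gt[2, j]
    if (is.na(a)) {
      k <- n_alleles[j]
      opts[[j]] <- cbind(rep(seq_len(k), each = k), rep(seq_len(k), k))
    } else if (a == b) {
      opts[[j]] <- cbind(a, b)
    } else {
      opts[[j]] <- rbind(c(a, b), c(b, a))
    }
  }
  n_opt <- vapply(opts, nrow, integer(1))
  if (prod(n_opt) > 65536) {
    stop("too many phase/missing-data completions (", prod(n_opt),
         "); reduce the marker subset or the missingness")
  }
  idx <- do.call(expand.grid, lapply(n_opt, seq_len))
  h1 <- matrix(0L, nrow(idx), m)
  h2 <- matrix(0L, nrow(idx), m)
  for (j in seq_len(m)) {
    h1[, j] <- opts[[j]][idx[[j]], 1]
    h2[, j] <- opts[[j]][idx[[j]], 2]
  }
  radix <- rev(cumprod(rev(c(n_alleles[-1], 1))))
  c1 <- hap_code(h1 - 1L, radix)
  c2 <- hap_code(h2 - 1L, radix)
  # collapse to unordered pairs
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  keep <- !duplicated(cbind(lo, hi))
  cbind(h1 = lo[keep], h2 = hi[keep])
}

# Build the class structure for a set of individuals over a marker subset.
build_classes <- function(gm, n_alleles) {
  n <- nrow(gm$a1)
  m <- ncol(gm$a1)
  # drop individuals with no information at all markers? No: fully missing
  # individuals still contribute all completions (weight spreads over them).
  key <- apply(matrix(paste(pmin(gm$a1, gm$a2), pmax(gm$a1, gm$a2), sep = "/"),
                      n, m), 1, paste, collapse = "|")
  uk <- unique(key)
  class_of <- match(key, uk)
  counts <- tabulate(class_of, length(uk))
  pairs <- vector("list", length(uk))
  for (c in seq_along(uk)) {
    i <- which(class_of == c)[1]
    gt <- rbind(gm$a1[i, ], gm$a2[i, ])
    pairs[[c]] <- enumerate_pairs(gt, n_alleles)
  }
  hap_codes <- sort(unique(unlist(lapply(pairs, as.vector))))
  p1 <- unlist(lapply(pairs, function(p) match(p[, 1], hap_codes)))
  p2 <- unlist(lapply(pairs, function(p) match(p[, 2], hap_codes)))
  cls <- rep(seq_along(pairs), vapply(pairs, nrow, integer(1)))
  list(hap_codes = hap_codes, p1 = p1, p2 = p2, cls = cls,
       counts = counts, class_of = class_of, n_classes = length(uk))
}

# One E step: per-pair posterior weights, per-class likelihoods, LL.
e_step <- function(f, st, counts = st$counts) {
  w <- f[st$p1] * f[st$p2] * ifelse(st$p1 == st$p2, 1, 2)
  s <- rep(0, st$n_classes)
  agg <- rowsum(w, st$cls)
  s[as.integer(rownames(agg))] <- agg
  zero <- s[st$cls] == 0
  post <- numeric(length(w))
  post[!zero] <- w[!zero] / s[st$cls][!zero]
  # incompatible-with-all-positive-frequency classes: uniform fallback
  if (any(zero)) {
    npc <- tabulate(st$cls, st$n_classes)
    post[zero] <- 1 / npc[st$cls][zero]
  }
  ll <- sum(counts[s > 0] * log(s[s > 0]))
  list(post = post, s = s, ll = ll, any_zero = any(s == 0 & counts > 0))
}

m_step <- function(post, st, counts = st$counts) {
  wc <- post * counts[st$cls]
  cnt <- numeric(length(st$hap_codes))
  agg <- rowsum(c(wc, wc), c(st$p1, st$p2))
  cnt[as.integer(rownames(agg))] <- agg
  cnt / (2 * sum(counts))
}

# Plain EM loop over a fixed class structure with arbitrary class counts.
em_run <- function(st, counts, f0, tol = 1e-8, max_iter = 1000) {
  f <- f0
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    es <- e_step(f, st, counts)
    f_new <- m_step(es$post, st, counts)
    if (es$ll - ll_old < -1e-9 * max(1, abs(es$ll))) {
      stop("internal error: EM log-likelihood decreased")
    }
    if (max(abs(f_new - f)) < tol && es$ll - ll_old < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    ll_old <- es$ll
    f <- f_new
  }
  es <- e_step(f, st, counts)
  list(f = f, ll = es$ll, post = es$post, converged = converged,
       iterations = it, incompatible = es$any_zero)
}

# Deterministic initialization: product of single-marker allele frequencies.
init_freq <- function(gm, n_alleles, st) {
  m <- ncol(gm$a1)
  pf <- vector("list", m)
  for (j in seq_len(m)) {
    a <- c(gm$a1[, j], gm$a2[, j])
    a <- a[!is.na(a)]
    pf[[j]] <- if (length(a) == 0) rep(1 / n_alleles[j], n_alleles[j]) else
      tabulate(a, n_alleles[j]) / length(a)
  }
  f <- vapply(st$hap_codes, function(code) {
    al <- decode_hap(code, n_alleles)
    prod(vapply(seq_len(m), function(j) pf[[j]][al[j]], numeric(1)))
  }, numeric(1))
  if (sum(f) == 0) f <- rep(1, length(f))
  f / sum(f)
}

em_core <- function(gm, n_alleles, tol = 1e-8, max_iter = 1000,
                    prior_f = NULL, seed = NULL, n_restarts = 0) {
  st <- build_classes(gm, n_alleles)
  if (!is.null(prior_f)) {
    f <- numeric(length(st$hap_codes))
    hit <- match(st$hap_codes, prior_f$codes)
    f[!is.na(hit)] <- prior_f$f[hit[!is.na(hit)]]
    es <- e_step(f, st)
    return(list(f = f, st = st, ll = es$ll, post = es$post,
                converged = TRUE, iterations = 0L,
                incompatible = es$any_zero))
  }
  run_from <- function(f0) em_run(st, st$counts, f0, tol = tol, max_iter = max_iter)
  best <- run_from(init_freq(gm, n_alleles, st))
  if (n_restarts > 0) {
    if (is.null(seed)) seed <- 0L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      f0 <- stats::rgamma(length(st$hap_codes), 1)
      cand <- run_from(f0 / sum(f0))
      if (cand$ll > best$ll) best <- cand
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  c(best, list(st = st))
}

# Resolve a cohort subset + marker set to matrices and allele metadata.
subset_geno <- function(x, marker_ids, individual_ids = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (length(marker_ids) == 0) stop("empty marker set")
  ord <- x$markers$id[x$markers$id %in% marker_ids]
  if (length(ord) != length(marker_ids)) {
    stop("unknown marker(s): ", paste(setdiff(marker_ids, ord), collapse = ", "))
  }
  gm <- genotype_matrix(x, ord, individual_ids)
  labels <- x$markers$alleles[match(ord, x$markers$id)]
  list(gm = gm, marker_ids = ord, labels = labels,
       n_alleles = lengths(labels))
}

freq_tibble <- function(codes, f, n_alleles, labels) {
  tibble::tibble(
    haplotype = vapply(codes, function(code)
      hap_label(decode_hap(code, n_alleles), labels), character(1)),
    code = codes,
    frequency = f
  ) |> dplyr::arrange(.data$code)
}

#' EM estimation of multilocus haplotype frequencies
#'
#' Maximizes the multinomial phase-ambiguity likelihood of unphased genotypes
#' over a marker subset. Individuals with missing calls contribute through all
#' compatible completions rather than being excluded. Initialization is the
#' deterministic product of single-marker allele frequencies; the seed matters
#' only when random restarts are requested.
#'
#' With `prior` supplied (training-set mode) the frequencies are fixed to the
#' prior and never re-estimated — only the likelihood and the per-individual
#' explanations change, mirroring a training cohort used to stabilize rare
#' haplotypes in small subsamples.
#'
#' @param x A [cohort()].
#' @param marker_ids Markers defining the haplotype (panel order enforced).
#' @param individual_ids Subset of individuals (default all). Founder-only
#'   estimation is obtained by passing the founder ids; the default pools all
#'   individuals as in case+reference pooled estimation.
#' @param prior Optional `hap_freq` object whose frequencies are held fixed.
#' @param tol,max_iter Convergence controls.
#' @param seed,n_restarts Optional random restarts (default none).
#' @return A `hap_freq` object: tibble of haplotypes and frequencies plus
#'   `log_likelihood`, `n_chromosomes`, `converged`, `iterations`.
#' @export
em_haplotype_frequencies <- function(x, marker_ids, individual_ids = NULL,
                                     prior = NULL, tol = 1e-8, max_iter = 1000,
                                     seed = NULL, n_restarts = 0) {
  sg <- subset_geno(x, marker_ids, individual_ids)
  n_inf <- sum(rowSums(!is.na(sg$gm$a1)) > 0)
  if (n_inf < 1) stop("no individual with a non-missing genotype over the marker set")
  prior_f <- NULL
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "hap_freq"),
              identical(prior$marker_ids, sg$marker_ids))
    prior_f <- list(codes = prior$table$code, f = prior$table$frequency)
  }
  fit <- em_core(sg$gm, sg$n_alleles, tol = tol, max_iter = max_iter,
                 prior_f = prior_f, seed = seed, n_restarts = n_restarts)
  structure(list(
    marker_ids = sg$marker_ids,
    allele_labels = sg$labels,
    n_alleles = sg$n_alleles,
    table = freq_tibble(fit$st$hap_codes, fit$f, sg$n_alleles, sg$labels),
    log_likelihood = fit$ll,
    n_chromosomes = 2 * nrow(sg$gm$a1),
    converged = fit$converged,
    iterations = fit$iterations
  ), class = "hap_freq")
}

#' @export
print.hap_freq <- function(x, ...) {
  cat("<hap_freq> ", paste(x$marker_ids, collapse = "-"),
      "  LL = ", format(x$log_likelihood, digits = 6),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  print(dplyr::arrange(x$table[x$table$frequency > 0, c("haplotype", "frequency")],
                       dplyr::desc(.data$frequency)))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy hap_freq
#' @export
tidy.hap_freq <- function(x, ...) {
  dplyr::mutate(x$table[, c("haplotype", "frequency")],
                markers = paste(x$marker_ids, collapse = "-"), .before = 1)
}

#' @rdname tidiers
#' @method glance hap_freq
#' @export
glance.hap_freq <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 n_chromosomes = x$n_chromosomes,
                 n_haplotypes = nrow(x$table),
                 converged = x$converged, iterations = x$iterations)
}

#' Weighted haplotype explanation lists
#'
#' For each individual, every genotype-compatible unordered haplotype pair
#' (h1, h2) is weighted proportionally to f(h1) f(h2), doubled for
#' heterozygous pairs, and normalized to sum to one. Individuals incompatible
#' with every positive-frequency haplotype fall back to uniform weights over
#' their compatible pairs, with a warning.
#'
#' @param x A [cohort()].
#' @param freq_table A `hap_freq` from [em_haplotype_frequencies()].
#' @param individual_ids Subset of individuals (default all).
#' @return Tibble: `individual_id`, `hap1`, `hap2`, `weight`.
#' @export
explanation_lists <- function(x, freq_table, individual_ids = NULL) {
  stopifnot(inherits(freq_table, "hap_freq"))
  sg <- subset_geno(x, freq_table$marker_ids, individual_ids)
  st <- build_classes(sg$gm, sg$n_alleles)
  f <- numeric(length(st$hap_codes))
  hit <- match(st$hap_codes, freq_table$table$code)
  f[!is.na(hit)] <- freq_table$table$frequency[hit[!is.na(hit)]]
  es <- e_step(f, st)
  if (es$any_zero) {
    warning("individual(s) incompatible with all positive-frequency haplotypes; ",
            "uniform weights used")
  }
  ids <- rownames(sg$gm$a1)
  lab <- vapply(st$hap_codes, function(code)
    hap_label(decode_hap(code, sg$n_alleles), sg$labels), character(1))
  purrr::map_dfr(seq_along(ids), function(i) {
    sel <- st$cls == st$class_of[i]
    tibble::tibble(individual_id = ids[i],
                   hap1 = lab[st$p1[sel]], hap2 = lab[st$p2[sel]],
                   weight = es$post[sel]) |>
      dplyr::filter(.data$weight > 0)
  })
}

#' Allele frequencies and informative-marker selection
#'
#' A marker is informative when its minor allele frequency exceeds the
#' threshold strictly, with MAF defined as one minus the frequency of the most
#' common allele (which extends naturally to microsatellites).
#'
#' @param x A [cohort()].
#' @param maf_threshold Strict lower bound on MAF (default 0.4).
#' @param individual_ids Subset used for the frequency estimates.
#' @return Character vector of informative marker ids, in panel order.
#' @export
informative_markers <- function(x, maf_threshold = 0.4, individual_ids = NULL) {
  af <- allele_frequencies(x, individual_ids)
  keep <- af |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(maf = 1 - max(.data$frequency), .groups = "drop") |>
    dplyr::filter(.data$maf > maf_threshold)
  x$markers$id[x$markers$id %in% keep$marker_id]
}

#' @rdname informative_markers
#' @return `allele_frequencies()`: tibble of `marker_id`, `allele`, `frequency`.
#' @export
allele_frequencies <- function(x, individual_ids = NULL) {
  stopifnot(inherits(x, "cohort"))
  gm <- genotype_matrix(x, individual_ids = individual_ids)
  purrr::map_dfr(seq_len(nrow(x$markers)), function(m) {
    a <- c(gm$a1[, m], gm$a2[, m])
    a <- a[!is.na(a)]
    labs <- x$markers$alleles[[m]]
    n <- if (length(a)) tabulate(a, length(labs)) else rep(0L, length(labs))
    tibble::tibble(marker_id = x$markers$id[m], allele = labs,
                   frequency = if (sum(n) > 0) n / sum(n) else rep(NA_real_, length(labs)))
  })
}

# Reduce a marker to major-allele-vs-other coding when multiallelic.
reduce_biallelic <- function(col_a1, col_a2, n_allele) {
  if (n_allele <= 2) return(list(a1 = col_a1, a2 = col_a2, k = max(2L, n_allele)))
  a <- c(col_a1, col_a2)
  cnt <- tabulate(a[!is.na(a)], n_allele)
  major <- which.max(cnt)
  list(a1 = ifelse(is.na(col_a1), NA_integer_, ifelse(col_a1 == major, 1L, 2L)),
       a2 = ifelse(is.na(col_a2), NA_integer_, ifelse(col_a2 == major, 1L, 2L)),
       k = 2L)
}

#' Pairwise linkage disequilibrium D and D'
#'
#' Two-marker haplotype frequencies are estimated by EM; multiallelic markers
#' are reduced to major-allele-vs-other. D is computed for the (1,1) allele
#' combination and D' = |D| / Dmax with the usual sign-dependent Dmax.
#'
#' @param x A [cohort()].
#' @param marker_a,marker_b Marker ids.
#' @param individual_ids Subset used for estimation.
#' @return One-row tibble: `marker_a`, `marker_b`, `D`, `D_prime`, `maf_a`,
#'   `maf_b`.
#' @export
d_prime <- function(x, marker_a, marker_b, individual_ids = NULL) {
  sg <- subset_geno(x, c(marker_a, marker_b), individual_ids)
  r1 <- reduce_biallelic(sg$gm$a1[, 1], sg$gm$a2[, 1], sg$n_alleles[1])
  r2 <- reduce_biallelic(sg$gm$a1[, 2], sg$gm$a2[, 2], sg$n_alleles[2])
  gm <- list(a1 = cbind(r1$a1, r2$a1), a2 = cbind(r1$a2, r2$a2))
  fit <- em_core(gm, c(r1$k, r2$k))
  f <- numeric(r1$k * r2$k)
  f[fit$st$hap_codes] <- fit$f
  # codes: (a-1)*k2 + b with k=2 after reduction -> AB=1, Ab=2, aB=3, ab=4
  p_ab <- f[1]
  p_a <- f[1] + f[2]
  p_b <- f[1] + f[3]
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("monomorphic marker: D' undefined for ",
         if (p_a %in% c(0, 1)) sg$marker_ids[1] else sg$marker_ids[2])
  }
  D <- p_ab - p_a * p_b
  dmax <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  tibble::tibble(marker_a = sg$marker_ids[1], marker_b = sg$marker_ids[2],
                 D = D, D_prime = if (D == 0) 0 else abs(D) / dmax,
                 maf_a = min(p_a, 1 - p_a), maf_b = min(p_b, 1 - p_b))
}

#' Haplotype blocks from adjacent-marker D'
#'
#' Adjacent markers (in panel order) whose pairwise D' exceeds the threshold
#' are chained into one block.
#'
#' @param x A [cohort()].
#' @param marker_ids Markers considered (default: informative markers).
#' @param threshold Strict D' threshold (default 0.8).
#' @param individual_ids Subset used for estimation.
#' @return Tibble of blocks: `block`, `chrom`, `start`, `end`, `markers`
#'   (list column), `n_markers`.
#' @export
define_blocks <- function(x, marker_ids = NULL, threshold = 0.8,
                          individual_ids = NULL) {
  if (is.null(marker_ids)) marker_ids <- informative_markers(x)
  marker_ids <- x$markers$id[x$markers$id %in% marker_ids]
  if (length(marker_ids) < 1) stop("no markers to block")
  joined <- logical(max(0, length(marker_ids) - 1))
  for (i in seq_along(joined)) {
    ld <- d_prime(x, marker_ids[i], marker_ids[i + 1], individual_ids)
    joined[i] <- ld$D_prime > threshold
  }
  block_id <- cumsum(c(1, !joined))
  pos <- x$markers$position[match(marker_ids, x$markers$id)]
  chrom <- x$markers$chrom[match(marker_ids, x$markers$id)]
  tibble::tibble(marker = marker_ids, block = block_id,
                 position = pos, chrom = chrom) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$position), end = max(.data$position),
                     markers = list(.data$marker),
                     n_markers = dplyr::n(), .groups = "drop")
}
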