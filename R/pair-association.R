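# Run an expression with a temporary RNG state derived from `seed`,
# restoring the caller's stream afterwards.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

# Precompute the genotype-class structure for a marker combination over a
# fixed individual roster, plus the pooled EM fit (pooled frequencies are
# label-invariant, so they are estimated exactly once per combination).
prep_lr <- function(x, marker_ids, individual_ids, tol = 1e-8, max_iter = 1000) {
  sg <- subset_geno(x, marker_ids, individual_ids)
  st <- build_classes(sg$gm, sg$n_alleles)
  f0 <- init_freq(sg$gm, sg$n_alleles, st)
  pooled <- em_run(st, st$counts, f0, tol = tol, max_iter = max_iter)
  mono <- vapply(seq_len(ncol(sg$gm$a1)), function(j) {
    a <- c(sg$gm$a1[, j], sg$gm$a2[, j])
    length(unique(a[!is.na(a)])) < 2
  }, logical(1))
  list(sg = sg, st = st, pooled = pooled, ids = rownames(sg$gm$a1),
       monomorphic = any(mono), tol = tol, max_iter = max_iter)
}

# Likelihood-ratio statistic for a 2-group split given a prepared structure.
# Group EMs start from the pooled estimate (deterministic, and already a
# stationary point of the pooled problem).
lr_from_split <- function(prep, idx1, idx2) {
  if (prep$monomorphic) return(0)
  c1 <- tabulate(prep$st$class_of[idx1], prep$st$n_classes)
  c2 <- tabulate(prep$st$class_of[idx2], prep$st$n_classes)
  f0 <- pmax(prep$pooled$f, 1e-12)
  f0 <- f0 / sum(f0)
  fit1 <- em_run(prep$st, c1, f0, tol = prep$tol, max_iter = prep$max_iter)
  fit2 <- em_run(prep$st, c2, f0, tol = prep$tol, max_iter = prep$max_iter)
  pooled_ll <- e_step(prep$pooled$f, prep$st, c1 + c2)$ll
  max(0, 2 * (fit1$ll + fit2$ll - pooled_ll))
}

#' Likelihood-ratio haplotype statistic between two groups
#'
#' `2 (LL1 + LL2 - LLpooled)` where each log-likelihood is maximized by EM
#' over the multinomial phase-ambiguity model. Significance is always
#' assessed by permutation in this package, so no chi-square calibration of
#' the statistic is assumed. A marker monomorphic in the pooled data yields
#' statistic 0 with a warning.
#'
#' @param x A [cohort()].
#' @param group1_ids,group2_ids Individual ids of the two contrasted groups.
#' @param marker_ids Marker combination defining the haplotypes.
#' @return A single non-negative number.
#' @export
lr_statistic <- function(x, group1_ids, group2_ids, marker_ids) {
  if (length(group1_ids) == 0 || length(group2_ids) == 0) {
    stop("both groups must be non-empty")
  }
  ids <- c(group1_ids, group2_ids)
  prep <- prep_lr(x, marker_ids, ids)
  if (prep$monomorphic) {
    warning("marker monomorphic in pooled data; statistic is 0")
    return(0)
  }
  lr_from_split(prep, match(group1_ids, prep$ids), match(group2_ids, prep$ids))
}

# Normalize the pair table for the two permutation schemes.
check_pairs <- function(pairs, scheme) {
  pairs <- tibble::as_tibble(pairs)
  if (scheme == "group_flip") {
    stopifnot(all(c("sib1_id", "sib2_id", "group") %in% names(pairs)))
    lev <- sort(unique(pairs$group))
    if (length(lev) != 2) stop("group_flip needs exactly two group labels")
    if (min(table(pairs$group)) < 2) stop("need >= 2 pairs per group")
    lev
  } else if (scheme == "within_pair_swap") {
    stopifnot(all(c("mild_id", "severe_id") %in% names(pairs)))
    if (nrow(pairs) < 2) stop("need >= 2 discordant pairs")
    c("mild", "severe")
  } else stop("unknown scheme: ", scheme)
}

split_ids <- function(pairs, scheme, flip) {
  if (scheme == "group_flip") {
    lev <- sort(unique(pairs$group))
    g <- ifelse(flip, ifelse(pairs$group == lev[1], lev[2], lev[1]), pairs$group)
    list(g1 = c(pairs$sib1_id[g == lev[1]], pairs$sib2_id[g == lev[1]]),
         g2 = c(pairs$sib1_id[g == lev[2]], pairs$sib2_id[g == lev[2]]))
  } else {
    list(g1 = ifelse(flip, pairs$severe_id, pairs$mild_id),
         g2 = ifelse(flip, pairs$mild_id, pairs$severe_id))
  }
}

#' Pair-preserving permutation association over marker combinations
#'
#' Computes the likelihood-ratio statistic for each marker combination and a
#' permutation p-value under one of two pair-preserving relabelling schemes:
#'
#' * `group_flip` (interpair): each pair's group label flips with probability
#'   1/2, both siblings always moving together;
#' * `within_pair_swap` (intrapair): the mild/severe labels swap within each
#'   discordant pair independently with probability 1/2. Genotypes and pair
#'   membership are never touched, only labels.
#'
#' One sequence of relabellings (from `seed`) is shared by all combinations,
#' which is what makes the min-p multiple-testing correction coherent:
#' `p_corr(c)` is the add-one-adjusted fraction of permutations whose minimum
#' per-combination p-value is at most `p_raw(c)` (Westfall-Young style).
#' All p-values use the add-one estimator `(1 + #exceeding) / (1 + n_perm)`.
#'
#' @param x A [cohort()].
#' @param pairs Tibble of sibling pairs: `sib1_id`, `sib2_id`, `group` for
#'   `group_flip`; `mild_id`, `severe_id` for `within_pair_swap`.
#' @param combinations List of marker-id vectors (or one vector) to test.
#' @param scheme `"group_flip"` or `"within_pair_swap"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Mandatory RNG seed.
#' @param correct Compute min-p corrected p-values (default `TRUE` when more
#'   than one combination is tested).
#' @return A `hap_assoc` object; its `results` tibble has one row per
#'   combination with `statistic`, `p_raw`, `p_corr`, `n_perm`, `seed`, and
#'   `group_tables` holds the per-group haplotype frequency fits under the
#'   observed labels.
#' @export
haplotype_association <- function(x, pairs, combinations, scheme = "group_flip",
                                  n_perm = 1000, seed, correct = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for permutation runs")
  stopifnot(n_perm >= 1)
  if (!is.list(combinations)) combinations <- list(combinations)
  if (is.null(correct)) correct <- length(combinations) > 1
  check_pairs(pairs, scheme)
  n_pairs <- nrow(pairs)
  K <- length(combinations)

  obs_split <- split_ids(pairs, scheme, rep(FALSE, n_pairs))
  roster <- c(obs_split$g1, obs_split$g2)

  flips <- with_seed_local(seed,
    matrix(stats::runif(n_perm * n_pairs) < 0.5, n_perm, n_pairs))

  stat_obs <- numeric(K)
  S <- matrix(NA_real_, n_perm, K)
  group_tables <- vector("list", K)
  for (k in seq_len(K)) {
    prep <- prep_lr(x, combinations[[k]], roster)
    if (prep$monomorphic) {
      warning("combination ", k, ": marker monomorphic in pooled data; statistic 0")
    }
    stat_of <- function(flip) {
      sp <- split_ids(pairs, scheme, flip)
      lr_from_split(prep, match(sp$g1, prep$ids), match(sp$g2, prep$ids))
    }
    stat_obs[k] <- stat_of(rep(FALSE, n_pairs))
    S[, k] <- vapply(seq_len(n_perm), function(b) stat_of(flips[b, ]), numeric(1))
    group_tables[[k]] <- group_fits(x, prep, obs_split)
  }

  p_raw <- vapply(seq_len(K), function(k)
    (1 + sum(S[, k] >= stat_obs[k])) / (1 + n_perm), numeric(1))
  p_corr <- rep(NA_real_, K)
  if (correct) {
    p_perm <- apply(S, 2, function(col)
      (1 + (length(col) + 1 - rank(col, ties.method = "min"))) / (1 + n_perm))
    minp <- apply(p_perm, 1, min)
    p_corr <- vapply(seq_len(K), function(k)
      (1 + sum(minp <= p_raw[k])) / (1 + n_perm), numeric(1))
  }

  structure(list(
    results = tibble::tibble(
      combination = vapply(combinations, paste, character(1), collapse = "-"),
      marker_ids = combinations,
      statistic = stat_obs, p_raw = p_raw, p_corr = p_corr,
      n_perm = n_perm, seed = seed
    ),
    group_tables = group_tables,
    scheme = scheme, pairs = pairs, perm_stats = S
  ), class = "hap_assoc")
}

group_fits <- function(x, prep, sp) {
  mk <- prep$sg$marker_ids
  lapply(list(group1 = sp$g1, group2 = sp$g2), function(ids) {
    fit <- em_run(prep$st, tabulate(prep$st$class_of[match(ids, prep$ids)],
                                    prep$st$n_classes),
                  pmax(prep$pooled$f, 1e-12) / sum(pmax(prep$pooled$f, 1e-12)))
    freq_tibble(prep$st$hap_codes, fit$f, prep$sg$n_alleles, prep$sg$labels)
  })
}

#' @export
print.hap_assoc <- function(x, ...) {
  cat("<hap_assoc> scheme =", x$scheme, "\n")
  print(x$results[, c("combination", "statistic", "p_raw", "p_corr")])
  invisible(x)
}

#' Tidiers for sibhap result objects
#'
#' `tidy()` returns the per-term results as a tibble, `glance()` a one-row
#' model-level summary.
#'
#' @param x A fitted sibhap object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy hap_assoc
#' @export
tidy.hap_assoc <- function(x, ...) x$results

#' @rdname tidiers
#' @method glance hap_assoc
#' @export
glance.hap_assoc <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_pairs = nrow(x$pairs),
                 n_combinations = nrow(x$results),
                 n_perm = x$results$n_perm[1], seed = x$results$seed[1],
                 best_p_raw = min(x$results$p_raw))
}

#' Permutation p-value for a single marker combination
#'
#' Convenience wrapper around [haplotype_association()] for one combination.
#'
#' @inheritParams haplotype_association
#' @param marker_ids One marker-id vector.
#' @return The `hap_assoc` object (single-row results).
#' @export
permutation_pvalue <- function(x, pairs, marker_ids, scheme = "group_flip",
                               n_perm = 1000, seed) {
  haplotype_association(x, pairs, list(marker_ids), scheme = scheme,
                        n_perm = n_perm, seed = seed, correct = FALSE)
}

#' Transmission disequilibrium test
#'
#' Counts transmissions (`b`) and non-transmissions (`c`) of allele 1 from
#' heterozygous parents to affected offspring; `chi_square = (b - c)^2 /
#' (b + c)` with a 1-df p-value. When both parents and child are heterozygous
#' each parent contributes one transmission and one non-transmission.
#'
#' @param x A [cohort()].
#' @param marker A biallelic marker id.
#' @param affected_ids Ids of affected offspring (default: all offspring).
#' @return One-row tibble: `marker`, `b`, `c`, `chi_square`, `p`; statistic
#'   and p are `NA` (flagged undefined) when `b + c = 0`.
#' @export
tdt <- function(x, marker, affected_ids = NULL) {
  stopifnot(inherits(x, "cohort"))
  ma <- x$markers$alleles[[match(marker, x$markers$id)]]
  if (length(ma) != 2) stop("TDT requires a biallelic marker")
  if (is.null(affected_ids)) {
    affected_ids <- x$individuals$id[x$individuals$role == "offspring"]
  }
  gm <- genotype_matrix(x, marker)
  g1 <- gm$a1[, 1]; g2 <- gm$a2[, 1]
  ind <- x$individuals
  b <- 0L; cc <- 0L
  for (cid in affected_ids) {
    i <- match(cid, ind$id)
    fid <- ind$father_id[i]; mid <- ind$mother_id[i]
    if (is.na(fid) || is.na(mid)) next
    ch <- c(g1[cid], g2[cid])
    fa <- c(g1[fid], g2[fid]); mo <- c(g1[mid], g2[mid])
    if (anyNA(ch) || anyNA(fa) || anyNA(mo)) next
    fa_het <- fa[1] != fa[2]; mo_het <- mo[1] != mo[2]
    if (!fa_het && !mo_het) next
    if (fa_het && mo_het) {
      if (ch[1] != ch[2]) { b <- b + 1L; cc <- cc + 1L }        # one of each
      else if (ch[1] == 1L) b <- b + 2L else cc <- cc + 2L
    } else {
      het <- if (fa_het) fa else mo
      hom <- if (fa_het) mo else fa
      # the homozygous parent fixes its contribution; the het parent
      # transmitted whatever remains of the child genotype
      pos <- match(hom[1], ch)
      if (is.na(pos)) next  # Mendelian violation; flagged elsewhere
      rem <- ch[-pos]
      if (rem == 1L) b <- b + 1L else cc <- cc + 1L
    }
  }
  n <- b + cc
  chi <- if (n == 0) NA_real_ else (b - cc)^2 / n
  tibble::tibble(marker = marker, b = b, c = cc, chi_square = chi,
                 p = if (n == 0) NA_real_ else stats::pchisq(chi, 1, lower.tail = FALSE))
}

#' Localize an association signal from segment-wise p-values
#'
#' Genomic segments are spanned by adjacent informative markers; maximal runs
#' of consecutive significant segments are merged into candidate fragments
#' spanning their outermost markers.
#'
#' @param segments Tibble with `left`, `right` (marker ids of the segment
#'   ends, consecutive segments sharing `right`/`left`) and `p_raw`.
#' @param alpha Significance cutoff (default 0.05).
#' @return Tibble of fragments: `left`, `right`, `n_segments`, `min_p`;
#'   zero rows when nothing is significant.
#' @export
localize_signal <- function(segments, alpha = 0.05) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("left", "right", "p_raw") %in% names(segments)))
  sig <- segments$p_raw < alpha
  if (!any(sig)) {
    return(tibble::tibble(left = character(), right = character(),
                          n_segments = integer(), min_p = double()))
  }
  # a run continues while the next segment is both significant and adjacent
  run_id <- integer(nrow(segments))
  run <- 0L
  for (i in seq_len(nrow(segments))) {
    if (!sig[i]) { run_id[i] <- NA_integer_; next }
    if (i > 1 && sig[i - 1] && !is.na(run_id[i - 1]) &&
        segments$left[i] == segments$right[i - 1]) {
      run_id[i] <- run
    } else {
      run <- run + 1L
      run_id[i] <- run
    }
  }
  segments |>
    dplyr::mutate(.run = run_id) |>
    dplyr::filter(!is.na(.data$.run)) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(left = dplyr::first(.data$left),
                     right = dplyr::last(.data$right),
                     n_segments = dplyr::n(),
                     min_p = min(.data$p_raw), .groups = "drop") |>
    dplyr::select(-".run")
}
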