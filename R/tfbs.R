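#' Construct a position weight matrix
#'
#' A generic additive-score PWM: `matrix` holds one row per position and one
#' column per base (A, C, G, T); log-odds weights are the natural input but
#' any finite weights work — the scanner adds them and compares the sum to
#' `threshold`. No pseudocount logic lives here: matrices are inputs.
#'
#' @param factor Factor (transcription factor) name.
#' @param matrix Numeric matrix, positions x bases, colnames A/C/G/T.
#' @param threshold Minimum additive score for a hit.
#' @return A `pwm` object.
#' @export
pwm <- function(factor, matrix, threshold) {
  m <- as.matrix(matrix)
  if (is.null(colnames(m))) colnames(m) <- c("A", "C", "G", "T")
  stopifnot(ncol(m) >= 4, all(c("A", "C", "G", "T") %in% colnames(m)),
            all(is.finite(m)))
  structure(list(factor = factor, matrix = m, threshold = threshold),
            class = "pwm")
}

#' Read JASPAR-style plain-text matrices
#'
#' Accepts the four-row `A [ ... ]` count/weight layout with a `>name` header
#' per matrix.
#'
#' @param source File path or character vector of lines.
#' @param threshold_quantile Threshold set at this fraction of each matrix's
#'   maximum achievable score (default 0.8).
#' @return List of [pwm()] objects.
#' @export
read_jaspar <- function(source, threshold_quantile = 0.8) {
  lines <- read_text_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  purrr::map(seq_along(starts), function(i) {
    from <- starts[i] + 1
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    name <- sub("^>\\s*", "", lines[starts[i]])
    rows <- lines[from:to][1:4]
    vals <- lapply(rows, function(l) {
      base <- sub("^\\s*([ACGT]).*", "\\1", l)
      body <- trimws(gsub("\\[|\\]", " ", sub("^\\s*[ACGT]", "", l)))
      nums <- as.numeric(strsplit(body, "\\s+")[[1]])
      list(base = base, nums = nums)
    })
    m <- do.call(cbind, lapply(vals, `[[`, "nums"))
    colnames(m) <- vapply(vals, `[[`, character(1), "base")
    p <- pwm(name, m[, c("A", "C", "G", "T")], threshold = 0)
    p$threshold <- threshold_quantile * sum(apply(p$matrix, 1, max))
    p
  })
}

#' Scan a sequence window with a PWM
#'
#' All offsets on both strands where the additive position score reaches the
#' matrix threshold are reported. A site is identified by (factor, offset,
#' strand); minus-strand hits are scored on the reverse complement and their
#' offset refers to the plus-strand start of the matched stretch.
#'
#' @param window Sequence to scan (single string, ACGT alphabet).
#' @param p A [pwm()].
#' @param window_id Identifier carried into the hits (e.g. `"rs152731_T"`).
#' @return Tibble of hits: `window_id`, `factor`, `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(window, p, window_id = NA_character_) {
  stopifnot(inherits(p, "pwm"))
  L <- nchar(window)
  w <- nrow(p$matrix)
  bases <- strsplit(toupper(window), "")[[1]]
  if (!all(bases %in% colnames(p$matrix))) {
    stop("alphabet mismatch: window contains bases outside the PWM columns")
  }
  if (L < w) {
    return(tibble::tibble(window_id = character(), factor = character(),
                          offset = integer(), strand = character(),
                          score = double()))
  }
  score_at <- function(b, off) {
    sum(p$matrix[cbind(seq_len(w), match(b[off:(off + w - 1)], colnames(p$matrix)))])
  }
  offsets <- seq_len(L - w + 1)
  plus <- vapply(offsets, function(o) score_at(bases, o), numeric(1))
  rc <- strsplit(revcomp(window), "")[[1]]
  minus_rc <- vapply(offsets, function(o) score_at(rc, o), numeric(1))
  # map reverse-complement offsets back to plus-strand coordinates
  minus <- minus_rc[rev(seq_along(minus_rc))]
  hits <- dplyr::bind_rows(
    tibble::tibble(offset = offsets, strand = "+", score = plus),
    tibble::tibble(offset = offsets, strand = "-", score = minus)
  )
  hits <- hits[hits$score >= p$threshold, , drop = FALSE]
  tibble::tibble(window_id = window_id, factor = p$factor,
                 offset = hits$offset, strand = hits$strand, score = hits$score)
}

#' Allele-unique predicted binding sites per haplotype
#'
#' For each SNP, a (factor, offset, strand) site is unique to one haplotype
#' when it is predicted on that haplotype's allele window and absent from the
#' other allele's window. Counts are pooled over SNPs and compared with an
#' equal-distribution test.
#'
#' @param hits Tibble of PWM hits with columns `snp_id`, `allele`, `factor`,
#'   `offset`, `strand` (as from [scan_pwm()], with `window_id` split into
#'   `snp_id` and `allele`, or built directly).
#' @param haplotype_alleles Tibble mapping `snp_id` to the allele carried by
#'   each haplotype: columns `snp_id`, `discordance`, `concordance`.
#' @return An `allele_site_comparison` list: per-haplotype unique site
#'   tibbles, `k_discordance`, `k_concordance`, and `p_equal` from
#'   [equal_distribution_test()].
#' @export
allele_unique_sites <- function(hits, haplotype_alleles) {
  hits <- tibble::as_tibble(hits)
  stopifnot(all(c("snp_id", "allele", "factor", "offset", "strand") %in% names(hits)))
  ha <- tibble::as_tibble(haplotype_alleles)
  stopifnot(all(c("snp_id", "discordance", "concordance") %in% names(ha)))

  site_key <- function(d) paste(d$snp_id, d$factor, d$offset, d$strand)
  unique_for <- function(tag) {
    other <- if (tag == "discordance") "concordance" else "discordance"
    purrr::map_dfr(seq_len(nrow(ha)), function(i) {
      own <- hits[hits$snp_id == ha$snp_id[i] & hits$allele == ha[[tag]][i], ]
      oth <- hits[hits$snp_id == ha$snp_id[i] & hits$allele == ha[[other]][i], ]
      own[!(site_key(own) %in% site_key(oth)), , drop = FALSE]
    })
  }
  u_disc <- unique_for("discordance")
  u_conc <- unique_for("concordance")
  k1 <- nrow(u_conc); k2 <- nrow(u_disc)
  structure(list(
    unique_concordance = u_conc, unique_discordance = u_disc,
    k_concordance = k1, k_discordance = k2,
    p_equal = if (k1 + k2 >= 1) equal_distribution_test(k1, k2) else NA_real_
  ), class = "allele_site_comparison")
}

#' @export
print.allele_site_comparison <- function(x, ...) {
  cat("<allele_site_comparison> unique sites: concordance =", x$k_concordance,
      ", discordance =", x$k_discordance,
      "; equal-distribution p =", format(x$p_equal, digits = 3), "\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy allele_site_comparison
#' @export
tidy.allele_site_comparison <- function(x, ...) {
  tibble::tibble(haplotype = c("concordance", "discordance"),
                 k_unique = c(x$k_concordance, x$k_discordance),
                 p_equal = x$p_equal)
}

#' Two-sided test of equal site distribution between haplotypes
#'
#' Exact binomial test of `k1` successes in `k1 + k2` trials against
#' probability 1/2, two-sided by summing binomial point probabilities no
#' larger than the observed one. A chi-square variant (1 df, no continuity
#' correction) is available for sensitivity analysis.
#'
#' @param k1,k2 Site counts unique to each haplotype.
#' @param method `"binomial"` (exact, default) or `"chisq"`.
#' @return The two-sided p-value.
#' @export
equal_distribution_test <- function(k1, k2, method = c("binomial", "chisq")) {
  method <- match.arg(method)
  n <- k1 + k2
  if (n == 0) stop("k1 + k2 must be >= 1")
  if (method == "binomial") {
    stats::binom.test(k1, n, p = 0.5)$p.value
  } else {
    stats::prop.test(k1, n, p = 0.5, correct = FALSE)$p.value
  }
}
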