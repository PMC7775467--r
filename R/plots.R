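#' Plot association results along the region
#'
#' Points are -log10 raw permutation p-values of each tested marker
#' combination, placed at the midpoint of the combination's marker
#' positions; the corrected p-values overlay as open symbols when present.
#'
#' @param object A `hap_assoc` from [haplotype_association()].
#' @param cohort The [cohort()] the combinations refer to (for positions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hap_assoc
#' @export
autoplot.hap_assoc <- function(object, cohort = NULL, ...) {
  res <- object$results
  xpos <- if (!is.null(cohort)) {
    purrr::map_dbl(res$marker_ids, function(ids)
      mean(cohort$markers$position[match(ids, cohort$markers$id)]))
  } else seq_len(nrow(res))
  df <- dplyr::mutate(res, x = xpos)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p_raw))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = if (is.null(cohort)) "combination" else "position (bp)",
                  y = expression(-log[10]~p[raw]),
                  title = paste("Haplotype association,", object$scheme)) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$p_corr))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = -log10(.data$p_corr)),
                                 shape = 1)
  }
  p
}

#' Plot haplotype frequency estimates
#'
#' @param object A `hap_freq` from [em_haplotype_frequencies()].
#' @param min_frequency Hide haplotypes below this frequency (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hap_freq
#' @export
autoplot.hap_freq <- function(object, min_frequency = 0.01, ...) {
  df <- object$table[object$table$frequency >= min_frequency, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$haplotype, -.data$frequency),
    y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste(object$marker_ids, collapse = "-"),
                  y = "estimated frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot nested delta-delta-Ct values by experiment
#'
#' Shows all nine combinations per experiment, highlighting the unrelated
#' (index-matched) subset that enters the rank test.
#'
#' @param ddct A `ddct_result` from [ddct_nested()].
#' @return A ggplot object.
#' @export
plot_ddct <- function(ddct) {
  stopifnot(inherits(ddct, "ddct_result"))
  sub <- unrelated_subset(ddct)$subset
  key <- function(d) paste(d$experiment, d$case_replicate, d$ref_replicate)
  df <- dplyr::mutate(tibble::as_tibble(ddct),
                      unrelated = key(tibble::as_tibble(ddct)) %in% key(sub))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$ddct,
                                   colour = .data$unrelated)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = expression(Delta*Delta*Ct),
                  title = paste(attr(ddct, "treatment"), "-",
                                attr(ddct, "amplicon"))) +
    ggplot2::theme_minimal()
}
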