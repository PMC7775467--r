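#' Empirical centiles of a phenotype vector
#'
#' Centile = 100 x rank / n over the non-missing entries, with mean ranks for
#' ties, so a constant vector maps to a single shared centile. Centiles are
#' computed over the whole cohort (population centiles), never within family.
#'
#' @param values Numeric vector; `NA` in gives `NA` out.
#' @return Numeric vector of centiles in (0, 100].
#' @export
empirical_centiles <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing; centiles undefined")
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * rank(values[ok], ties.method = "average") / sum(ok)
  out
}

#' Classify a patient's severity from two phenotype centiles
#'
#' A patient is `severe` when both clinical parameters fall strictly below the
#' lower centile cut, `mild` when both lie strictly above the upper cut, and
#' `unclassified` otherwise (including boundary values and any missing
#' centile). Lower phenotype values are the worse outcome under this
#' convention, matching lung-function and weight-for-height centiles.
#'
#' @param centile1,centile2 Centiles (0-100) of the two clinical parameters.
#' @param low,high Centile cutpoints (defaults 25 and 75).
#' @return Character vector: `"mild"`, `"severe"` or `"unclassified"`.
#' @export
classify_patient <- function(centile1, centile2, low = 25, high = 75) {
  n <- max(length(centile1), length(centile2))
  centile1 <- rep_len(centile1, n); centile2 <- rep_len(centile2, n)
  miss <- is.na(centile1) | is.na(centile2)
  if (any(miss)) warning("missing centile(s): patient(s) left unclassified")
  out <- rep("unclassified", n)
  out[!miss & centile1 < low & centile2 < low] <- "severe"
  out[!miss & centile1 > high & centile2 > high] <- "mild"
  out
}

#' Classify a sibling pair from the two sibs' severity classes
#'
#' Symmetric in sib order; a pair with any unclassified sib is itself
#' unclassified and drops out of all contrasts.
#'
#' @param sev1,sev2 Severity classes from [classify_patient()].
#' @return `"concordant_mild"`, `"concordant_severe"`, `"discordant"` or
#'   `"unclassified"`.
#' @export
classify_pair <- function(sev1, sev2) {
  n <- max(length(sev1), length(sev2))
  sev1 <- rep_len(sev1, n); sev2 <- rep_len(sev2, n)
  out <- rep("unclassified", n)
  out[sev1 == "mild" & sev2 == "mild"] <- "concordant_mild"
  out[sev1 == "severe" & sev2 == "severe"] <- "concordant_severe"
  out[(sev1 == "mild" & sev2 == "severe") | (sev1 == "severe" & sev2 == "mild")] <-
    "discordant"
  out
}

#' Severity and pair classes for a cohort of sibling pairs
#'
#' Runs the centile -> severity -> pair-class cascade over a phenotype table.
#' Families with exactly two phenotyped sibs form one pair; larger sibships
#' contribute all within-family sib pairs.
#'
#' @param phenotypes Tibble with `id` plus two numeric phenotype columns.
#' @param individuals Tibble with `id`, `family_id`, `role` (pairs are formed
#'   among offspring; a family of only non-founders uses all members).
#' @param phenotype_cols Names of the two phenotype columns (default: the
#'   first two non-id numeric columns).
#' @param low,high Centile cutpoints passed to [classify_patient()].
#' @return List with `patients` (id, centiles, severity) and `pairs`
#'   (family_id, sib1_id, sib2_id, pair_class) tibbles.
#' @export
classify_cohort <- function(phenotypes, individuals, phenotype_cols = NULL,
                            low = 25, high = 75) {
  if (is.null(phenotype_cols)) {
    num <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
    phenotype_cols <- setdiff(num, "id")[1:2]
  }
  stopifnot(length(phenotype_cols) == 2, all(phenotype_cols %in% names(phenotypes)))
  patients <- phenotypes |>
    dplyr::select("id", dplyr::all_of(phenotype_cols)) |>
    dplyr::mutate(
      centile1 = empirical_centiles(.data[[phenotype_cols[1]]]),
      centile2 = empirical_centiles(.data[[phenotype_cols[2]]]),
      severity = suppressWarnings(
        classify_patient(.data$centile1, .data$centile2, low = low, high = high))
    )
  sibs <- individuals[individuals$role == "offspring", , drop = FALSE]
  if (nrow(sibs) == 0) sibs <- individuals
  sibs <- sibs[sibs$id %in% patients$id, , drop = FALSE]
  sev <- stats::setNames(patients$severity, patients$id)
  pairs <- sibs |>
    dplyr::group_by(.data$family_id) |>
    dplyr::reframe({
      ids <- sort(.data$id)
      if (length(ids) < 2) {
        tibble::tibble(sib1_id = character(), sib2_id = character())
      } else {
        cmb <- utils::combn(ids, 2)
        tibble::tibble(sib1_id = cmb[1, ], sib2_id = cmb[2, ])
      }
    }) |>
    dplyr::mutate(pair_class = classify_pair(sev[.data$sib1_id], sev[.data$sib2_id]))
  list(patients = patients, pairs = pairs)
}
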