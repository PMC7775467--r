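ct_conditions <- c("growth_control", "transfection_control",
                   "sirna_target", "sirna_scrambled")

#' Read a qPCR Ct table
#'
#' TSV with columns `experiment` (biological replicate), `replicate` (plate
#' within experiment), `condition` (one of growth_control,
#' transfection_control, sirna_target, sirna_scrambled), `amplicon`
#' (`target_wildtype`, `target_alternative` or `housekeeping`), `timepoint`,
#' `ct`, and optionally `tech_rep` for unaveraged technical duplicates.
#'
#' @param source File path or character vector of TSV lines.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(source) {
  tab <- readr::read_tsv(I(paste(read_text_lines(source), collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("experiment", "replicate", "condition", "amplicon", "ct") %in% names(tab)))
  if (any(!is.na(tab$ct) & tab$ct <= 0)) stop("Ct values must be positive")
  tab
}

#' Per-sample delta-Ct against the housekeeping amplicon
#'
#' Technical duplicates (rows sharing everything but `tech_rep`) are averaged
#' first; then `delta_ct = Ct[target] - Ct[housekeeping]` within each
#' (experiment, replicate, condition, timepoint) sample. Samples without a
#' housekeeping Ct are excluded with a warning.
#'
#' @param records Ct tibble as from [read_ct_table()].
#' @return Tibble: `experiment`, `replicate`, `condition`, `timepoint`,
#'   `amplicon` (target amplicons only), `delta_ct`.
#' @export
delta_ct <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"timepoint" %in% names(records)) records$timepoint <- 1
  avg <- records |>
    dplyr::group_by(.data$experiment, .data$replicate, .data$condition,
                    .data$timepoint, .data$amplicon) |>
    dplyr::summarise(ct = mean(.data$ct, na.rm = TRUE), .groups = "drop")
  wide <- avg |>
    tidyr::pivot_wider(names_from = "amplicon", values_from = "ct")
  if (!"housekeeping" %in% names(wide)) stop("no housekeeping amplicon present")
  targets <- setdiff(unique(avg$amplicon), "housekeeping")
  miss <- is.na(wide$housekeeping)
  if (any(miss)) {
    warning(sum(miss), " sample(s) without housekeeping Ct excluded")
    wide <- wide[!miss, , drop = FALSE]
  }
  purrr::map_dfr(targets, function(a) {
    out <- wide[!is.na(wide[[a]]), c("experiment", "replicate", "condition", "timepoint")]
    out$amplicon <- a
    out$delta_ct <- wide[[a]][!is.na(wide[[a]])] - wide$housekeeping[!is.na(wide[[a]])]
    out
  })
}

#' Nested delta-delta-Ct over all case x reference combinations
#'
#' Within each biological experiment, the three treatment plates are compared
#' to the three transfection-control plates in all nine combinations:
#' `ddct[i, j] = delta_ct[treatment, i] - delta_ct[control, j]`, each further
#' centred by the mean transfection-agent effect
#' `mean(delta_ct[growth] - delta_ct[transfection])` of the same experiment
#' (itself computed over its own nine combinations). For the transfection
#' agent itself (`treatment = "growth_control"`) no centring is applied.
#' Provenance (case and reference replicate indices) is retained so that the
#' unrelated-value rule can be applied downstream.
#'
#' Experiments are excluded (with a message) unless at least
#' `min_valid` replicates per condition are valid for the amplicon.
#'
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @param treatment Condition to contrast against the transfection control:
#'   `"sirna_target"`, `"sirna_scrambled"` or `"growth_control"`.
#' @param amplicon Target amplicon to analyse.
#' @param min_valid Minimum valid replicates per condition (default 2).
#' @return A `ddct_result`: tibble `experiment`, `case_replicate`,
#'   `ref_replicate`, `ddct`, plus attributes `treatment`, `amplicon`.
#' @export
ddct_nested <- function(dct, treatment, amplicon, min_valid = 2) {
  stopifnot(treatment %in% ct_conditions, treatment != "transfection_control")
  d <- dct[dct$amplicon == amplicon, , drop = FALSE]
  combos <- function(dd, cond_a, cond_b) {
    a <- dd[dd$condition == cond_a, c("replicate", "delta_ct")]
    b <- dd[dd$condition == cond_b, c("replicate", "delta_ct")]
    tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b))) |>
      dplyr::mutate(case_replicate = a$replicate[.data$i],
                    ref_replicate = b$replicate[.data$j],
                    ddct = a$delta_ct[.data$i] - b$delta_ct[.data$j]) |>
      dplyr::select(-"i", -"j")
  }
  out <- purrr::map_dfr(unique(d$experiment), function(ex) {
    dd <- d[d$experiment == ex, , drop = FALSE]
    need <- unique(c(treatment, "transfection_control", "growth_control"))
    n_ok <- vapply(need, function(cn) sum(dd$condition == cn), integer(1))
    if (any(n_ok < min_valid)) {
      message("experiment ", ex, " excluded: fewer than ", min_valid,
              " valid replicates for ", paste(need[n_ok < min_valid], collapse = ", "))
      return(NULL)
    }
    dh <- combos(dd, "growth_control", "transfection_control")
    base <- combos(dd, treatment, "transfection_control")
    centre <- if (treatment == "growth_control") 0 else mean(dh$ddct)
    dplyr::mutate(base, experiment = ex, ddct = .data$ddct - centre,
                  .before = 1)
  })
  structure(out, class = c("ddct_result", class(out)),
            treatment = treatment, amplicon = amplicon)
}

#' Unrelated-value subset and signed-rank test
#'
#' From each experiment's nine delta-delta-Ct combinations, keeps a perfect
#' matching that shares no case or reference replicate (deterministically the
#' index-matched diagonal: case_i vs ref_i; a seeded random matching is
#' available to show the conclusion does not depend on that choice). The
#' pooled unrelated values across experiments go into a two-sided Wilcoxon
#' signed-rank test against zero, exact for n <= 25.
#'
#' @param ddct A `ddct_result` from [ddct_nested()].
#' @param matching `"index"` (deterministic, default) or `"random"`.
#' @param seed Seed for `matching = "random"`.
#' @return List: `subset` (tibble of retained combinations), `p_value`,
#'   `direction` (sign of the median), `n`.
#' @export
unrelated_subset <- function(ddct, matching = c("index", "random"), seed = NULL) {
  matching <- match.arg(matching)
  stopifnot(inherits(ddct, "ddct_result"))
  pick <- purrr::map_dfr(unique(ddct$experiment), function(ex) {
    dd <- ddct[ddct$experiment == ex, , drop = FALSE]
    cases <- sort(unique(dd$case_replicate))
    refs <- sort(unique(dd$ref_replicate))
    k <- min(length(cases), length(refs))
    if (k < length(cases) || k < length(refs)) {
      warning("experiment ", ex, ": incomplete design, matching of size ", k)
    }
    perm <- if (matching == "random") {
      if (is.null(seed)) stop("seed required for random matching")
      with_seed_local(seed + match(ex, unique(ddct$experiment)), sample(k))
    } else seq_len(k)
    dplyr::filter(dd, paste(.data$case_replicate, .data$ref_replicate) %in%
                    paste(cases[seq_len(k)], refs[perm]))
  })
  # the matching never reuses a replicate on either side
  chk <- pick |> dplyr::group_by(.data$experiment) |>
    dplyr::summarise(ok = !anyDuplicated(.data$case_replicate) &&
                       !anyDuplicated(.data$ref_replicate), .groups = "drop")
  stopifnot(all(chk$ok))
  n <- nrow(pick)
  p <- if (n == 0) NA_real_ else if (all(pick$ddct == 0)) 1 else
    suppressWarnings(stats::wilcox.test(pick$ddct, mu = 0, exact = n <= 25)$p.value)
  list(subset = pick, p_value = p,
       direction = sign(stats::median(pick$ddct)), n = n)
}

#' Compare normalized gel-shift band intensities between probe alleles
#'
#' Within each experiment the specific-antibody signal is normalized by its
#' paired isotype-control signal (ratio); experiments with a missing or zero
#' isotype pair are excluded. The normalized C-allele and T-allele sets are
#' compared by an exact two-sided Mann-Whitney U test.
#'
#' @param intensities Tibble: `experiment_id`, `allele`, `antibody`
#'   (`"specific"` or `"isotype_control"`), `intensity`.
#' @param alleles The two allele labels to contrast (default `c("C", "T")`).
#' @return List: `normalized` tibble (`experiment_id`, `allele`,
#'   `normalized`), `p_value`, `n_per_allele`.
#' @export
compare_band_intensities <- function(intensities, alleles = c("C", "T")) {
  intensities <- tibble::as_tibble(intensities)
  stopifnot(all(c("experiment_id", "allele", "antibody", "intensity") %in%
                  names(intensities)),
            all(intensities$intensity >= 0, na.rm = TRUE))
  wide <- intensities |>
    dplyr::filter(.data$allele %in% alleles) |>
    tidyr::pivot_wider(names_from = "antibody", values_from = "intensity")
  if (!all(c("specific", "isotype_control") %in% names(wide))) {
    stop("need both specific and isotype_control intensities")
  }
  bad <- is.na(wide$specific) | is.na(wide$isotype_control) |
    wide$isotype_control == 0
  if (any(bad)) {
    warning(sum(bad), " experiment/allele pair(s) without usable isotype control excluded")
    wide <- wide[!bad, , drop = FALSE]
  }
  wide$normalized <- wide$specific / wide$isotype_control
  g1 <- wide$normalized[wide$allele == alleles[1]]
  g2 <- wide$normalized[wide$allele == alleles[2]]
  if (length(g1) < 3 || length(g2) < 3) stop("need >= 3 experiments per allele")
  p <- if (identical(sort(g1), sort(g2))) 1 else
    suppressWarnings(stats::wilcox.test(g1, g2, exact = TRUE)$p.value)
  list(normalized = wide[, c("experiment_id", "allele", "normalized")],
       p_value = p, n_per_allele = c(length(g1), length(g2)))
}
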