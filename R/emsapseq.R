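#' Convert a protein-identification score to a match probability
#'
#' Identification scores are defined as `-10 log10(P)`, `P` being the
#' probability that the match arose by chance, so `P = 10^(-score / 10)`.
#'
#' @param score Non-negative score(s).
#' @return Probabilities in (0, 1].
#' @export
score_to_probability <- function(score) {
  if (any(score < 0)) stop("scores must be non-negative")
  10^(-score / 10)
}

#' @rdname score_to_probability
#' @return `order_of_magnitude()`: `log10(P)` rounded to the nearest integer
#'   power, e.g. a score of 119 gives -12.
#' @export
order_of_magnitude <- function(score) round(-score / 10)

check_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "probe", "gel") %in% names(samples)))
  if (!"allele" %in% names(samples)) samples$allele <- NA_character_
  stopifnot(all(samples$gel %in% c("native", "denaturing")))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id(s)")
  samples
}

# Probe group: the two alleles of one SNP count as one probe; each control
# kind is its own group.
probe_group <- function(samples) samples$probe

#' Presence/absence matrix of protein identifications
#'
#' @param hits Tibble of identifications: `sample_id`, `protein_id` (extra
#'   columns such as `mascot_score`, `n_peptides` are allowed and ignored).
#' @param samples Sample sheet: `sample_id`, `probe` (an SNP id,
#'   `"empty_negative"` or `"consensus_probe"`), optional `allele`, and `gel`
#'   (`"native"` or `"denaturing"`).
#' @return Logical matrix, proteins x samples; `TRUE` iff at least one hit of
#'   that protein in that sample.
#' @export
presence_matrix <- function(hits, samples) {
  samples <- check_samples(samples)
  hits <- tibble::as_tibble(hits)
  stopifnot(all(c("sample_id", "protein_id") %in% names(hits)))
  orphan <- setdiff(hits$sample_id, samples$sample_id)
  if (length(orphan)) stop("hit(s) in unregistered sample(s): ",
                           paste(unique(orphan), collapse = ", "))
  prot <- sort(unique(hits$protein_id))
  m <- matrix(FALSE, length(prot), nrow(samples),
              dimnames = list(prot, samples$sample_id))
  m[cbind(match(hits$protein_id, prot), match(hits$sample_id, samples$sample_id))] <- TRUE
  m
}

#' Noise-filtering cascade for gel-shift mass-spectrometry candidates
#'
#' A protein identified in the target SNP's samples passes when it satisfies
#' all four criteria:
#' 1. absent from every empty negative control;
#' 2. absent from every (native-gel) sample of any other probe's SNP;
#' 3. reference abundance strictly below `ppm_cutoff` (unknown abundance
#'    fails, conservatively);
#' 4. annotated as nucleic-acid binding.
#'
#' Denaturing-gel samples lack the multiprotein complexes of native gels and
#' are excluded from criteria 1-2 by default. Per-criterion flags are always
#' reported, so a failing protein shows exactly which filters removed it.
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param samples The matching sample sheet.
#' @param abundance Tibble `protein_id`, `ppm`.
#' @param annotation Tibble `protein_id`, `nucleic_acid_binding`,
#'   `spliceosome_component` (logical).
#' @param target_snp The probe (SNP id) whose candidates are sought.
#' @param ppm_cutoff Strict upper bound on abundance (default 200 ppm).
#' @param include_denaturing Include denaturing-gel samples in criteria 1-2
#'   (default `FALSE`).
#' @return A `candidate_report` tibble: one row per protein seen in the
#'   target samples, per-criterion logical flags, and `candidate` (all four
#'   true).
#' @export
filter_candidates <- function(matrix, samples, abundance, annotation,
                              target_snp, ppm_cutoff = 200,
                              include_denaturing = FALSE) {
  samples <- check_samples(samples)
  stopifnot(identical(colnames(matrix), samples$sample_id))
  active <- samples$gel == "native" | include_denaturing

  tgt <- samples$probe == target_snp & active
  neg <- samples$probe == "empty_negative" & active
  oth <- !(samples$probe %in% c(target_snp, "empty_negative", "consensus_probe")) & active
  if (!any(tgt)) stop("no sample for target probe '", target_snp, "'")
  if (!any(neg)) stop("missing sample class: empty_negative")
  if (!any(oth)) stop("missing sample class: other-SNP probes")

  seen <- rownames(matrix)[rowSums(matrix[, tgt, drop = FALSE]) > 0]
  ppm <- stats::setNames(abundance$ppm, abundance$protein_id)[seen]
  nab <- stats::setNames(annotation$nucleic_acid_binding, annotation$protein_id)[seen]
  spl <- stats::setNames(annotation$spliceosome_component, annotation$protein_id)[seen]

  out <- tibble::tibble(
    snp_id = target_snp,
    protein_id = seen,
    pass_negative = rowSums(matrix[seen, neg, drop = FALSE]) == 0,
    pass_other_snp = rowSums(matrix[seen, oth, drop = FALSE]) == 0,
    pass_abundance = !is.na(ppm) & ppm < ppm_cutoff,
    pass_na_binding = !is.na(nab) & nab,
    ppm = unname(ppm),
    spliceosome_component = unname(!is.na(spl) & spl)
  )
  out$candidate <- out$pass_negative & out$pass_other_snp &
    out$pass_abundance & out$pass_na_binding
  class(out) <- c("candidate_report", class(out))
  out
}

#' Is a protein a unique signal of a single probe?
#'
#' `TRUE` iff the protein appears only in samples of exactly one probe group,
#' where the two allele lanes of one SNP form one group and each control kind
#' its own.
#'
#' @param protein_id Protein to query.
#' @param matrix Presence matrix from [presence_matrix()].
#' @param samples The matching sample sheet.
#' @return One-row tibble: `protein_id`, `unique`, `probe` (the owning probe,
#'   `NA` when not unique or never seen).
#' @export
unique_signal <- function(protein_id, matrix, samples) {
  samples <- check_samples(samples)
  stopifnot(identical(colnames(matrix), samples$sample_id))
  if (length(unique(probe_group(samples))) < 2) stop("need >= 2 distinct probes")
  if (!protein_id %in% rownames(matrix)) {
    return(tibble::tibble(protein_id = protein_id, unique = FALSE,
                          probe = NA_character_))
  }
  present <- matrix[protein_id, ]
  groups <- unique(probe_group(samples)[present])
  tibble::tibble(protein_id = protein_id,
                 unique = length(groups) == 1,
                 probe = if (length(groups) == 1) groups else NA_character_)
}

#' Flag spliceosome components in a candidate report
#'
#' Spliceosomal candidates are flagged as excluded from prioritization but
#' retained in the report (they may still be genuine binders; the flag only
#' removes them from the trans-candidate shortlist).
#'
#' @param report A `candidate_report` from [filter_candidates()].
#' @param annotation Tibble `protein_id`, `spliceosome_component`.
#' @return The report with an `excluded_spliceosome` column.
#' @export
flag_spliceosome <- function(report, annotation) {
  spl <- stats::setNames(annotation$spliceosome_component, annotation$protein_id)
  hit <- spl[report$protein_id]
  report$excluded_spliceosome <- !is.na(hit) & hit & report$candidate
  report
}

#' Read a minimal delimited protein-identification export
#'
#' Accepts a TSV with columns `sample`/`sample_id`, `accession`/`protein_id`,
#' `score`/`mascot_score`, `peptides`/`n_peptides`. Full vendor XML is out of
#' scope.
#'
#' @param source File path or character vector of TSV lines.
#' @return Tibble with canonical column names.
#' @export
read_protein_hits <- function(source) {
  tab <- readr::read_tsv(I(paste(read_text_lines(source), collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  ren <- c(sample = "sample_id", accession = "protein_id",
           score = "mascot_score", peptides = "n_peptides")
  for (nm in names(ren)) {
    if (nm %in% names(tab)) names(tab)[names(tab) == nm] <- ren[[nm]]
  }
  stopifnot(all(c("sample_id", "protein_id") %in% names(tab)))
  if ("mascot_score" %in% names(tab) && any(tab$mascot_score < 0)) {
    stop("negative identification score(s)")
  }
  if ("n_peptides" %in% names(tab) && any(tab$n_peptides < 1)) {
    stop("peptide count(s) < 1")
  }
  tab
}
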