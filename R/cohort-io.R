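#' Construct a cohort object
#'
#' A cohort bundles a marker panel, a pedigree and unphased genotype calls.
#' It is the substrate for every association stage: markers are kept ordered
#' by (chromosome, position), genotypes are stored as allele indices into each
#' marker's allele list, and phase is always treated as unknown (phase comes
#' from the EM stage, never from the input).
#'
#' @param markers Tibble with columns `id`, `chrom`, `position`, `alleles`
#'   (list column of character allele labels, >= 2 per marker) and `kind`
#'   (`"snp"` or `"microsatellite"`).
#' @param individuals Tibble with columns `id`, `family_id`, `father_id`,
#'   `mother_id` (both `NA` for founders) and `role` (`"founder"` or
#'   `"offspring"`).
#' @param genotypes Long tibble with columns `individual_id`, `marker_id`,
#'   `a1`, `a2` (1-based allele indices, both `NA` for a missing call).
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(markers, individuals, genotypes) {
  markers <- tibble::as_tibble(markers)
  individuals <- tibble::as_tibble(individuals)
  genotypes <- tibble::as_tibble(genotypes)

  stopifnot(
    all(c("id", "chrom", "position", "alleles", "kind") %in% names(markers)),
    all(c("id", "family_id", "father_id", "mother_id", "role") %in% names(individuals)),
    all(c("individual_id", "marker_id", "a1", "a2") %in% names(genotypes))
  )
  if (anyDuplicated(markers$id)) {
    stop("duplicate marker id(s): ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  }
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  if (any(markers$position <= 0)) stop("marker positions must be positive (1-based)")
  bad_alleles <- purrr::map_lgl(markers$alleles, function(a) {
    length(a) < 1 || anyDuplicated(a) > 0 || any(!nzchar(a))
  })
  if (any(bad_alleles)) {
    stop("marker(s) with empty or duplicated allele labels: ",
         paste(markers$id[bad_alleles], collapse = ", "))
  }

  markers <- dplyr::arrange(markers, .data$chrom, .data$position)

  if (!all(genotypes$marker_id %in% markers$id)) {
    stop("genotype(s) reference unknown marker(s): ",
         paste(setdiff(genotypes$marker_id, markers$id), collapse = ", "))
  }
  if (!all(genotypes$individual_id %in% individuals$id)) {
    stop("genotype(s) reference unknown individual(s): ",
         paste(setdiff(genotypes$individual_id, individuals$id), collapse = ", "))
  }
  # missing is all-or-nothing per call
  half <- xor(is.na(genotypes$a1), is.na(genotypes$a2))
  if (any(half)) stop("half-missing genotype call(s); missing must be all-or-nothing")
  n_alleles <- stats::setNames(lengths(markers$alleles), markers$id)
  idx_max <- n_alleles[genotypes$marker_id]
  bad <- !is.na(genotypes$a1) &
    (genotypes$a1 < 1 | genotypes$a2 < 1 | genotypes$a1 > idx_max | genotypes$a2 > idx_max)
  if (any(bad)) stop("allele index out of range for marker(s): ",
                     paste(unique(genotypes$marker_id[bad]), collapse = ", "))

  # offspring must reference two parents present in the family, or none
  offs <- individuals[individuals$role == "offspring", , drop = FALSE]
  if (nrow(offs) > 0) {
    has_both <- !is.na(offs$father_id) & !is.na(offs$mother_id)
    has_none <- is.na(offs$father_id) & is.na(offs$mother_id)
    if (any(!has_both & !has_none)) {
      stop("offspring with exactly one parent reference: ",
           paste(offs$id[!has_both & !has_none], collapse = ", "))
    }
    fam_of <- stats::setNames(individuals$family_id, individuals$id)
    for (i in which(has_both)) {
      pp <- c(offs$father_id[i], offs$mother_id[i])
      if (!all(pp %in% individuals$id) ||
          !all(fam_of[pp] == offs$family_id[i])) {
        stop("offspring ", offs$id[i], " references parents outside its family")
      }
    }
  }

  structure(
    list(markers = markers, individuals = individuals, genotypes = genotypes),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$individuals), " individuals in ",
      dplyr::n_distinct(x$individuals$family_id), " families, ",
      nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Extract unphased genotypes as paired allele-index matrices
#'
#' @param x A [cohort()].
#' @param marker_ids Markers to extract, in panel order if omitted.
#' @param individual_ids Individuals to extract (default: all, in pedigree order).
#' @return List with integer matrices `a1` and `a2` (individuals x markers,
#'   dimnames set), `NA` where the call is missing.
#' @export
genotype_matrix <- function(x, marker_ids = NULL, individual_ids = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(marker_ids)) marker_ids <- x$markers$id
  if (is.null(individual_ids)) individual_ids <- x$individuals$id
  miss <- setdiff(marker_ids, x$markers$id)
  if (length(miss)) stop("unknown marker(s): ", paste(miss, collapse = ", "))
  g <- x$genotypes[x$genotypes$marker_id %in% marker_ids &
                     x$genotypes$individual_id %in% individual_ids, , drop = FALSE]
  a1 <- matrix(NA_integer_, length(individual_ids), length(marker_ids),
               dimnames = list(individual_ids, marker_ids))
  a2 <- a1
  ii <- match(g$individual_id, individual_ids)
  jj <- match(g$marker_id, marker_ids)
  a1[cbind(ii, jj)] <- g$a1
  a2[cbind(ii, jj)] <- g$a2
  list(a1 = a1, a2 = a2)
}

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a LINKAGE-style PED/MAP pair into a cohort
#'
#' PED rows are `family id father mother sex phenotype` followed by two allele
#' columns per mapped marker; `0` codes a missing allele and missingness must
#' be all-or-nothing within a call. Allele labels are registered per marker in
#' order of first appearance, so integer-labelled microsatellites need no
#' special handling. MAP rows are `chrom id position` (a fourth column is read
#' as position with the third as genetic distance, as in classic LINKAGE maps).
#'
#' @param ped_source,map_source File paths or character vectors of lines.
#' @return A [cohort()] with markers ordered by (chrom, position).
#' @export
read_pedigree <- function(ped_source, map_source) {
  map_lines <- read_text_lines(map_source)
  map_tok <- split_ws(map_lines)
  map <- purrr::imap_dfr(map_tok, function(tok, i) {
    if (length(tok) < 3) stop("MAP line ", i, ": expected >= 3 columns")
    pos <- suppressWarnings(as.integer(tok[[length(tok)]]))
    if (is.na(pos)) stop("MAP line ", i, ": non-numeric position")
    tibble::tibble(chrom = tok[[1]], id = tok[[2]], position = pos)
  })

  ped_lines <- read_text_lines(ped_source)
  ped_tok <- split_ws(ped_lines)
  n_mark <- nrow(map)
  need <- 6L + 2L * n_mark
  alleles <- rep(list(character()), n_mark)

  ind_rows <- list(); gen_rows <- list()
  for (i in seq_along(ped_tok)) {
    tok <- ped_tok[[i]]
    if (length(tok) != need) {
      stop("PED line ", i, ": expected ", need, " columns, found ", length(tok))
    }
    fid <- tok[1]; iid <- tok[2]; fat <- tok[3]; mot <- tok[4]
    a <- tok[-(1:6)]
    ax <- a[seq(1, 2 * n_mark, by = 2)]
    bx <- a[seq(2, 2 * n_mark, by = 2)]
    i1 <- integer(n_mark); i2 <- integer(n_mark)
    for (m in seq_len(n_mark)) {
      for (al in c(ax[m], bx[m])) {
        if (al != "0" && !(al %in% alleles[[m]])) alleles[[m]] <- c(alleles[[m]], al)
      }
      if (xor(ax[m] == "0", bx[m] == "0")) {
        stop("PED line ", i, ", marker ", map$id[m], ": half-missing call")
      }
      i1[m] <- if (ax[m] == "0") NA_integer_ else match(ax[m], alleles[[m]])
      i2[m] <- if (bx[m] == "0") NA_integer_ else match(bx[m], alleles[[m]])
    }
    ind_rows[[i]] <- tibble::tibble(
      id = iid, family_id = fid,
      father_id = ifelse(fat == "0", NA_character_, fat),
      mother_id = ifelse(mot == "0", NA_character_, mot),
      sex = tok[5], phenotype = tok[6]
    )
    gen_rows[[i]] <- tibble::tibble(individual_id = iid, marker_id = map$id,
                                    a1 = i1, a2 = i2)
  }
  individuals <- dplyr::bind_rows(ind_rows)
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s) in PED: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  individuals$role <- ifelse(is.na(individuals$father_id) & is.na(individuals$mother_id),
                             "founder", "offspring")
  # pad monomorphic-with-missing markers so every marker keeps >= 1 allele label
  alleles <- purrr::map(alleles, function(a) if (length(a) == 0) "?" else a)
  markers <- tibble::tibble(
    id = map$id, chrom = map$chrom, position = map$position,
    alleles = alleles,
    kind = ifelse(purrr::map_lgl(alleles, ~ all(.x %in% c("A", "C", "G", "T", "?"))),
                  "snp", "microsatellite")
  )
  cohort(markers, individuals, dplyr::bind_rows(gen_rows))
}

#' Write a cohort as LINKAGE-style PED/MAP text
#'
#' @param x A [cohort()].
#' @param ped_path,map_path Output file paths.
#' @return Invisibly, a list of the two character vectors written.
#' @export
write_pedigree <- function(x, ped_path, map_path) {
  stopifnot(inherits(x, "cohort"))
  map_lines <- sprintf("%s %s %d", x$markers$chrom, x$markers$id, x$markers$position)
  gm <- genotype_matrix(x)
  labels <- x$markers$alleles
  ind <- x$individuals
  sex <- if ("sex" %in% names(ind)) ind$sex else rep("0", nrow(ind))
  phe <- if ("phenotype" %in% names(ind)) ind$phenotype else rep("0", nrow(ind))
  ped_lines <- vapply(seq_len(nrow(ind)), function(i) {
    cells <- character(2 * nrow(x$markers))
    for (m in seq_len(nrow(x$markers))) {
      a1 <- gm$a1[ind$id[i], m]; a2 <- gm$a2[ind$id[i], m]
      cells[2 * m - 1] <- if (is.na(a1)) "0" else labels[[m]][a1]
      cells[2 * m]     <- if (is.na(a2)) "0" else labels[[m]][a2]
    }
    paste(c(ind$family_id[i], ind$id[i],
            ifelse(is.na(ind$father_id[i]), "0", ind$father_id[i]),
            ifelse(is.na(ind$mother_id[i]), "0", ind$mother_id[i]),
            sex[i], phe[i], cells), collapse = " ")
  }, character(1))
  writeLines(ped_lines, ped_path)
  writeLines(map_lines, map_path)
  invisible(list(ped = ped_lines, map = map_lines))
}

#' Merge VCF genotypes onto a pedigree skeleton
#'
#' Reads GT fields only; phase separators (`|`) are deliberately ignored —
#' phase in this pipeline comes from EM estimation, never from the input.
#' Markers found in the VCF are appended to (or replace same-id members of)
#' the pedigree's panel.
#'
#' @param vcf_source Path to an uncompressed or gzipped VCF 4.x file.
#' @param pedigree A [cohort()] whose individual ids cover the VCF samples.
#' @return A [cohort()] with the VCF calls merged in.
#' @export
read_vcf_genotypes <- function(vcf_source, pedigree) {
  stopifnot(inherits(pedigree, "cohort"))
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- tibble::as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  unmatched <- setdiff(samples, pedigree$individuals$id)
  if (length(unmatched)) {
    stop("VCF sample(s) absent from pedigree: ", paste(unmatched, collapse = ", "))
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  new_markers <- tibble::tibble(
    id = ids, chrom = fix$CHROM, position = as.integer(fix$POS),
    alleles = purrr::map2(fix$REF, fix$ALT, function(r, a) {
      alt <- if (is.na(a) || a == ".") character() else strsplit(a, ",")[[1]]
      c(r, alt)
    }),
    kind = "snp"
  )
  calls <- purrr::map_dfr(seq_along(ids), function(k) {
    g <- gt[k, samples]
    parts <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    a1 <- suppressWarnings(as.integer(purrr::map_chr(parts, 1))) + 1L
    a2 <- suppressWarnings(as.integer(purrr::map_chr(parts, function(p)
      if (length(p) >= 2) p[[2]] else p[[1]]))) + 1L
    miss <- is.na(a1) | is.na(a2)
    tibble::tibble(individual_id = samples, marker_id = ids[k],
                   a1 = ifelse(miss, NA_integer_, a1),
                   a2 = ifelse(miss, NA_integer_, a2))
  })
  markers <- dplyr::bind_rows(
    pedigree$markers[!pedigree$markers$id %in% new_markers$id, , drop = FALSE],
    new_markers
  )
  genotypes <- dplyr::bind_rows(
    pedigree$genotypes[!pedigree$genotypes$marker_id %in% new_markers$id, , drop = FALSE],
    calls
  )
  cohort(markers, pedigree$individuals, genotypes)
}

#' Read a delimited phenotype table
#'
#' Expects a header row with an `id` column plus one or more named phenotypes.
#' Non-numeric cells (including empties) become missing values; rows are kept.
#'
#' @param source File path or character vector of TSV lines.
#' @return Tibble with one record per individual id.
#' @export
read_phenotypes <- function(source) {
  txt <- read_text_lines(source)
  tab <- readr::read_tsv(I(paste(txt, collapse = "\n")), col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"id" %in% names(tab)) stop("phenotype table needs an 'id' column")
  if (anyDuplicated(tab$id)) {
    stop("duplicate individual id(s) in phenotype table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  dplyr::mutate(tab, dplyr::across(-"id", ~ suppressWarnings(as.numeric(.x))))
}

#' Check Mendelian consistency of a cohort
#'
#' Violations are reported, never silently fixed: a child call is inconsistent
#' when no assignment of one allele from each parent can produce it.
#'
#' @param x A [cohort()].
#' @return Tibble of violations: `family_id`, `individual_id`, `marker_id`.
#' @export
mendelian_check <- function(x) {
  stopifnot(inherits(x, "cohort"))
  gm <- genotype_matrix(x)
  ind <- x$individuals
  out <- list()
  for (i in which(ind$role == "offspring")) {
    cid <- ind$id[i]; fid <- ind$father_id[i]; mid <- ind$mother_id[i]
    if (is.na(fid) || is.na(mid)) next
    for (m in seq_len(nrow(x$markers))) {
      c1 <- gm$a1[cid, m]; c2 <- gm$a2[cid, m]
      if (is.na(c1)) next
      ok_parent <- function(pid, allele) {
        p1 <- gm$a1[pid, m]; p2 <- gm$a2[pid, m]
        is.na(p1) || allele %in% c(p1, p2)
      }
      consistent <- (ok_parent(fid, c1) && ok_parent(mid, c2)) ||
        (ok_parent(fid, c2) && ok_parent(mid, c1))
      if (!consistent) {
        out[[length(out) + 1]] <- tibble::tibble(
          family_id = ind$family_id[i], individual_id = cid,
          marker_id = x$markers$id[m]
        )
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(family_id = character(), individual_id = character(),
                   marker_id = character())
}

# Accept either a file path or a character vector of lines.
read_text_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n")[[1]]
  } else {
    as.character(source)
  }
}
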