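#' Construct an allele matrix of resequenced haplotypes
#'
#' Rows are resequenced haplotypes tagged by their phenotype association
#' (discordance vs concordance), columns are variant positions, cells are
#' single-base allele labels. The matrix must be complete.
#'
#' @param alleles Character matrix (haplotype x position) with dimnames, or a
#'   data frame with one column per position.
#' @param association Character vector, one tag per row: `"discordance"` or
#'   `"concordance"`.
#' @return An `allele_matrix` object.
#' @export
allele_matrix <- function(alleles, association) {
  m <- as.matrix(alleles)
  stopifnot(is.character(m), nrow(m) == length(association))
  if (anyNA(m) || any(!nzchar(m))) stop("allele matrix must be complete")
  association <- match.arg(association, c("discordance", "concordance"),
                           several.ok = TRUE)
  if (is.null(colnames(m))) colnames(m) <- paste0("pos", seq_len(ncol(m)))
  structure(list(alleles = m, association = association), class = "allele_matrix")
}

#' Haplotype-divergent sites
#'
#' A position is divergent when every discordance-tagged haplotype's allele
#' differs from every concordance-tagged haplotype's allele there. The result
#' is invariant to row and column permutation of the matrix.
#'
#' @param x An [allele_matrix()].
#' @return Character vector of divergent position names, in column order.
#' @export
divergent_sites <- function(x) {
  stopifnot(inherits(x, "allele_matrix"))
  disc <- x$alleles[x$association == "discordance", , drop = FALSE]
  conc <- x$alleles[x$association == "concordance", , drop = FALSE]
  if (nrow(disc) == 0 || nrow(conc) == 0) {
    stop("both association tags must be present")
  }
  div <- vapply(seq_len(ncol(x$alleles)), function(j) {
    length(intersect(disc[, j], conc[, j])) == 0
  }, logical(1))
  colnames(x$alleles)[div]
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character vector of DNA sequences (ACGT alphabet).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

probe_from_reference <- function(reference, snp_position, allele, flank) {
  n <- nchar(reference)
  if (snp_position - flank < 1 || snp_position + flank > n) {
    stop("flank of ", flank, " bp exceeds the available sequence around position ",
         snp_position)
  }
  s <- substr(reference, snp_position - flank, snp_position + flank)
  substr(s, flank + 1, flank + 1) <- allele
  s
}

#' Build an allele-centred probe sequence
#'
#' Extracts an odd-length window from the reference, centred on the variant
#' position, and substitutes the requested allele at the centre (1-based
#' index `(length + 1) / 2`). Only the plus strand is generated;
#' double-stranded probes are presentationally covered by [revcomp()].
#'
#' @param reference Reference sequence (single string) containing the SNP.
#' @param snp_id Variant identifier carried through to the output.
#' @param snp_position 1-based position of the variant within `reference`.
#' @param allele Single base to place at the centre.
#' @param length Odd probe length (default 35, the classic EMSA probe size).
#' @return One-row tibble: `snp_id`, `allele`, `sequence`, `length`.
#' @export
build_probe <- function(reference, snp_id, snp_position, allele, length = 35) {
  stopifnot(length %% 2 == 1, nchar(allele) == 1)
  flank <- (length - 1) / 2
  tibble::tibble(snp_id = snp_id, allele = allele,
                 sequence = probe_from_reference(reference, snp_position, allele, flank),
                 length = length)
}

#' @rdname build_probe
#' @param flank Flanking bases on each side (default 20, giving a 41-base
#'   window for binding-site prediction).
#' @export
build_window <- function(reference, snp_id, snp_position, allele, flank = 20) {
  build_probe(reference, snp_id, snp_position, allele, length = 2 * flank + 1)
}

#' Write probe/window sequences as FASTA
#'
#' @param probes Tibble from [build_probe()] rows.
#' @param path Output file path.
#' @return Invisibly, the FASTA lines.
#' @export
write_probe_fasta <- function(probes, path) {
  lines <- as.vector(rbind(paste0(">", probes$snp_id, "_", probes$allele),
                           probes$sequence))
  writeLines(lines, path)
  invisible(lines)
}
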