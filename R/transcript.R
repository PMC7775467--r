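#' Construct a gene model
#'
#' Exons are 1-based inclusive genomic intervals, non-overlapping and sorted
#' 5' to 3' (i.e. descending genomic coordinates on the minus strand);
#' `cds_start` is the transcript coordinate of the first base of the start
#' codon.
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble/data frame with `start`, `end` (genomic, 1-based
#'   inclusive).
#' @param cds_start Transcript coordinate (1-based) of the start codon.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, strand, exons, cds_start) {
  exons <- tibble::as_tibble(exons)
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)),
            all(exons$start <= exons$end))
  g5 <- if (strand == "+") order(exons$start) else order(-exons$start)
  exons <- exons[g5, , drop = FALSE]
  sorted <- exons[order(exons$start), , drop = FALSE]
  if (nrow(sorted) > 1 && any(sorted$start[-1] <= sorted$end[-nrow(sorted)])) {
    stop("exons overlap")
  }
  tx_len <- sum(exons$end - exons$start + 1)
  stopifnot(cds_start >= 1, cds_start <= tx_len)
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start)),
            class = "gene_model")
}

#' Read a GFF3-like exon table into a gene model
#'
#' Expects tab-separated columns `seqid source type start end score strand
#' phase attributes`; rows with `type == "exon"` define the model and an
#' attribute `cds_start=<n>` (transcript coordinate) on any row sets the
#' start codon.
#'
#' @param source File path or character vector of GFF lines.
#' @param gene_id Identifier for the resulting model.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(source, gene_id = "gene") {
  lines <- read_text_lines(source)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  rows <- purrr::map_dfr(f, function(v) tibble::tibble(
    type = v[3], start = as.integer(v[4]), end = as.integer(v[5]),
    strand = v[7], attributes = v[9]))
  ex <- rows[rows$type == "exon", ]
  if (nrow(ex) == 0) stop("no exon rows")
  cds <- sub(".*cds_start=([0-9]+).*", "\\1", rows$attributes)
  cds <- suppressWarnings(as.integer(cds[grepl("cds_start=", rows$attributes)]))
  gene_model(gene_id, ex$strand[1], ex[, c("start", "end")],
             cds_start = if (length(cds)) cds[1] else 1L)
}

slice_genomic <- function(genome, start, end) {
  if (start < 1 || end > nchar(genome)) stop("exon coordinates out of range")
  substr(genome, start, end)
}

#' Splice a gene model against a genomic sequence
#'
#' Concatenates the exon sequences in 5'-to-3' transcript order; minus-strand
#' models are reverse-complemented exon-wise.
#'
#' @param model A [gene_model()].
#' @param genome Genomic sequence (single string) in plus-strand orientation.
#' @return The mRNA sequence (character scalar).
#' @export
splice <- function(model, genome) {
  stopifnot(inherits(model, "gene_model"))
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- slice_genomic(genome, model$exons$start[i], model$exons$end[i])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Read-through (intron-retention) transcript
#'
#' Splices exons 1..k normally, then continues straight into the genomic
#' sequence past exon k's 3' boundary for `retained` bases (default: to the
#' template end). With zero retention this degenerates to the plain splice of
#' exons 1..k. The retained stretch matches the genomic sequence base by
#' base, which is the defining signature of an exon read-through product.
#'
#' @param model A [gene_model()].
#' @param genome Genomic sequence (plus strand).
#' @param after_exon Exon index k (1 <= k < exon count) whose donor site is
#'   read through.
#' @param retained Number of intronic bases retained (default: to template
#'   end; biologically the 3' end of such transcripts is a parameter, not a
#'   claim).
#' @return The read-through mRNA sequence.
#' @export
readthrough_transcript <- function(model, genome, after_exon, retained = NULL) {
  stopifnot(inherits(model, "gene_model"))
  k <- after_exon
  if (k < 1 || k >= nrow(model$exons)) stop("after_exon out of range")
  head_model <- gene_model(model$gene_id, model$strand,
                           model$exons[seq_len(k), , drop = FALSE],
                           cds_start = min(model$cds_start,
                                           sum(model$exons$end[seq_len(k)] -
                                                 model$exons$start[seq_len(k)] + 1)))
  spliced <- splice(head_model, genome)
  if (model$strand == "+") {
    from <- model$exons$end[k] + 1
    avail <- nchar(genome) - from + 1
    keep <- if (is.null(retained)) avail else min(retained, avail)
    tail_seq <- if (keep > 0) substr(genome, from, from + keep - 1) else ""
  } else {
    to <- model$exons$start[k] - 1
    avail <- to
    keep <- if (is.null(retained)) avail else min(retained, avail)
    tail_seq <- if (keep > 0) revcomp(substr(genome, to - keep + 1, to)) else ""
  }
  paste0(spliced, tail_seq)
}

#' Translate a CDS until the first in-frame stop
#'
#' Standard genetic code. `junction` (a transcript coordinate, typically the
#' last base of the final spliced exon of a read-through transcript) splits
#' the protein into residues encoded before versus at/after the junction:
#' `residues_past_junction` counts complete codons whose first base lies at
#' or after it.
#'
#' @param mrna Transcript sequence.
#' @param cds_start 1-based transcript coordinate of the start codon.
#' @param junction Optional transcript coordinate marking an exon/intron
#'   border.
#' @return List: `protein` (residue string, stop excluded), `length`,
#'   `stop_found`, `residues_past_junction` (`NA` without a junction).
#' @export
translate_cds <- function(mrna, cds_start, junction = NULL) {
  stopifnot(cds_start >= 1, cds_start <= nchar(mrna))
  code <- Biostrings::GENETIC_CODE
  n <- nchar(mrna)
  aa <- character()
  stop_found <- FALSE
  past <- if (is.null(junction)) NA_integer_ else 0L
  pos <- cds_start
  while (pos + 2 <= n) {
    codon <- toupper(substr(mrna, pos, pos + 2))
    res <- unname(code[codon])
    if (is.na(res)) stop("non-ACGT codon at transcript position ", pos)
    if (res == "*") { stop_found <- TRUE; break }
    aa <- c(aa, res)
    if (!is.null(junction) && pos >= junction) past <- past + 1L
    pos <- pos + 3
  }
  list(protein = paste(aa, collapse = ""), length = length(aa),
       stop_found = stop_found, residues_past_junction = past)
}

#' Predicted amplicon size from a primer pair
#'
#' `reverse 3'-end coordinate - forward 5'-start coordinate + 1` on a shared
#' template, 1-based inclusive.
#'
#' @param forward_start,forward_end,reverse_start,reverse_end 1-based
#'   template coordinates of the two primers (forward must lie 5' of
#'   reverse).
#' @param template Optional template sequence; when given, coordinates are
#'   checked against its length.
#' @return Amplicon length in bp.
#' @export
amplicon_size <- function(forward_start, forward_end, reverse_start, reverse_end,
                          template = NULL) {
  stopifnot(forward_start <= forward_end, reverse_start <= reverse_end)
  if (!is.null(template)) {
    if (reverse_end > nchar(template) || forward_start < 1) {
      stop("primer coordinates outside the template")
    }
  }
  if (reverse_start <= forward_end) stop("reverse primer upstream of forward primer")
  reverse_end - forward_start + 1
}
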