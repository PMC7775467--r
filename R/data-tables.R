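#' Published allele matrix of Sanger-resequenced contrasting haplotypes
#'
#' The 18-position allele matrix observed on the resequenced 8-kb modifier
#' fragment: one haplotype associated with intrapair discordance (carried by
#' TTAGA homozygotes at the five mapping markers) and two associated with
#' concordance (GGAAT and GTCAT homozygotes). Running [divergent_sites()] on
#' it identifies the six SNPs at which the discordance-associated haplotype
#' differs from both concordance-associated ones.
#'
#' @return An [allele_matrix()] with rows TTAGA, GGAAT, GTCAT.
#' @export
resequencing_matrix <- function() {
  positions <- c("rs152730", "rs62029384", "rs8044970", "rs8044984",
                 "rs80443907", "rs152731", "rs152732", "rs180878", "rs152733",
                 "rs63982", "rs152745", "rs8062922", "rs152744", "rs62029385",
                 "rs152743", "rs152741", "rs57406669", "rs152740")
  m <- rbind(
    TTAGA = c("T", "C", "T", "T", "C", "T", "C", "T", "T",
              "A", "G", "C", "A", "C", "G", "C", "C", "A"),
    GGAAT = c("G", "T", "G", "G", "T", "C", "C", "T", "T",
              "A", "A", "T", "G", "T", "G", "T", "G", "T"),
    GTCAT = c("G", "C", "T", "T", "C", "C", "T", "G", "C",
              "C", "A", "C", "G", "C", "A", "T", "C", "T")
  )
  colnames(m) <- positions
  allele_matrix(m, c("discordance", "concordance", "concordance"))
}

#' Reported haplotype distribution among discordant and concordant pairs
#'
#' Frequencies of the five-marker haplotypes (rs152730-rs8044970-rs63982-
#' rs152745-rs152740) among 14 discordant and 23 concordant sibling pairs,
#' with rare haplotypes pooled. Useful as a qualitative yardstick for the
#' cis-by-trans simulator: the receptive haplotype TTAGA is strongly
#' overrepresented among discordant pairs.
#'
#' @return Tibble: `haplotype`, `freq_discordant`, `freq_concordant`.
#' @export
pair_haplotype_freqs <- function() {
  tibble::tibble(
    haplotype = c("TTAGA", "GTCAT", "GGAAT", "other"),
    freq_discordant = c(0.839, 0.051, 0.036, 0.074),
    freq_concordant = c(0.599, 0.185, 0.129, 0.087)
  )
}
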