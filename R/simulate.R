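#' Preset cis-locus panel
#'
#' Five-marker panel with a founder haplotype pool whose frequencies follow
#' the concordant-pair distribution reported for the fine-mapped modifier
#' fragment (0.599 / 0.185 / 0.129 for the three major haplotypes, remainder
#' split over two rare ones). The first haplotype of the pool is the
#' designated receptive haplotype.
#'
#' @return List with `markers` (tibble) and `haplotypes` (tibble of
#'   `haplotype`, `frequency`).
#' @export
cis_preset <- function() {
  markers <- tibble::tibble(
    id = c("rs152730", "rs8044970", "rs63982", "rs152745", "rs152740"),
    chrom = "16",
    position = c(23310000L, 23312000L, 23314000L, 23316000L, 23318000L),
    alleles = list(c("T", "G"), c("T", "G"), c("A", "C"), c("G", "A"), c("A", "T")),
    kind = "snp"
  )
  haplotypes <- tibble::tibble(
    haplotype = c("TTAGA", "GTCAT", "GGAAT", "GTAGT", "TTCAT"),
    frequency = c(0.599, 0.185, 0.129, 0.050, 0.037)
  )
  list(markers = markers, haplotypes = haplotypes)
}

#' Simulation parameters for the cis-by-trans cohort model
#'
#' The generative model: founders carry two cis haplotypes drawn from the
#' panel pool and two alleles at an unlinked trans locus; sibs inherit by
#' Mendelian transmission. Each phenotype is
#' `y_ip = mu - beta_cis * X_cis - beta_int * R * (X_trans - 2 f_trans) +
#' c_family + u_individual + e_ip`, where `X_cis` is the receptive-haplotype
#' dosage, `R` its phenotypic coding (`"additive"`, `dosage / 2`, by
#' default: a cis-regulatory element acts per chromosome copy; `"dominant"`
#' codes carrier status instead) and `X_trans` is the trans-allele dosage,
#' centred at its population mean `2 f_trans` because the two trans alleles
#' are functionally divergent: among receptive-haplotype carriers one allele
#' is protective and the other deleterious. Lower phenotype values are the
#' worse outcome, so positive effects worsen severity.
#'
#' The noise has three components, as in any sibling design: a family-shared
#' severity component `c_family` (shared environment, birth cohort, care),
#' an individual component `u_individual` shared by both clinical parameters
#' of one patient, and an independent per-phenotype error `e_ip`. The shared
#' components matter structurally: concordant pairs arise mainly through the
#' family component (and so carry cis haplotypes at about their population
#' frequency), while intrapair discordance cannot come from family-shared
#' variance — under a strong interaction it is dominated by receptive
#' carrier pairs whose sibs differ at the trans locus. That is the
#' receptive-haplotype enrichment among discordant pairs that the
#' association stage is designed to recover.
#'
#' @param seed Mandatory RNG seed.
#' @param n_families Number of nuclear families (default 318, the scale of
#'   the extreme-phenotype sib-pair study the model emulates).
#' @param sibs_per_family Sibs per family (default 2).
#' @param cis_panel Panel + founder haplotype pool (default [cis_preset()]).
#' @param trans_freq Frequency of the trans risk allele (default 0.5).
#' @param beta_cis Main cis effect (default 0).
#' @param beta_interaction Cis-by-trans interaction effect (default 3, a
#'   strong interaction relative to the noise components).
#' @param receptive_haplotype Designated receptive cis haplotype (default:
#'   first haplotype of the pool).
#' @param receptive_coding `"additive"` (default) or `"dominant"`.
#' @param noise_sd Per-phenotype error SD (> 0, default 0.6).
#' @param family_sd SD of the family-shared severity component (default 1.2).
#' @param indiv_sd SD of the individual component shared by both phenotypes
#'   (default 0.4).
#' @param mu Phenotype mean (default 0).
#' @param n_phenotypes Number of phenotypes (default 2).
#' @param n_filler Filler markers per side for LD structure (default 0).
#' @param filler_copy First-order copying probability controlling adjacent
#'   filler D' (default 0.9).
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed, n_families = 318, sibs_per_family = 2,
                       cis_panel = cis_preset(), trans_freq = 0.5,
                       beta_cis = 0, beta_interaction = 3,
                       receptive_haplotype = NULL,
                       receptive_coding = c("additive", "dominant"),
                       noise_sd = 0.6, family_sd = 1.2, indiv_sd = 0.4,
                       mu = 0, n_phenotypes = 2,
                       n_filler = 0, filler_copy = 0.9) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd > 0, family_sd >= 0, indiv_sd >= 0,
            n_families >= 1, sibs_per_family >= 1,
            trans_freq > 0, trans_freq < 1)
  f <- cis_panel$haplotypes$frequency
  if (abs(sum(f) - 1) > 1e-9 || any(f < 0)) stop("haplotype frequencies must sum to 1")
  if (any(f == 1)) stop("degenerate haplotype pool (a frequency of 1)")
  if (is.null(receptive_haplotype)) {
    receptive_haplotype <- cis_panel$haplotypes$haplotype[1]
  }
  stopifnot(receptive_haplotype %in% cis_panel$haplotypes$haplotype)
  list(seed = seed, n_families = n_families, sibs_per_family = sibs_per_family,
       cis_panel = cis_panel, trans_freq = trans_freq, beta_cis = beta_cis,
       beta_interaction = beta_interaction,
       receptive_haplotype = receptive_haplotype,
       receptive_coding = match.arg(receptive_coding),
       noise_sd = noise_sd, family_sd = family_sd, indiv_sd = indiv_sd,
       mu = mu, n_phenotypes = n_phenotypes,
       n_filler = n_filler, filler_copy = filler_copy)
}

#' Simulate a sibling-pair cohort under the cis-by-trans model
#'
#' @param params A [sim_params()] list.
#' @return List: `cohort` (a [cohort()] including the trans marker and any
#'   filler markers), `phenotypes` (tibble `id`, `pheno1`, ...), `truth`
#'   (per-individual receptive dosage, trans dosage, true haplotypes) and
#'   `manifest` (params, seed, content hash). Bit-identical for a given
#'   seed.
#' @export
simulate_cohort <- function(params) {
  with_seed_local(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  pool <- params$cis_panel$haplotypes
  markers <- params$cis_panel$markers
  hap_mat <- do.call(rbind, strsplit(pool$haplotype, ""))
  n_cis <- nrow(markers)
  n_fam <- params$n_families
  n_sib <- params$sibs_per_family

  draw_hap <- function(n) sample.int(nrow(pool), n, replace = TRUE, prob = pool$frequency)
  draw_trans <- function(n) ifelse(stats::runif(n) < params$trans_freq, 1L, 2L)

  rows_ind <- list(); hap_of <- list(); trans_of <- list()
  for (f in seq_len(n_fam)) {
    fam <- sprintf("F%03d", f)
    fa <- paste0(fam, "_1"); mo <- paste0(fam, "_2")
    sib_ids <- paste0(fam, "_", 2 + seq_len(n_sib))
    rows_ind[[f]] <- tibble::tibble(
      id = c(fa, mo, sib_ids), family_id = fam,
      father_id = c(NA, NA, rep(fa, n_sib)),
      mother_id = c(NA, NA, rep(mo, n_sib)),
      role = c("founder", "founder", rep("offspring", n_sib))
    )
    fh <- matrix(draw_hap(4), 2)       # founders x 2 haplotypes
    ft <- matrix(draw_trans(4), 2)     # founders x 2 trans alleles
    pick <- function(v) v[sample.int(2, 1)]
    sh <- t(vapply(seq_len(n_sib), function(s) c(pick(fh[1, ]), pick(fh[2, ])),
                   integer(2)))
    st <- t(vapply(seq_len(n_sib), function(s) c(pick(ft[1, ]), pick(ft[2, ])),
                   integer(2)))
    hap_of[[f]] <- rbind(fh, sh)
    trans_of[[f]] <- rbind(ft, st)
    rownames(hap_of[[f]]) <- rownames(trans_of[[f]]) <- c(fa, mo, sib_ids)
  }
  individuals <- dplyr::bind_rows(rows_ind)
  H <- do.call(rbind, hap_of)[individuals$id, , drop = FALSE]
  TR <- do.call(rbind, trans_of)[individuals$id, , drop = FALSE]

  # cis genotype calls: allele index of each haplotype at each marker
  allele_idx <- matrix(0L, nrow(pool), n_cis)
  for (m in seq_len(n_cis)) {
    allele_idx[, m] <- match(hap_mat[, m], markers$alleles[[m]])
  }
  gen <- purrr::map_dfr(seq_len(n_cis), function(m) tibble::tibble(
    individual_id = individuals$id, marker_id = markers$id[m],
    a1 = allele_idx[H[, 1], m], a2 = allele_idx[H[, 2], m]))

  trans_marker <- tibble::tibble(
    id = "trans1", chrom = "16", position = 68000000L,
    alleles = list(c("A", "G")), kind = "snp")
  gen_trans <- tibble::tibble(individual_id = individuals$id, marker_id = "trans1",
                              a1 = TR[, 1], a2 = TR[, 2])

  panel <- dplyr::bind_rows(markers, trans_marker)
  gen_all <- dplyr::bind_rows(gen, gen_trans)

  if (params$n_filler > 0) {
    fil <- filler_markers(params, individuals$id, H, hap_mat, markers)
    panel <- dplyr::bind_rows(panel, fil$markers)
    gen_all <- dplyr::bind_rows(gen_all, fil$genotypes)
  }

  cohort_obj <- cohort(panel, individuals, gen_all)

  receptive_idx <- match(params$receptive_haplotype, pool$haplotype)
  x_cis <- rowSums(H == receptive_idx)
  r <- if (params$receptive_coding == "dominant") as.numeric(x_cis >= 1) else x_cis / 2
  x_trans <- rowSums(TR == 1L)
  # trans dosage is centred at its population mean: among receptive-haplotype
  # carriers one trans allele is protective and the other deleterious
  # (functionally divergent alleles), so non-carriers and dosage-average
  # carriers sit in the middle of the phenotype distribution
  lin <- params$mu - params$beta_cis * x_cis -
    params$beta_interaction * r * (x_trans - 2 * params$trans_freq)
  fam_eff <- stats::rnorm(n_fam, 0, params$family_sd)
  shared <- lin + fam_eff[match(individuals$family_id, unique(individuals$family_id))] +
    stats::rnorm(length(lin), 0, params$indiv_sd)
  phen <- purrr::map_dfc(seq_len(params$n_phenotypes), function(p) {
    tibble::tibble(!!paste0("pheno", p) :=
                     shared + stats::rnorm(length(shared), 0, params$noise_sd))
  })
  phenotypes <- dplyr::bind_cols(tibble::tibble(id = individuals$id), phen)
  truth <- tibble::tibble(
    id = individuals$id,
    hap1 = pool$haplotype[H[, 1]], hap2 = pool$haplotype[H[, 2]],
    receptive_dosage = x_cis, trans_dosage = x_trans
  )
  out <- list(cohort = cohort_obj, phenotypes = phenotypes, truth = truth)
  out$manifest <- list(seed = params$seed,
                       params = params[setdiff(names(params), "cis_panel")],
                       hash = digest::digest(out))
  out
}

# First-order haplotype-copying filler markers flanking the cis panel: the
# first filler chromosome state copies the nearest cis allele, each further
# filler copies its neighbour with probability `filler_copy`, otherwise
# redraws at its own marginal frequency. Adjacent D' rises with filler_copy.
filler_markers <- function(params, ids, H, hap_mat, markers) {
  n <- length(ids)
  nf <- params$n_filler
  copy_p <- params$filler_copy
  anchor <- match(hap_mat[, 1], markers$alleles[[1]])  # allele idx at first marker
  state1 <- anchor[H[, 1]]; state2 <- anchor[H[, 2]]
  mk <- list(); gn <- list()
  for (k in seq_len(nf)) {
    redraw <- function(s) ifelse(stats::runif(n) < copy_p, s,
                                 ifelse(stats::runif(n) < 0.5, 1L, 2L))
    state1 <- redraw(state1); state2 <- redraw(state2)
    id <- sprintf("fill%02d", k)
    mk[[k]] <- tibble::tibble(id = id, chrom = "16",
                              position = 23308000L - 1000L * (nf - k + 1L),
                              alleles = list(c("A", "G")), kind = "snp")
    gn[[k]] <- tibble::tibble(individual_id = ids, marker_id = id,
                              a1 = state1, a2 = state2)
  }
  list(markers = dplyr::bind_rows(mk), genotypes = dplyr::bind_rows(gn))
}

#' Simulate a gel-shift mass-spectrometry experiment set
#'
#' Emits a 25-sample layout (three SNP probes x two alleles x three native
#' replicates, one consensus probe, three empty negative controls, three
#' denaturing-gel samples), background contaminants appearing across samples
#' with the stated dropout, and planted probe-specific binders that are
#' low-abundance, nucleic-acid-binding and confined to their own SNP's
#' samples. Background proteins occupy the complementary strata (abundant or
#' not nucleic-acid-binding), so the four-criterion filter separates planted
#' from background exactly.
#'
#' @param planted Tibble `protein_id`, `snp_id` of planted binders (default:
#'   one binder on the second SNP).
#' @param snps SNP probes (default the three assayed SNP ids).
#' @param n_background Number of background contaminant proteins.
#' @param dropout Per-sample probability that a background protein is missed.
#' @param seed Mandatory RNG seed.
#' @return List: `hits`, `samples`, `abundance`, `annotation`, `planted`,
#'   `manifest`.
#' @export
simulate_emsapseq <- function(planted = NULL,
                              snps = c("rs152730", "rs152731", "rs152744"),
                              n_background = 30, dropout = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(snps) >= 2)
  if (is.null(planted)) {
    planted <- tibble::tibble(protein_id = "BINDER1", snp_id = snps[2])
  }
  with_seed_local(seed, {
    samples <- dplyr::bind_rows(
      tidyr::expand_grid(snp = snps, allele = c("ref", "alt"), rep = 1:3) |>
        dplyr::transmute(sample_id = paste0(.data$snp, "_", .data$allele, "_", .data$rep),
                         probe = .data$snp, allele = .data$allele, gel = "native"),
      tibble::tibble(sample_id = "consensus_1", probe = "consensus_probe",
                     allele = NA_character_, gel = "native"),
      tibble::tibble(sample_id = paste0("neg_", 1:3), probe = "empty_negative",
                     allele = NA_character_, gel = "native"),
      tibble::tibble(sample_id = paste0("denat_", 1:3), probe = snps,
                     allele = "ref", gel = "denaturing")
    )
    bg_ids <- sprintf("BG%03d", seq_len(n_background))
    bg_hits <- purrr::map_dfr(bg_ids, function(p) {
      present <- stats::runif(nrow(samples)) > dropout
      tibble::tibble(sample_id = samples$sample_id[present], protein_id = p,
                     mascot_score = round(stats::runif(sum(present), 20, 80)),
                     n_peptides = sample.int(5, sum(present), replace = TRUE))
    })
    pl_hits <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      sel <- samples$probe == planted$snp_id[i] & samples$gel == "native"
      tibble::tibble(sample_id = samples$sample_id[sel],
                     protein_id = planted$protein_id[i],
                     mascot_score = round(stats::runif(sum(sel), 60, 150)),
                     n_peptides = sample.int(8, sum(sel), replace = TRUE) + 2L)
    })
    # background strata are disjoint from the planted stratum: abundant,
    # or rare but not nucleic-acid binding
    abundant <- stats::runif(n_background) < 0.5
    abundance <- dplyr::bind_rows(
      tibble::tibble(protein_id = bg_ids,
                     ppm = ifelse(abundant, stats::runif(n_background, 200, 5000),
                                  stats::runif(n_background, 1, 150))),
      tibble::tibble(protein_id = planted$protein_id,
                     ppm = stats::runif(nrow(planted), 5, 150))
    )
    annotation <- dplyr::bind_rows(
      # abundant contaminants fail on ppm, rare ones on annotation
      tibble::tibble(protein_id = bg_ids,
                     nucleic_acid_binding = abundant,
                     spliceosome_component = stats::runif(n_background) < 0.2),
      tibble::tibble(protein_id = planted$protein_id,
                     nucleic_acid_binding = TRUE, spliceosome_component = FALSE)
    )
    out <- list(hits = dplyr::bind_rows(bg_hits, pl_hits), samples = samples,
                abundance = abundance, annotation = annotation, planted = planted)
    out$manifest <- list(seed = seed, n_background = n_background,
                         dropout = dropout, hash = digest::digest(out))
    out
  })
}

#' Simulate a qPCR Ct table with planted condition effects
#'
#' `Ct = baseline[amplicon] + effect[condition] (target amplicons only) +
#' plate noise + technical noise`, with technical duplicates. The planted
#' knockdown recovered by the nested delta-delta-Ct analysis equals
#' `effect[treatment] - effect[growth_control]` and is invariant to the
#' transfection-control effect by construction.
#'
#' @param effects Named condition effects in cycles (defaults: a -1.2-cycle
#'   target effect of the targeting siRNA, a 0.3-cycle transfection-agent
#'   effect, none for growth control or scrambled siRNA).
#' @param baselines Named amplicon baseline Ct values.
#' @param noise_sd Plate-level noise SD in cycles (default 0.15).
#' @param tech_sd Technical-duplicate noise SD (default 0.05).
#' @param n_experiments Biological experiments (default 3).
#' @param n_replicates Plates per condition per experiment (default 3).
#' @param timepoint Recorded timepoint label (default 48).
#' @param seed Mandatory RNG seed.
#' @return Tibble of Ct records with technical duplicates (`tech_rep`).
#' @export
simulate_ct <- function(effects = c(growth_control = 0, transfection_control = 0.3,
                                    sirna_target = -1.2, sirna_scrambled = 0.3),
                        baselines = c(target_wildtype = 28, target_alternative = 32,
                                      housekeeping = 20),
                        noise_sd = 0.15, tech_sd = 0.05,
                        n_experiments = 3, n_replicates = 3, timepoint = 48,
                        seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(ct_conditions %in% names(effects)))
  with_seed_local(seed, {
    grid <- tidyr::expand_grid(
      experiment = paste0("E", seq_len(n_experiments)),
      replicate = seq_len(n_replicates),
      condition = ct_conditions,
      amplicon = names(baselines)
    )
    plate_mu <- unname(baselines[grid$amplicon]) +
      unname(ifelse(grid$amplicon == "housekeeping", 0, effects[grid$condition])) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    purrr::map_dfr(1:2, function(tr) {
      dplyr::mutate(grid, timepoint = timepoint, tech_rep = tr,
                    ct = plate_mu + stats::rnorm(nrow(grid), 0, tech_sd))
    }) |> dplyr::arrange(.data$experiment, .data$replicate, .data$condition,
                         .data$amplicon, .data$tech_rep)
  })
}

non_stop_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

rand_codons <- function(n) paste(sample(non_stop_codons(), n, replace = TRUE),
                                 collapse = "")
rand_bases <- function(n) if (n == 0) "" else
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Construct a toy mini-gene with a planted read-through truncation
#'
#' Builds a plus-strand gene whose spliced CDS encodes `n_aa` residues and
#' whose intron after `readthrough_exon` carries a planted in-frame stop
#' `stop_offset` codons past the junction, so the read-through translation
#' has a truncation length known by construction. `utr5` bases precede the
#' start codon. When the junction is not in frame (`frame_shift` > 0), the
#' junction-spanning codon is completed with non-stop bases and the planted
#' stop follows the shifted frame.
#'
#' The `"scnn1b_analog"` preset mirrors the dimensions of the beta-ENaC
#' modifier gene: 13 exons, a 640-residue spliced protein, an in-frame
#' junction at the end of exon 3 after 195 codons, and a stop 26 codons into
#' intron 3 — a synthetic stand-in (no real genomic sequence is bundled).
#'
#' @param seed Mandatory RNG seed.
#' @param n_exons Number of exons.
#' @param n_aa Length of the spliced protein in residues.
#' @param utr5 5' UTR length in bases (start codon at transcript position
#'   `utr5 + 1`).
#' @param readthrough_exon Exon whose downstream intron carries the planted
#'   stop.
#' @param codons_before_junction Complete codons 5' of the junction (fixes
#'   exon sizes so the junction is in frame when `frame_shift = 0`).
#' @param stop_offset Codons between junction and planted stop.
#' @param frame_shift 0 (in-frame junction), 1 or 2 extra bases before the
#'   junction.
#' @param intron_length Length of every intron (default 200).
#' @param preset `"scnn1b_analog"` overrides the dimensional arguments.
#' @return List: `model` (a [gene_model()]), `genome` (string), `junction`
#'   (transcript coordinate of the junction for
#'   [translate_cds()]), `expected` (planted truths: spliced and
#'   read-through protein lengths, residues past junction).
#' @export
make_minigene <- function(seed, n_exons = 4, n_aa = 60, utr5 = 30,
                          readthrough_exon = 3, codons_before_junction = 30,
                          stop_offset = 9, frame_shift = 0,
                          intron_length = 200, preset = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(preset)) {
    preset <- match.arg(preset, "scnn1b_analog")
    return(make_minigene(seed, n_exons = 13, n_aa = 640, utr5 = 99,
                         readthrough_exon = 3, codons_before_junction = 195,
                         stop_offset = 26, frame_shift = 0,
                         intron_length = 200))
  }
  stopifnot(readthrough_exon >= 1, readthrough_exon < n_exons,
            frame_shift %in% 0:2,
            codons_before_junction >= 1, codons_before_junction < n_aa,
            intron_length >= 3 * (stop_offset + 2))
  with_seed_local(seed, {
    cds <- paste0("ATG", rand_codons(n_aa - 1), "TAA")
    utr3 <- rand_bases(30)
    tx <- paste0(rand_bases(utr5), cds, utr3)
    # junction transcript coordinate: end of the last fully exonic codon
    # (+ frame_shift bases pushed before the junction)
    junction <- utr5 + 3 * codons_before_junction + frame_shift
    stopifnot(junction < nchar(tx))
    # exon boundaries: exons 1..readthrough_exon end at `junction`; split
    # the halves evenly
    split_lengths <- function(total, k) {
      base <- total %/% k
      out <- rep(base, k)
      out[k] <- out[k] + total - base * k
      out
    }
    ex_head <- split_lengths(junction, readthrough_exon)
    ex_tail <- split_lengths(nchar(tx) - junction, n_exons - readthrough_exon)
    ex_len <- c(ex_head, ex_tail)
    # intron after the read-through exon: complete any junction-spanning
    # codon without a stop, then stop_offset non-stop codons, then TAA
    introns <- vapply(seq_len(n_exons - 1), function(k) {
      if (k == readthrough_exon) {
        # complete a junction-spanning codon with C's (X+CC / XY+C can
        # never form a stop), then the planted in-frame stop
        fill <- if (frame_shift == 0) "" else
          substr("CC", 1, 3 - frame_shift)
        planted <- paste0(fill, rand_codons(stop_offset), "TAA")
        paste0(planted, rand_bases(intron_length - nchar(planted)))
      } else {
        rand_bases(intron_length)
      }
    }, character(1))
    # assemble genome and exon coordinates
    tx_off <- cumsum(c(0, ex_len))
    genome <- ""
    starts <- integer(n_exons); ends <- integer(n_exons)
    for (k in seq_len(n_exons)) {
      starts[k] <- nchar(genome) + 1L
      genome <- paste0(genome, substr(tx, tx_off[k] + 1, tx_off[k + 1]))
      ends[k] <- nchar(genome)
      if (k < n_exons) genome <- paste0(genome, introns[k])
    }
    model <- gene_model("minigene", "+",
                        tibble::tibble(start = starts, end = ends),
                        cds_start = utr5 + 1)
    # a junction-spanning codon exists iff frame_shift > 0; it starts at
    # transcript position junction - frame_shift + 1, which is "past" the
    # junction (start >= junction) only for frame_shift == 1
    past <- stop_offset + as.integer(frame_shift == 1)
    total <- codons_before_junction + as.integer(frame_shift > 0) + stop_offset
    list(model = model, genome = genome, junction = junction,
         expected = list(
           spliced_aa = n_aa,
           readthrough_aa = total,
           residues_past_junction = past
         ))
  })
}
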