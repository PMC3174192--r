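#' Generate a full synthetic disease-profiling scenario
#'
#' Builds an atlas plus three overlapping disease gene lists whose planted
#' structure mirrors the published study conditions, so that every
#' downstream set computation has a known expected value: a 219-gene
#' ASD-style list of which 32 are highly expressed (9 of them in every
#' region), an epilepsy-style list with 42 highly expressed genes, a
#' schizophrenia-style list with 212, a triple intersection of 11 genes
#' exactly one of which is highly expressed, 8 highly expressed genes
#' shared between the ASD and schizophrenia lists, 2 shared between ASD
#' and epilepsy, and planted non-detected patterns giving 46 / 52 / 40
#' ASD genes below the detection threshold in hippocampus / cerebellum /
#' dorsolateral prefrontal cortex. A 21-gene housekeeping panel with
#' bounded tier span is included for calibration. Everything is synthetic
#' and deterministic given the seed.
#'
#' @param seed RNG seed.
#' @param noise_sd multiplicative log-normal noise (log-scale sd).
#' @return list with \code{atlas}, \code{sets} (named list of three
#'   [gene_set()]s: ASD, Epilepsy, Schizophrenia), \code{housekeeping}
#'   (a [gene_set()]), and \code{truth} (planted memberships and expected
#'   counts).
#' @export
generate_disease_scenario <- function(seed = 1, noise_sd = 0.25) {
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  tri <- mk("TRI", 11)            # in all three lists; TRI001 highly expressed
  ae  <- mk("AE", 15)             # ASD & epilepsy only; AE001 high
  as_ <- mk("AS", 30)             # ASD & schizophrenia only; AS001..AS007 high
  es  <- mk("ES", 25)             # epilepsy & schizophrenia only; 5 high
  apan <- mk("APAN", 9)           # ASD-only, high in every region
  ahigh <- mk("AH", 14)           # ASD-only, high in 1-3 regions
  asil_all <- mk("ASILA", 38)     # ASD-only, silent everywhere
  asil_dhc <- mk("ASILB", 2)      # silent in DLPC+Hipp+Cere
  asil_hc  <- mk("ASILC", 6)      # silent in Hipp+Cere
  asil_c   <- mk("ASILD", 6)      # silent in Cere only
  abg <- mk("ABG", 88)            # ASD-only background
  ehigh <- mk("EH", 35); ebg <- mk("EBG", 315)
  shigh <- mk("SH", 199); sbg <- mk("SBG", 501)
  hk <- mk("HK", 21)

  asd <- c(tri, ae, as_, apan, ahigh, asil_all, asil_dhc, asil_hc, asil_c, abg)
  epi <- c(tri, ae, es, ehigh, ebg)
  sz  <- c(tri, as_, es, shigh, sbg)
  stopifnot(length(asd) == 219)

  high_shared <- c("TRI001", "AE001", mk("AS", 30)[1:7], mk("ES", 25)[1:5])
  high_genes <- c(high_shared, ahigh, ehigh, shigh)
  pan_genes <- apan
  silent_all <- asil_all
  masks <- c(stats::setNames(rep(list(c("DLPC", "Hipp", "Cere")), length(asil_dhc)), asil_dhc),
             stats::setNames(rep(list(c("Hipp", "Cere")), length(asil_hc)), asil_hc),
             stats::setNames(rep(list("Cere"), length(asil_c)), asil_c))

  genes <- c(asd, setdiff(epi, asd), setdiff(sz, c(asd, epi)), hk)
  regions <- canonical_regions()
  atlas <- with_seed(seed, {
    profiles <- lapply(genes, function(g) {
      p <- list(gene = g, class = "background")
      if (g %in% hk) p$class <- "housekeeping"
      if (g %in% silent_all) p$class <- "silent"
      if (g %in% pan_genes) {
        p$class <- "pan_region_high"
        p$high_regions <- regions
      } else if (g %in% high_genes) {
        p$class <- "high"
        p$high_regions <- sample(regions, sample(1:3, 1))
      }
      if (g %in% names(masks)) p$silent_regions <- masks[[g]]
      p
    })
    simulate_profiles(profiles, regions, default_ages(), noise_sd = noise_sd)
  })

  list(atlas = atlas,
       sets = list(ASD = gene_set("ASD", asd),
                   Epilepsy = gene_set("Epilepsy", epi),
                   Schizophrenia = gene_set("Schizophrenia", sz)),
       housekeeping = gene_set("housekeeping", hk),
       truth = list(
         high = sort(normalize_genes(high_genes)),
         pan_region = sort(normalize_genes(pan_genes)),
         silent = sort(normalize_genes(silent_all)),
         expected = list(n_asd = 219, high_asd = 32, high_epi = 42,
                         high_sz = 212, triple = 11, pan_region_asd = 9,
                         asd_sz_high = 8, asd_epi_high = 2,
                         all_three_high = 1,
                         not_detected_hipp = 46, not_detected_cere = 52,
                         not_detected_dlpc = 40)))
}
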