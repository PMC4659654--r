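# Canned simulation scenarios: the study conditions under which the
# package's estimators are validated.  Problem sizes are chosen so that the
# signal of interest (proportion recovery, junction-read counts, hit-ratio
# separation, sampling-noise contrasts) is well resolved at the stated
# coverages while keeping a full validation run on one CPU in minutes; the
# methods vignette discusses each choice.

#' Three-species comparative panel
#'
#' 10 Mbp genomes for three species with a shared repeat complement:
#' a high-copy Ty3/gypsy-like LTR family (`OgreLike`), a conserved
#' Ty1/copia-like family (`AngelaLike`, low divergence in all species), one
#' shared satellite (`SatShared`), one satellite with strong species-level
#' lineage divergence (`SatPrivate`) whose variants are effectively
#' species-private, and one satellite (`SatSister`) conserved between the
#' sister species SPX/SPY but divergent in SPZ.
#'
#' @return list with `specs` (family specifications), `species` (named
#'   genome lengths) and `coverage` (0.05).
#' @export
scenario_comparative_panel <- function() {
  specs <- list(
    sim_family("OgreLike", "ltr_retrotransposon", unit_length = 5000,
               ltr_length = 500,
               copies = c(SPX = 350, SPY = 250, SPZ = 150),
               divergence = 0.02, lineage_divergence = 0.01,
               repeat_class = "LTR/Ty3-gypsy/OgreLike"),
    sim_family("AngelaLike", "ltr_retrotransposon", unit_length = 2500,
               ltr_length = 300,
               copies = c(SPX = 200, SPY = 200, SPZ = 200),
               divergence = 0.01, lineage_divergence = 0.005,
               repeat_class = "LTR/Ty1-copia/AngelaLike"),
    sim_family("SatShared", "satellite", unit_length = 180,
               copies = c(SPX = 3000, SPY = 1500, SPZ = 800),
               divergence = 0.02, lineage_divergence = 0.01,
               monomers_per_array = 400,
               repeat_class = "satellite/SatShared"),
    sim_family("SatPrivate", "satellite", unit_length = 160,
               copies = c(SPX = 1500, SPY = 1500, SPZ = 1500),
               divergence = 0.015, lineage_divergence = 0.08,
               monomers_per_array = 400,
               repeat_class = "satellite/SatPrivate"),
    sim_family("SatSister", "satellite", unit_length = 200,
               copies = c(SPX = 1000, SPY = 1000, SPZ = 1000),
               divergence = 0.015,
               lineage_divergence = c(SPX = 0.01, SPY = 0.01, SPZ = 0.08),
               monomers_per_array = 400,
               repeat_class = "satellite/SatSister")
  )
  list(specs = specs,
       species = c(SPX = 1e7, SPY = 1e7, SPZ = 1e7),
       coverage = 0.05)
}

#' Single-species genome for solo-LTR parameter recovery
#'
#' One LTR-retrotransposon family (2.5 kb element, 300 bp LTRs) with about
#' 2000 full-length copies and a solo-LTR count set by the requested
#' solo:full ratio; the genome length scales with the repeat content (about
#' 45% background) and reads are sampled at 0.2x.  Copy numbers are sized so
#' that a single run yields on the order of 200 LTR/5'UTR junction reads,
#' keeping the sampling error of one Rsf estimate near 0.15.
#'
#' @param solo_ratio target solo:full ratio (0, 0.5, 1, 2, ...).
#' @return list with `specs`, `species`, `coverage` and `solo_ratio`.
#' @export
scenario_sololtr <- function(solo_ratio = 0) {
  n_full <- 2000
  copies <- round(n_full * (1 + solo_ratio))
  specs <- list(
    sim_family("OgreLike", "ltr_retrotransposon", unit_length = 2500,
               ltr_length = 300, copies = c(SIM = copies),
               solo_fraction = solo_ratio / (1 + solo_ratio),
               divergence = 0.02,
               repeat_class = "LTR/Ty3-gypsy/OgreLike")
  )
  target <- round(1.45 * (n_full * 2500 + n_full * solo_ratio * 300))
  list(specs = specs, species = c(SIM = target), coverage = 0.2,
       solo_ratio = solo_ratio)
}

#' Single-species genome for replicate-variation analysis
#'
#' Several low-abundance satellite families next to a few high-abundance
#' mobile-element families in one 10 Mbp genome.  Two independent read
#' samplings of this genome differ by sampling noise only, so per-cluster
#' fold-differences are largest for the small satellite clusters and shrink
#' when read counts are summed per repeat class.
#'
#' @return list with `specs`, `species` and `coverage` (0.05).
#' @export
scenario_replicates <- function() {
  sat <- lapply(1:6, function(i)
    sim_family(paste0("Sat", LETTERS[i]), "satellite",
               unit_length = c(150, 190, 230, 270, 320, 380)[i],
               copies = c(SIM = round(c(180, 140, 110, 90, 70, 55)[i])),
               divergence = 0.02, monomers_per_array = 60,
               repeat_class = paste0("satellite/Sat", LETTERS[i])))
  mob <- list(
    sim_family("OgreLike", "ltr_retrotransposon", unit_length = 5000,
               ltr_length = 500, copies = c(SIM = 80), divergence = 0.02,
               repeat_class = "LTR/Ty3-gypsy/OgreLike"),
    sim_family("AngelaLike", "ltr_retrotransposon", unit_length = 2500,
               ltr_length = 300, copies = c(SIM = 120), divergence = 0.02,
               repeat_class = "LTR/Ty1-copia/AngelaLike"),
    sim_family("CactaLike", "dispersed_other", unit_length = 3000,
               copies = c(SIM = 70), divergence = 0.02,
               repeat_class = "DNA/CACTA/CactaLike"))
  list(specs = c(sat, mob), species = c(SIM = 1e7), coverage = 0.05)
}

#' Synthetic abundance panel with a known contribution fraction
#'
#' Abundance table over `n_species` genomes spanning `g_range` where one
#' class's absolute amount is `f * G + noise` (so its expected contribution
#' to pairwise genome-size differences is `100 f`), a second class adds a
#' small constant amount, and the residual is non-repetitive.
#'
#' @param f fraction of genome-size differences explained by the focal
#'   class.
#' @param n_species number of species.
#' @param g_range genome-size range in Gbp.
#' @param noise_sd noise on the focal class in Mbp.
#' @param seed RNG seed.
#' @return list with `abundance` (abundance table) and `profiles`.
#' @export
scenario_contribution_panel <- function(f = 0.6, n_species = 8,
                                        g_range = c(2, 12), noise_sd = 30,
                                        seed = 1) {
  set.seed(seed)
  g_gbp <- seq(g_range[1], g_range[2], length.out = n_species)
  codes <- sprintf("SP%02d", seq_len(n_species))
  profiles <- species_profiles(codes, g_gbp * 1e9)
  g_mbp <- g_gbp * 1000
  focal <- f * g_mbp + stats::rnorm(n_species, 0, noise_sd)
  minor <- 80 + stats::rnorm(n_species, 0, 5)
  abundance <- rbind(
    abundance_record(codes, "LTR/Ty3-gypsy/Focal", focal / g_mbp,
                     g_mbp * 1e6),
    abundance_record(codes, "satellite/Minor", minor / g_mbp, g_mbp * 1e6))
  list(abundance = abundance, profiles = profiles, f = f)
}
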