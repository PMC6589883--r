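#' Default current-density profiles per treatment
#'
#' Anchor parameters of the rise / first-peak / dip / maximum / decay
#' trajectory typical of batch soil MFCs: start-up delay, first peak
#' within days 1-3, maximum later in the run, then decline to a tail.
#' Defaults emulate the closed-circuit treatments spiked with tetracycline
#' (TC), sulfadiazine (SC), and no antibiotic (CC): start-up 9/16/17 h,
#' first peaks 65/53/22 mA m^-2 (days 1-3), maxima 136/109/47 mA m^-2 on
#' day 27/27/19. Dip and tail fractions shape the between-peak troughs so
#' that the accumulated charge of the default run lands near 1130 C (TC)
#' and 920 C (SC); the CC tail is nearly zero (its current collapses after
#' the early peak).
#'
#' @return Data frame of per-treatment profile parameters.
#' @export
default_current_profiles <- function() {
  data.frame(
    treatment = c("TC", "SC", "CC"),
    startup_h = c(9, 16, 17),
    first_peak_mA_m2 = c(65, 53, 22),
    t_first_peak_days = c(2, 2, 2),
    max_mA_m2 = c(136, 109, 47),
    t_max_days = c(27, 27, 19),
    dip_frac = c(0.35, 0.35, 0.35),
    tail_frac = c(0.35, 0.35, 0.02),
    stringsAsFactors = FALSE)
}

#' Default polarization parameters per treatment
#'
#' Open-circuit voltage and internal resistance of the voltage-divider
#' model U = OCV * R / (R + Rint): 0.37/0.36/0.18 V and 262/336/1332 ohm
#' for TC/SC/CC.
#'
#' @return Data frame with `treatment`, `ocv_V`, `rint_ohm`.
#' @export
default_polarization_params <- function() {
  data.frame(treatment = c("TC", "SC", "CC"),
             ocv_V = c(0.37, 0.36, 0.18),
             rint_ohm = c(262, 336, 1332),
             stringsAsFactors = FALSE)
}

#' Default first-order antibiotic decay rates
#'
#' Per treatment x layer rate constants k (day^-1) chosen so that the
#' day-58 residuals of a 5 mg kg^-1 spike reproduce the study-condition
#' removal levels: treatment averages 70/66/52 % for tetracycline
#' (TC/TO/TN) and 95/93/87 % for sulfadiazine (SC/SO/SN), with the
#' layered TC residuals 1.5/1.4/1.6 and SC residuals 0.23/0.255/0.265
#' mg kg^-1 in layers C/A/S.
#'
#' @param spike_mg_per_kg spike level (mg kg^-1).
#' @param t_end_days endpoint the residuals refer to.
#' @return Data frame: `treatment`, `layer`, `k_per_day`.
#' @export
default_decay_rates <- function(spike_mg_per_kg = 5, t_end_days = 58) {
  resid <- rbind(
    data.frame(treatment = "TC", layer = c("C", "A", "S"),
               residual = c(1.5, 1.4, 1.6)),
    data.frame(treatment = "TO", layer = c("C", "A", "S"),
               residual = c(1.65, 1.6, 1.85)),
    data.frame(treatment = "TN", layer = c("C", "A", "S"),
               residual = c(2.4, 2.35, 2.45)),
    data.frame(treatment = "SC", layer = c("C", "A", "S"),
               residual = c(0.23, 0.255, 0.265)),
    data.frame(treatment = "SO", layer = c("C", "A", "S"),
               residual = c(0.33, 0.35, 0.37)),
    data.frame(treatment = "SN", layer = c("C", "A", "S"),
               residual = c(0.62, 0.65, 0.68)))
  resid$k_per_day <- log(spike_mg_per_kg / resid$residual) / t_end_days
  resid[c("treatment", "layer", "k_per_day")]
}

#' Default qPCR plate design
#'
#' Target genes of the Smartchip panel exercised here (tet and sul
#' resistance genes, mobile-genetic-element genes, and the 16S rRNA
#' normalizer), the 27-sample layout (9 treatments x 3 layers), 3
#' replicate wells, and quality-control failure probabilities.
#'
#' @return List describing the plate.
#' @export
default_qpcr_design <- function() {
  genes <- data.frame(
    gene = c("tetG", "tetPA", "sul2", "intI1", "cIntI1", "Tn21", "Tn24",
             "Tn25", "TnpA", "Tn23", "16S"),
    gene_class = c("tet", "tet", "sul", "MGE", "MGE", "MGE", "MGE", "MGE",
                   "MGE", "MGE", "16S"),
    stringsAsFactors = FALSE)
  treatments <- c("TC", "TO", "TN", "SC", "SO", "SN", "CC", "CO", "CN")
  samples <- as.vector(outer(treatments, c("C", "A", "S"), paste0))
  list(genes = genes, samples = samples, replicates = 3L,
       p_multi_peak = 0.03, p_bad_efficiency = 0.03, ct_sd = 0.15)
}

#' Default community design
#'
#' 40 genera across three kingdoms (20 bacteria, 12 fungi, 8 archaea)
#' observed in 30 samples, with three planted co-occurrence modules of 6
#' taxa each at within-module Spearman rho 0.9 (between-module rho 0),
#' log-normal abundances, and unit treatment fold-changes.
#'
#' @return List describing the community generator.
#' @export
default_community_design <- function() {
  n_taxa <- c(bacteria = 20L, fungi = 12L, archaea = 8L)
  taxa <- unlist(lapply(names(n_taxa), function(k)
    paste0(substr(k, 1, 1), seq_len(n_taxa[[k]]))), use.names = FALSE)
  modules <- list(m1 = taxa[1:6],           # bacteria
                  m2 = c(taxa[7:10], taxa[21:22]),   # bacteria + fungi
                  m3 = c(taxa[23:26], taxa[33:34]))  # fungi + archaea
  list(n_taxa = n_taxa, n_samples = 30L, modules = modules,
       rho_within = 0.9, meanlog = log(200), sdlog = 1,
       fold_change = setNames(rep(1, length(taxa)), taxa))
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. All
#' generators are deterministic given `seed`; rates, areas and intervals
#' must be strictly positive and the qPCR replicate count at least 2.
#'
#' @param seed integer RNG seed.
#' @param n_reactors reactors per treatment.
#' @param duration_days incubation length (default 58).
#' @param sample_interval_s voltage logging cadence, seconds (default
#'   1800, one logger cycle).
#' @param external_resistance_ohm closed-circuit load (default 100).
#' @param cathode_area_m2 projected cathode area (default 0.0036).
#' @param profiles per-treatment current profiles
#'   ([default_current_profiles()]).
#' @param polarization per-treatment OCV/Rint
#'   ([default_polarization_params()]).
#' @param resistance_ladder_ohm polarization sweep loads, 10000 down to
#'   100 ohm.
#' @param spike_mg_per_kg antibiotic spike (default 5).
#' @param decay per treatment-layer first-order rates
#'   ([default_decay_rates()]).
#' @param qpcr plate design ([default_qpcr_design()]).
#' @param community community design ([default_community_design()]).
#' @param voltage_noise_sd_V additive voltage noise, V.
#' @param conc_noise_cv multiplicative (log-normal) concentration noise CV.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_reactors = 2L,
                       duration_days = 58,
                       sample_interval_s = 1800,
                       external_resistance_ohm = 100,
                       cathode_area_m2 = 0.0036,
                       profiles = default_current_profiles(),
                       polarization = default_polarization_params(),
                       resistance_ladder_ohm = round(exp(seq(log(10000), log(100),
                                                             length.out = 15))),
                       spike_mg_per_kg = 5,
                       decay = default_decay_rates(spike_mg_per_kg),
                       qpcr = default_qpcr_design(),
                       community = default_community_design(),
                       voltage_noise_sd_V = 2e-4,
                       conc_noise_cv = 0.05) {
  stopifnot(duration_days > 0, sample_interval_s > 0,
            external_resistance_ohm > 0, cathode_area_m2 > 0,
            spike_mg_per_kg > 0, qpcr$replicates >= 2L,
            all(decay$k_per_day >= 0))
  structure(list(seed = as.integer(seed), n_reactors = as.integer(n_reactors),
                 duration_days = duration_days,
                 sample_interval_s = sample_interval_s,
                 external_resistance_ohm = external_resistance_ohm,
                 cathode_area_m2 = cathode_area_m2,
                 profiles = profiles, polarization = polarization,
                 resistance_ladder_ohm = resistance_ladder_ohm,
                 spike_mg_per_kg = spike_mg_per_kg, decay = decay,
                 qpcr = qpcr, community = community,
                 voltage_noise_sd_V = voltage_noise_sd_V,
                 conc_noise_cv = conc_noise_cv),
            class = "sim_config")
}
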