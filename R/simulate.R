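# Synthetic-data generators. Each one is deterministic given the config
# seed; the seed is combined with a small per-generator offset so the five
# generators draw from independent streams.

local_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Generate a synthetic voltage trace
#'
#' Piecewise-linear current-density envelope through the profile anchors
#' (zero before start-up; first peak; dip; maximum; decay to a tail),
#' converted to voltage via U = I' * R * A, plus additive Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param treatment treatment label present in `config$profiles`.
#' @param reactor reactor label.
#' @return A [voltage_trace()].
#' @export
gen_voltage_trace <- function(config, treatment, reactor = paste0(treatment, "1")) {
  pr <- config$profiles[config$profiles$treatment == treatment, ]
  if (nrow(pr) != 1L) stop("unknown treatment: ", treatment)
  local_seed(config, 11L + match(reactor, paste0(treatment, 1:99), nomatch = 0L))
  t_s <- seq(0, config$duration_days * 86400, by = config$sample_interval_s)
  t_d <- t_s / 86400
  # current density whose voltage sits just above the 1 mV start-up
  # threshold, so the trace crosses it at the programmed delay
  i_thresh <- 1000 * 0.0015 / (config$external_resistance_ohm *
                                 config$cathode_area_m2)
  dt_d <- config$sample_interval_s / 86400
  anchors_t <- c(0, pr$startup_h / 24 - dt_d, pr$startup_h / 24,
                 pr$t_first_peak_days, pr$t_first_peak_days + 6,
                 pr$t_max_days, pr$t_max_days + 8, config$duration_days)
  anchors_i <- c(0, 0, i_thresh, pr$first_peak_mA_m2,
                 pr$dip_frac * pr$first_peak_mA_m2, pr$max_mA_m2,
                 pr$tail_frac * pr$max_mA_m2, pr$tail_frac * pr$max_mA_m2)
  keep <- !duplicated(anchors_t) & anchors_t <= config$duration_days
  i_target <- approx(anchors_t[keep], anchors_i[keep], xout = t_d,
                     rule = 2)$y
  u <- i_target / 1000 * config$external_resistance_ohm *
    config$cathode_area_m2
  if (config$voltage_noise_sd_V > 0)
    u <- u + rnorm(length(u), 0, config$voltage_noise_sd_V)
  voltage_trace(t_s, u, config$external_resistance_ohm,
                config$cathode_area_m2, reactor = reactor,
                treatment = treatment)
}

#' Generate a synthetic polarization sweep
#'
#' Voltage-divider model U = OCV * R / (R + Rint) over the configured
#' resistance ladder, plus proportional Gaussian noise. Noiseless sweeps
#' are monotone non-decreasing in R.
#'
#' @param config a [sim_config()].
#' @param treatment treatment label present in `config$polarization`.
#' @param noise_cv relative noise on each voltage (default 0: noiseless).
#' @return A [polarization_sweep()].
#' @export
gen_polarization <- function(config, treatment, noise_cv = 0) {
  pp <- config$polarization[config$polarization$treatment == treatment, ]
  if (nrow(pp) != 1L) stop("unknown treatment: ", treatment)
  r <- config$resistance_ladder_ohm
  if (length(r) == 0L) stop("empty resistance ladder")
  stopifnot(pp$ocv_V > 0, pp$rint_ohm > 0)
  local_seed(config, 23L)
  u <- pp$ocv_V * r / (r + pp$rint_ohm)
  if (noise_cv > 0) u <- u * (1 + rnorm(length(u), 0, noise_cv))
  polarization_sweep(r, u, treatment = treatment)
}

#' Generate antibiotic residual concentrations
#'
#' First-order decay C(t) = C0 * exp(-k t) with the configured
#' treatment-layer rate; log-normal replicate noise is applied after the
#' deterministic decay.
#'
#' @param config a [sim_config()].
#' @param treatment,layer labels present in `config$decay`.
#' @param t_days sampling time (>= 0), days.
#' @param n_replicates replicate measurements to draw.
#' @param noiseless skip replicate noise.
#' @return Numeric vector of `n_replicates` concentrations, mg kg^-1.
#' @export
gen_antibiotic_decay <- function(config, treatment, layer, t_days,
                                 n_replicates = 3L, noiseless = FALSE) {
  if (any(t_days < 0)) stop("negative time")
  k <- config$decay$k_per_day[config$decay$treatment == treatment &
                                config$decay$layer == layer]
  if (length(k) != 1L) stop("unknown treatment/layer: ", treatment, "/", layer)
  local_seed(config, 31L + match(layer, c("C", "A", "S")) +
               10L * match(treatment, unique(config$decay$treatment)))
  c_det <- config$spike_mg_per_kg * exp(-k * t_days)
  if (noiseless || config$conc_noise_cv == 0)
    return(rep(c_det, n_replicates))
  sdl <- sqrt(log(1 + config$conc_noise_cv^2))
  c_det * exp(rnorm(n_replicates, -sdl^2 / 2, sdl))
}

#' Simulate the full concentration table
#'
#' Every antibiotic-spiked treatment x layer x replicate at the end of the
#' run, in the long format read by [removal_summary()].
#'
#' @param config a [sim_config()].
#' @param t_days sampling time (defaults to the full run).
#' @return Data frame: `treatment`, `layer`, `replicate`, `analyte`,
#'   `concentration_mg_kg`, `spike_mg_kg`.
#' @export
gen_concentration_table <- function(config, t_days = config$duration_days) {
  combos <- unique(config$decay[c("treatment", "layer")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    trt <- combos$treatment[r]
    lay <- combos$layer[r]
    conc <- gen_antibiotic_decay(config, trt, lay, t_days)
    data.frame(treatment = trt, layer = lay,
               replicate = seq_along(conc),
               analyte = if (startsWith(trt, "T")) "tetracycline" else "sulfadiazine",
               concentration_mg_kg = conc,
               spike_mg_kg = config$spike_mg_per_kg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic qPCR well table
#'
#' Inverts the gamma transform: CT = 31 - (10/3) * log10(gamma_true) plus
#' replicate noise. A configured fraction of wells is planted with a
#' quality-control failure (a second melt peak, or an amplification
#' efficiency outside 90-110 percent); genes absent from `truth` for a
#' sample receive CT >= 31. The planted failures are recorded in the
#' `"planted_qc"` attribute for recovery tests.
#'
#' @param config a [sim_config()].
#' @param truth data frame `sample`, `gene`, `gamma_true` (> 0) of true
#'   relative copy numbers; defaults to [default_qpcr_truth()].
#' @param noiseless drop CT noise (QC failures are still planted).
#' @return Well table: `sample`, `gene`, `gene_class`, `replicate`, `ct`,
#'   `n_melt_peaks`, `efficiency_pct`; attribute `planted_qc` is a logical
#'   vector over rows.
#' @export
gen_qpcr_plate <- function(config, truth = default_qpcr_truth(config),
                           noiseless = FALSE) {
  if (any(truth$gamma_true <= 0)) stop("true copy numbers must be > 0")
  des <- config$qpcr
  local_seed(config, 47L)
  grid <- merge(expand.grid(sample = des$samples, gene = des$genes$gene,
                            replicate = seq_len(des$replicates),
                            stringsAsFactors = FALSE),
                des$genes, by = "gene")
  grid <- merge(grid, truth, by = c("sample", "gene"), all.x = TRUE)
  grid <- grid[order(grid$sample, grid$gene, grid$replicate), ]
  rownames(grid) <- NULL
  nwell <- nrow(grid)

  ct <- ifelse(is.na(grid$gamma_true),
               31 + runif(nwell, 0.5, 3),             # undetected: CT >= 31
               31 - (10 / 3) * log10(grid$gamma_true))
  if (!noiseless && des$ct_sd > 0) {
    noise <- rnorm(nwell, 0, des$ct_sd)
    ct <- ifelse(is.na(grid$gamma_true), pmax(ct + noise, 31), ct + noise)
  }
  multi <- runif(nwell) < des$p_multi_peak
  badeff <- !multi & runif(nwell) < des$p_bad_efficiency
  eff <- runif(nwell, 95, 105)
  eff[badeff] <- ifelse(runif(sum(badeff)) < 0.5,
                        runif(sum(badeff), 75, 89.9),
                        runif(sum(badeff), 110.1, 125))
  out <- data.frame(sample = grid$sample, gene = grid$gene,
                    gene_class = grid$gene_class,
                    replicate = grid$replicate, ct = ct,
                    n_melt_peaks = ifelse(multi, 2L, 1L),
                    efficiency_pct = eff, stringsAsFactors = FALSE)
  attr(out, "planted_qc") <- multi | badeff
  attr(out, "truth") <- truth
  out
}

#' Default true relative copy numbers for the qPCR generator
#'
#' Deterministic design: each target gene gets a baseline gamma, scaled by
#' circuit group (closed 0.45 x, open 0.7 x, non-electrode 1 x) and layer
#' (C 0.85, A 0.9, S 1.0), so that class aggregates reproduce the
#' closed < open < non-electrode ordering. The 16S normalizer is constant
#' and large. tetG, tetPA, sul2, intI1, Tn24 and Tn25 are present in every
#' sample (100 percent detection); Tn23 and TnpA are left undetected in
#' the non-antibiotic treatments.
#'
#' @param config a [sim_config()].
#' @return Data frame `sample`, `gene`, `gamma_true`.
#' @export
default_qpcr_truth <- function(config) {
  des <- config$qpcr
  grid <- expand.grid(sample = des$samples, gene = des$genes$gene,
                      stringsAsFactors = FALSE)
  base <- setNames(c(120, 80, 60, 40, 30, 25, 35, 30, 15, 12, 1e4),
                   c("tetG", "tetPA", "sul2", "intI1", "cIntI1", "Tn21",
                     "Tn24", "Tn25", "TnpA", "Tn23", "16S"))
  circuit <- substr(grid$sample, 2, 2)            # C=closed, O=open, N=none
  grp <- c(C = 0.45, O = 0.7, N = 1.0)[circuit]
  lay <- c(C = 0.85, A = 0.9, S = 1.0)[substr(grid$sample, 3, 3)]
  gamma <- base[grid$gene] * grp * lay
  gamma[grid$gene == "16S"] <- base["16S"]
  keep <- !(grid$gene %in% c("Tn23", "TnpA") &
              substr(grid$sample, 1, 1) == "C")
  data.frame(sample = grid$sample, gene = grid$gene,
             gamma_true = unname(gamma),
             stringsAsFactors = FALSE)[keep, ]
}

#' Generate a multi-kingdom abundance table with planted modules
#'
#' Log-normal genus abundances whose rank-correlation structure is imposed
#' through a Gaussian copula: taxa of one planted module share a latent
#' factor giving the configured within-module Spearman rho (latent Pearson
#' r = 2 sin(pi rho / 6)); all other pairs are independent. Treatment
#' fold-changes act multiplicatively. Ground truth (planted edges and
#' module memberships) is returned for recovery tests.
#'
#' @param config a [sim_config()].
#' @param n_samples overrides the configured sample count.
#' @param rho_within overrides the configured within-module Spearman rho
#'   (must lie in (-1, 1)).
#' @param integer_counts round abundances to integer counts (default TRUE).
#' @return List: `table` (abundance data frame with `taxon`, `kingdom`,
#'   `lineage` + sample columns), `truth_edges`
#'   (`taxon_a`, `taxon_b`, `rho_true`), `modules` (list of member vectors).
#' @export
gen_community <- function(config, n_samples = config$community$n_samples,
                          rho_within = config$community$rho_within,
                          integer_counts = TRUE) {
  cm <- config$community
  if (n_samples < 2L) stop("need >= 2 samples")
  if (abs(rho_within) >= 1) stop("correlation must lie in (-1, 1)")
  if (rho_within < 0)
    stop("negative within-module correlation is not representable by a shared factor")
  local_seed(config, 59L)
  taxa <- unlist(lapply(names(cm$n_taxa), function(k)
    paste0(substr(k, 1, 1), seq_len(cm$n_taxa[[k]]))), use.names = FALSE)
  kingdom <- rep(names(cm$n_taxa), cm$n_taxa)
  p <- length(taxa)

  # latent Gaussian with one shared factor per module
  r_latent <- 2 * sin(pi * rho_within / 6)
  z <- matrix(rnorm(p * n_samples), p, n_samples)
  if (r_latent != 0) {
    for (mod in cm$modules) {
      idx <- match(mod, taxa)
      f <- rnorm(n_samples)
      z[idx, ] <- sqrt(abs(r_latent)) * sign(r_latent) *
        matrix(f, length(idx), n_samples, byrow = TRUE) +
        sqrt(1 - abs(r_latent)) * z[idx, ]
    }
  }
  ab <- qlnorm(pnorm(z), meanlog = cm$meanlog, sdlog = cm$sdlog)
  fc <- cm$fold_change[taxa]
  fc[is.na(fc)] <- 1
  ab <- ab * fc
  if (integer_counts) ab <- round(ab)
  colnames(ab) <- sprintf("s%02d", seq_len(n_samples))

  lineage <- paste("p_x", "c_x", "o_x", "f_x", taxa, sep = ";")
  table <- data.frame(taxon = taxa, kingdom = kingdom, lineage = lineage,
                      ab, stringsAsFactors = FALSE, check.names = FALSE)
  truth_edges <- do.call(rbind, lapply(cm$modules, function(mod) {
    pr <- t(utils::combn(sort(mod), 2))
    data.frame(taxon_a = pr[, 1], taxon_b = pr[, 2],
               rho_true = rho_within, stringsAsFactors = FALSE)
  }))
  rownames(truth_edges) <- NULL
  list(table = table, truth_edges = truth_edges, modules = cm$modules)
}
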