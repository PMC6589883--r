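# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are plain CSV/TSV with fixed headers; see the individual
# readers for the expected columns.

#' Read voltage traces
#'
#' CSV columns: `reactor`, `treatment`, `time_s`, `voltage_V`,
#' `resistance_ohm`, `cathode_area_m2`.
#'
#' @param path CSV file.
#' @return Named list of [voltage_trace()] objects, one per reactor.
#' @export
read_voltage_traces <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$reactor), function(s)
    voltage_trace(s$time_s, s$voltage_V, s$resistance_ohm[1],
                  s$cathode_area_m2[1], reactor = s$reactor[1],
                  treatment = s$treatment[1]))
}

#' Write voltage traces
#'
#' @param traces list of [voltage_trace()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_voltage_traces <- function(traces, path) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  d <- do.call(rbind, lapply(traces, function(tr)
    data.frame(reactor = tr$reactor, treatment = tr$treatment,
               time_s = tr$time_s, voltage_V = tr$voltage_V,
               resistance_ohm = tr$resistance_ohm,
               cathode_area_m2 = tr$cathode_area_m2)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read polarization sweeps
#'
#' CSV columns: `treatment`, `resistance_ohm`, `voltage_V`.
#'
#' @param path CSV file.
#' @return Named list of [polarization_sweep()] objects, one per treatment.
#' @export
read_polarization_sweeps <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$treatment), function(s)
    polarization_sweep(s$resistance_ohm, s$voltage_V, treatment = s$treatment[1]))
}

#' Write polarization sweeps
#'
#' @param sweeps list of [polarization_sweep()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_polarization_sweeps <- function(sweeps, path) {
  if (inherits(sweeps, "polarization_sweep")) sweeps <- list(sweeps)
  d <- do.call(rbind, lapply(sweeps, function(sw)
    data.frame(treatment = sw$treatment, resistance_ohm = sw$resistance_ohm,
               voltage_V = sw$voltage_V)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an antibiotic concentration table
#'
#' CSV columns: `treatment`, `layer`, `replicate`, `analyte`,
#' `concentration_mg_kg`, `spike_mg_kg`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_concentrations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (any(d$concentration_mg_kg < 0)) stop("negative concentrations")
  d
}

#' Read a qPCR well table
#'
#' TSV columns: `sample`, `gene`, `gene_class`, `replicate`, `ct`,
#' `n_melt_peaks`, `efficiency_pct`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_qpcr_wells <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (any(d$ct <= 0, na.rm = TRUE)) stop("CT values must be > 0")
  d
}

#' Read an abundance table
#'
#' TSV: columns `taxon`, `kingdom`, `lineage`, then one numeric column per
#' sample.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_abundance_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abundance_matrix(d)  # validates
  d
}

#' Write a generic TSV
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every synthetic input of one simulated experiment
#'
#' Generates voltage traces, polarization sweeps, the concentration table,
#' the qPCR well table and the abundance table from a [sim_config()], and
#' writes them (plus the ground-truth sidecar of planted edges and module
#' memberships) under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(traces = file.path(outdir, "voltage_traces.csv"),
             sweeps = file.path(outdir, "polarization_sweeps.csv"),
             conc = file.path(outdir, "concentrations.csv"),
             qpcr = file.path(outdir, "qpcr_wells.tsv"),
             abundance = file.path(outdir, "abundance.tsv"),
             truth_edges = file.path(outdir, "truth_edges.tsv"),
             truth_modules = file.path(outdir, "truth_modules.tsv"))
  traces <- lapply(config$profiles$treatment, function(tr)
    gen_voltage_trace(config, tr))
  write_voltage_traces(traces, paths["traces"])
  sweeps <- lapply(config$polarization$treatment, function(tr)
    gen_polarization(config, tr))
  write_polarization_sweeps(sweeps, paths["sweeps"])
  write.csv(gen_concentration_table(config), paths["conc"], row.names = FALSE)
  write_tsv(gen_qpcr_plate(config), paths["qpcr"])
  comm <- gen_community(config)
  write_tsv(comm$table, paths["abundance"])
  write_tsv(comm$truth_edges, paths["truth_edges"])
  write_tsv(data.frame(
    module = rep(names(comm$modules), lengths(comm$modules)),
    taxon = unlist(comm$modules, use.names = FALSE)), paths["truth_modules"])
  invisible(paths)
}
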