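#' Quality-control filter for qPCR wells
#'
#' Retains wells with exactly one melt peak and amplification efficiency
#' inside the closed interval \[90, 110\] percent; everything else is
#' excluded. Idempotent. Exclusion counts per reason are attached as the
#' `"qc_log"` attribute.
#'
#' @param wells data frame with at least `n_melt_peaks` and
#'   `efficiency_pct` columns (see [read_qpcr_wells()]).
#' @param efficiency_range closed efficiency interval, percent.
#' @return The retained rows, with a `qc_log` attribute
#'   (`data.frame(reason, n)`).
#' @export
qc_filter <- function(wells, efficiency_range = c(90, 110)) {
  need <- c("n_melt_peaks", "efficiency_pct")
  if (!all(need %in% names(wells))) stop("missing QC columns")
  if (nrow(wells) == 0L) {
    attr(wells, "qc_log") <- data.frame(reason = character(), n = integer())
    return(wells)
  }
  bad_peaks <- wells$n_melt_peaks != 1L
  bad_eff <- wells$efficiency_pct < efficiency_range[1] |
    wells$efficiency_pct > efficiency_range[2]
  keep <- !bad_peaks & !bad_eff
  out <- wells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_log") <- data.frame(
    reason = c("multiple_melt_peaks", "efficiency_out_of_range", "retained"),
    n = c(sum(bad_peaks), sum(bad_eff & !bad_peaks), sum(keep)))
  out
}

#' Detection call from replicate CT values
#'
#' A target is called detected when the mean CT of the surviving replicates
#' is below `ct_max`, the replicate deviation (coefficient of variation of
#' the CT values, percent) is below `cv_max_pct`, and at least
#' `min_replicates` wells survived quality control (a single well cannot
#' define a deviation). With `mode = "per_replicate"` every replicate CT,
#' not just the mean, must be below `ct_max`.
#'
#' @param cts numeric CT values of the surviving replicates (0-3 values).
#' @param ct_max detection CT ceiling (default 31).
#' @param cv_max_pct maximum replicate CV in percent (default 20).
#' @param min_replicates detection quorum (default 2).
#' @param mode `"mean"` (default) or `"per_replicate"` CT rule.
#' @return Logical flag with a `"reason"` attribute when not detected.
#' @export
call_detection <- function(cts, ct_max = 31, cv_max_pct = 20,
                           min_replicates = 2L,
                           mode = c("mean", "per_replicate")) {
  mode <- match.arg(mode)
  cts <- cts[!is.na(cts)]
  fail <- function(reason) structure(FALSE, reason = reason)
  if (length(cts) == 0L) return(fail("no surviving replicates"))
  if (length(cts) < min_replicates) return(fail("below replicate quorum"))
  ct_ok <- if (mode == "mean") mean(cts) < ct_max else all(cts < ct_max)
  if (!ct_ok) return(fail("CT at or above threshold"))
  cv <- sd(cts) / mean(cts) * 100
  if (!(cv < cv_max_pct)) return(fail("replicate deviation too high"))
  TRUE
}

#' CT to relative copy number
#'
#' gamma = 10^((31 - CT) / (10/3)): one decade of template per 10/3
#' amplification cycles, anchored at gamma = 1 for CT = 31.
#'
#' @param ct threshold cycle value(s), > 0.
#' @return Relative copy number gamma (vectorized).
#' @export
relative_copy_number <- function(ct) {
  if (any(ct <= 0, na.rm = TRUE)) stop("CT must be > 0")
  10^((31 - ct) / (10 / 3))
}

#' Normalize a gene's copy number to 16S
#'
#' copies of gene / copies of 16S rRNA within the same sample.
#'
#' @param gamma_gene relative copy number of the target gene.
#' @param gamma_16S relative copy number of the 16S rRNA gene (> 0).
#' @return Normalized relative abundance.
#' @export
normalize_to_16S <- function(gamma_gene, gamma_16S) {
  if (any(gamma_16S <= 0, na.rm = TRUE)) stop("16S copy number must be > 0")
  gamma_gene / gamma_16S
}

#' Detection rate of a gene across samples
#'
#' @param detected logical vector of per-sample detection flags.
#' @return Percent of samples in which the gene was detected.
#' @export
detection_rate <- function(detected) {
  if (length(detected) == 0L) stop("need >= 1 sample")
  mean(as.logical(detected)) * 100
}

#' Full qPCR pipeline: wells to per-sample gene abundances
#'
#' Applies [qc_filter()], makes a detection call per sample x gene from the
#' surviving replicate CTs, converts the mean CT of detected targets to a
#' relative copy number, and normalizes to the sample's 16S rRNA gene.
#' Undetected genes get abundance 0 (treated as absent, not imputed);
#' samples whose 16S gene fails detection are flagged and their
#' abundances set to `NA`.
#'
#' @param wells qPCR well table (see [read_qpcr_wells()]).
#' @param ref_gene name of the normalizing gene (default `"16S"`).
#' @param ... passed to [call_detection()].
#' @return A data frame with one row per sample x gene: `sample`, `gene`,
#'   `gene_class`, `n_wells`, `mean_ct`, `detected`, `gamma`,
#'   `rel_abundance`. The QC log is carried in attribute `qc_log`.
#' @export
gene_abundance_table <- function(wells, ref_gene = "16S", ...) {
  need <- c("sample", "gene", "gene_class", "replicate", "ct")
  if (!all(need %in% names(wells))) stop("missing well columns")
  ok <- qc_filter(wells)
  qc_log <- attr(ok, "qc_log")

  # every sample x gene present in the raw table gets a row, so that wells
  # fully removed by QC still yield a not-detected call
  key_all <- unique(wells[c("sample", "gene", "gene_class")])
  rows <- lapply(seq_len(nrow(key_all)), function(r) {
    sub <- ok[ok$sample == key_all$sample[r] & ok$gene == key_all$gene[r], ]
    det <- call_detection(sub$ct, ...)
    mct <- if (nrow(sub) > 0L) mean(sub$ct) else NA_real_
    data.frame(sample = key_all$sample[r], gene = key_all$gene[r],
               gene_class = key_all$gene_class[r], n_wells = nrow(sub),
               mean_ct = mct, detected = isTRUE(det),
               gamma = if (isTRUE(det)) relative_copy_number(mct) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  res$rel_abundance <- NA_real_
  for (s in unique(res$sample)) {
    sel <- res$sample == s
    ref <- res[sel & res$gene == ref_gene, ]
    if (nrow(ref) == 1L && ref$detected) {
      res$rel_abundance[sel] <- normalize_to_16S(res$gamma[sel], ref$gamma)
    } else {
      warning("16S not detected in sample ", s, "; abundances undefined")
    }
  }
  attr(res, "qc_log") <- qc_log
  res
}

#' Class-aggregated relative abundance
#'
#' Per-sample sum of normalized abundances over a gene set (for example the
#' mobile-genetic-element genes Tn21, Tn24, Tn25 and cIntI1). Undetected
#' genes contribute zero.
#'
#' @param abund output of [gene_abundance_table()].
#' @param genes character vector of gene names to sum.
#' @return Named numeric vector of per-sample sums.
#' @export
aggregate_class <- function(abund, genes) {
  if (!all(genes %in% abund$gene)) stop("gene(s) not present in table")
  sub <- abund[abund$gene %in% genes, , drop = FALSE]
  r <- tapply(sub$rel_abundance, sub$sample, sum)
  setNames(as.numeric(r), names(r))
}
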