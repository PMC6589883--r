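make_wells <- function(ct, peaks = 1L, eff = 100, sample = "s1", gene = "g",
                       class = "tet") {
  data.frame(sample = sample, gene = gene, gene_class = class,
             replicate = seq_along(ct), ct = ct,
             n_melt_peaks = rep_len(peaks, length(ct)),
             efficiency_pct = rep_len(eff, length(ct)),
             stringsAsFactors = FALSE)
}

test_that("QC filter enforces single melt peak and the closed 90-110 window", {
  wells <- rbind(make_wells(25, peaks = 1L, eff = 95),
                 make_wells(25, peaks = 2L, eff = 100),
                 make_wells(25, peaks = 1L, eff = 85))
  out <- qc_filter(wells)
  expect_equal(nrow(out), 1L)
  expect_equal(out$efficiency_pct, 95)
  log <- attr(out, "qc_log")
  expect_equal(log$n[log$reason == "multiple_melt_peaks"], 1L)
  expect_equal(log$n[log$reason == "efficiency_out_of_range"], 1L)
  # boundary wells at exactly 90 and 110 are retained
  expect_equal(nrow(qc_filter(make_wells(c(25, 25), eff = c(90, 110)))), 2L)
  # idempotence and empty input
  expect_equal(nrow(qc_filter(out)), 1L)
  expect_equal(nrow(qc_filter(wells[0, ])), 0L)
})

test_that("detection calls follow the CT < 31 and CV < 20 percent rule", {
  expect_true(call_detection(c(25.0, 25.1, 24.9)))
  expect_false(call_detection(c(32, 32, 32)))
  # CV of (20, 30, 25) is 20.4 percent -> not detected
  expect_equal(sd(c(20, 30, 25)) / mean(c(20, 30, 25)) * 100, 20.4, tolerance = 0.05)
  det <- call_detection(c(20, 30, 25))
  expect_false(as.logical(det))
  expect_match(attr(det, "reason"), "deviation")
  # quorum: a single surviving well cannot be called
  det1 <- call_detection(27)
  expect_false(as.logical(det1))
  expect_match(attr(det1, "reason"), "quorum")
  det0 <- call_detection(numeric(0))
  expect_false(as.logical(det0))
  # per-replicate mode requires every CT below the ceiling
  expect_false(as.logical(call_detection(c(29, 30, 32), mode = "per_replicate")))
  expect_true(call_detection(c(29, 30, 30.5), mode = "per_replicate"))
})

test_that("the gamma transform is anchored at CT 31 and log-linear", {
  expect_equal(relative_copy_number(31), 1)
  expect_equal(relative_copy_number(21), 1000)
  expect_equal(relative_copy_number(31 + 10 / 3), 0.1)
  cts <- seq(15, 35, by = 0.5)
  slope <- coef(lm(log10(relative_copy_number(cts)) ~ cts))[2]
  expect_equal(unname(slope), -3 / 10)
  expect_true(all(diff(relative_copy_number(cts)) < 0))
  expect_error(relative_copy_number(-1), "CT")
})

test_that("16S normalization is a CT difference on the decade scale", {
  expect_equal(normalize_to_16S(5, 5), 1)
  ct16 <- 18
  expect_equal(normalize_to_16S(relative_copy_number(ct16 + 10 / 3),
                                relative_copy_number(ct16)), 0.1)
  expect_error(normalize_to_16S(1, 0), "16S")
})

test_that("normalized abundance is invariant to plate-wide CT shifts", {
  ct_gene <- 24.7; ct_16s <- 17.2
  for (shift in c(-2, 0, 1.5)) {
    expect_equal(
      normalize_to_16S(relative_copy_number(ct_gene + shift),
                       relative_copy_number(ct_16s + shift)),
      normalize_to_16S(relative_copy_number(ct_gene),
                       relative_copy_number(ct_16s)))
  }
})

test_that("detection rate is detected count over n", {
  expect_equal(detection_rate(rep(TRUE, 27)), 100)
  expect_equal(detection_rate(rep(FALSE, 10)), 0)
  expect_equal(detection_rate(c(rep(TRUE, 13), rep(FALSE, 14))), 48.1,
               tolerance = 0.01)
  expect_error(detection_rate(logical(0)), "sample")
})

test_that("noiseless plates are inverted to the generating copy numbers", {
  cfg <- sim_config(seed = 9)
  cfg$qpcr$p_multi_peak <- 0
  cfg$qpcr$p_bad_efficiency <- 0
  plate <- gen_qpcr_plate(cfg, noiseless = TRUE)
  truth <- attr(plate, "truth")
  ga <- gene_abundance_table(plate)
  m <- merge(ga[ga$detected, ], truth, by = c("sample", "gene"))
  expect_gt(nrow(m), 200)
  expect_equal(m$gamma, m$gamma_true, tolerance = 1e-9)
  ref <- truth$gamma_true[truth$gene == "16S"][1]
  expect_equal(m$rel_abundance, m$gamma_true / ref, tolerance = 1e-9)
})

test_that("planted QC failures are recovered by the filter", {
  cfg <- sim_config(seed = 13)
  cfg$qpcr$p_multi_peak <- 0.1
  cfg$qpcr$p_bad_efficiency <- 0.1
  plate <- gen_qpcr_plate(cfg)
  planted <- attr(plate, "planted_qc")
  out <- qc_filter(plate)
  expect_equal(nrow(out), sum(!planted))
  log <- attr(out, "qc_log")
  expect_equal(sum(log$n[log$reason != "retained"]), sum(planted))
})

test_that("class aggregation is additive and recovers the planted circuit ordering", {
  cfg <- sim_config(seed = 17)
  ga <- suppressWarnings(gene_abundance_table(gen_qpcr_plate(cfg)))
  single <- aggregate_class(ga, "Tn24")
  expect_equal(unname(single),
               ga$rel_abundance[ga$gene == "Tn24"][order(ga$sample[ga$gene == "Tn24"])])
  a <- aggregate_class(ga, c("Tn21", "Tn24"))
  b <- aggregate_class(ga, c("Tn25", "cIntI1"))
  both <- aggregate_class(ga, c("Tn21", "Tn24", "Tn25", "cIntI1"))
  expect_equal(a + b, both)
  # planted ordering: closed < open < non-electrode circuit groups
  grp <- substr(names(both), 2, 2)
  m <- tapply(both, grp, mean)
  expect_true(m[["C"]] < m[["O"]] && m[["O"]] < m[["N"]])
  expect_error(aggregate_class(ga, "nope"), "not present")
})
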