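#' Shannon diversity index
#'
#' H = -sum p_i log p_i over taxa with p_i > 0. Natural logarithm by
#' default (the dominant convention); any base can be requested.
#' Delegates to [vegan::diversity()].
#'
#' @param counts non-negative counts (or relative abundances) of one sample.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index H.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero sample")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1)) by default, with
#' F1 the singleton and F2 the doubleton count; this form is defined even
#' without doubletons. The classical form S_obs + F1^2 / (2 F2) is
#' available and returns `NaN` (with a warning) when F2 = 0.
#'
#' @param counts integer counts of one sample (relative abundances are
#'   rejected: the estimator needs singleton/doubleton counts).
#' @param bias_corrected use the bias-corrected form (default `TRUE`).
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("Chao1 requires integer counts")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0 && f1 > 0) {
      warning("no doubletons: classical Chao1 undefined")
      return(NaN)
    }
    if (f1 == 0) return(s_obs)
    s_obs + f1^2 / (2 * f2)
  }
}

#' Good's coverage estimator
#'
#' 1 - F1/N: the estimated probability that the next read belongs to an
#' already-observed taxon.
#'
#' @param counts integer counts of one sample (total > 0).
#' @return Coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("coverage requires integer counts")
  n <- sum(counts)
  if (n <= 0) stop("all-zero sample")
  1 - sum(round(counts) == 1) / n
}

#' Per-sample alpha-diversity table
#'
#' Observed richness, Shannon, Chao1 and Good's coverage for every sample
#' column of an abundance table, optionally after rarefying all samples to
#' the minimum depth.
#'
#' @param table abundance table: data frame with `taxon`, `kingdom`,
#'   `lineage` columns followed by one numeric column per sample (see
#'   [read_abundance_table()]), or a bare taxa x samples numeric matrix.
#' @param rarefy rarefy all samples to the minimum column sum first
#'   (default `FALSE`; indices are otherwise computed on the given counts).
#' @param seed seed for the rarefaction draw.
#' @return Data frame: `sample`, `richness`, `shannon`, `chao1`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(table, rarefy = FALSE, seed = 1L) {
  m <- abundance_matrix(table)
  if (rarefy) {
    set.seed(seed)
    m <- t(vegan::rrarefy(t(m), min(colSums(m))))
  }
  data.frame(
    sample = colnames(m),
    richness = apply(m, 2, function(x) sum(x > 0)),
    shannon = apply(m, 2, shannon),
    chao1 = apply(m, 2, chao1),
    goods_coverage = apply(m, 2, goods_coverage),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the numeric taxa x samples matrix of an abundance table
#'
#' @param table abundance data frame (metadata columns `taxon`, `kingdom`,
#'   `lineage`) or an already-numeric matrix.
#' @return Numeric matrix, rownames = taxa, colnames = samples.
#' @export
abundance_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  meta <- intersect(c("taxon", "kingdom", "lineage"), names(table))
  m <- as.matrix(table[setdiff(names(table), meta)])
  if (!is.numeric(m)) stop("sample columns must be numeric")
  if (any(m < 0)) stop("negative abundances")
  rownames(m) <- if ("taxon" %in% names(table)) table$taxon else rownames(table)
  m
}

#' Aggregate an abundance table at a taxonomic rank
#'
#' Sums counts per taxon at the requested rank of the lineage string
#' (format `"phylum;class;order;family;genus"`), then keeps the `top_n`
#' taxa per kingdom by mean relative abundance, lumping the remainder into
#' `"other"`. Default `top_n` follows the reporting convention of 55
#' bacterial, 35 fungal and 15 archaeal genera. Column sums are conserved
#' exactly.
#'
#' @param table abundance data frame with `taxon`, `kingdom`, `lineage`
#'   plus sample columns.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @param top_n named list of per-kingdom cutoffs, or a single number, or
#'   `Inf` to keep everything.
#' @return Aggregated abundance data frame in the same format.
#' @export
aggregate_taxonomy <- function(table, rank = "genus",
                               top_n = list(bacteria = 55, fungi = 35,
                                            archaea = 15)) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  idx <- match(rank, ranks)
  parts <- strsplit(table$lineage, ";", fixed = TRUE)
  at_rank <- vapply(parts, function(p) if (length(p) >= idx) p[idx] else NA_character_,
                    character(1))
  if (all(is.na(at_rank))) stop("rank absent from all lineages")
  lin_to <- vapply(parts, function(p)
    paste(p[seq_len(min(idx, length(p)))], collapse = ";"), character(1))
  m <- abundance_matrix(table)
  key <- paste(table$kingdom, at_rank, lin_to, sep = "|")
  agg <- rowsum(m, key)
  kingdoms <- sub("\\|.*$", "", rownames(agg))
  names_at <- sub("\\|[^|]*$", "", rownames(agg))
  lineages <- sub("^.*\\|", "", rownames(agg))
  names_at <- sub("^[^|]*\\|", "", names_at)

  out <- NULL
  for (kg in unique(kingdoms)) {
    sel <- kingdoms == kg
    sub <- agg[sel, , drop = FALSE]
    cutoff <- if (is.list(top_n)) top_n[[kg]] else top_n
    if (is.null(cutoff)) cutoff <- Inf
    rel <- sweep(sub, 2, pmax(colSums(agg), 1e-300), "/")
    ord <- order(rowMeans(rel), decreasing = TRUE)
    keep <- head(ord, cutoff)
    rest <- setdiff(ord, keep)
    block <- sub[keep, , drop = FALSE]
    nm <- names_at[sel][keep]
    lin <- lineages[sel][keep]
    if (length(rest) > 0L) {
      block <- rbind(block, colSums(sub[rest, , drop = FALSE]))
      nm <- c(nm, "other")
      lin <- c(lin, "other")
    }
    out <- rbind(out, data.frame(taxon = nm, kingdom = kg,
                                 lineage = lin, block,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE))
  }
  rownames(out) <- NULL
  out
}
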