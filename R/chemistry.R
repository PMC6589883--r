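#' Antibiotic removal efficiency
#'
#' beta = (C' - C) / C' * 100, where C' is the spiked concentration of the
#' original soil and C the residual at the end of the experiment (both
#' mg kg^-1). A residual above the spike is allowed (negative beta) but
#' warned about.
#'
#' @param spike_C0 spiked concentration C', mg kg^-1 (> 0).
#' @param residual_C residual concentration C, mg kg^-1 (>= 0).
#' @return Removal efficiency in percent (vectorized).
#' @export
removal_efficiency <- function(spike_C0, residual_C) {
  if (any(spike_C0 <= 0)) stop("spike concentration must be > 0")
  if (any(residual_C < 0)) stop("residual concentration must be >= 0")
  if (any(residual_C > spike_C0))
    warning("residual exceeds spike: negative removal efficiency")
  (spike_C0 - residual_C) / spike_C0 * 100
}

#' One-way ANOVA
#'
#' Classical between/within decomposition for >= 2 groups with replicate
#' observations; p-value from the F distribution. Returns the mean square
#' error and residual degrees of freedom needed by [duncan_letters()].
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor), same length as `values`.
#' @return A list: `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `means` (named group means), `n` (named group sizes). With zero
#'   within-group variance and equal means, `F` and `p` are `NaN`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 replicates per group")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"],
       ms_within = tab[2, "Mean Sq"],
       means = tapply(values, groups, mean),
       n = tapply(values, groups, length))
}

# Least significant ranges for Duncan's multiple range test.
# Protection level for a span of p means: alpha_p = 1 - (1 - alpha)^(p - 1);
# the critical value is the studentized-range quantile at that level.
duncan_lsr <- function(k, df, ms_within, n_harmonic, alpha = 0.05) {
  p <- 2:k
  q <- suppressWarnings(qtukey((1 - alpha)^(p - 1), p, df))
  q[is.nan(q)] <- Inf   # quantile overflow as alpha_p -> 0: nothing separates
  lsr <- q * sqrt(ms_within / n_harmonic)
  lsr[is.nan(lsr)] <- Inf
  setNames(lsr, p)
}

#' Duncan's multiple range test with compact letter display
#'
#' Ranks the group means, computes least significant ranges from
#' studentized-range quantiles at Duncan's protection levels
#' alpha_p = 1 - (1 - alpha)^(p - 1), and applies the standard
#' range-testing rule: a range of means is declared non-significant when
#' its spread is within the least significant range for its span, and any
#' range contained in a non-significant range is itself non-significant.
#' Letters are assigned so that groups sharing no letter differ at `alpha`.
#'
#' For unbalanced designs the harmonic mean of group sizes is used in the
#' standard error.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level (default 0.05).
#' @return A data frame (one row per group, sorted by decreasing mean) with
#'   `group`, `mean`, `n`, `letters`.
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) == 1L) {
    return(data.frame(group = levels(groups),
                      mean = mean(values), n = length(values),
                      letters = "a", stringsAsFactors = FALSE))
  }
  av <- anova_oneway(values, groups)
  k <- length(av$means)
  ord <- order(av$means, decreasing = TRUE)
  m <- av$means[ord]
  nh <- 1 / mean(1 / av$n)  # harmonic mean group size
  lsr <- duncan_lsr(k, av$df_within, av$ms_within, nh, alpha)

  # ns[i, j]: means ranked i..j (descending) not significantly different.
  ns <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (ns[i, j]) next  # shadowed by an enclosing non-significant range
      if (m[i] - m[j] <= lsr[as.character(span)]) {
        for (a in i:j) for (b in a:j) ns[a, b] <- TRUE
      }
    }
  }
  letters_str <- cld_from_ns(ns)
  data.frame(group = names(m), mean = unname(m),
             n = unname(av$n[ord]), letters = letters_str,
             stringsAsFactors = FALSE)
}

# Compact letter display from an upper-triangular non-significance matrix
# over means sorted in decreasing order. Because non-significant ranges are
# intervals in rank order, the display is the set of maximal intervals
# [a, b] with ns[a, b]; each gets one letter.
cld_from_ns <- function(ns) {
  k <- nrow(ns)
  reach <- vapply(seq_len(k), function(a) max(which(ns[a, ])), integer(1))
  # maximal intervals: drop any [a, reach(a)] contained in an earlier one
  ivals <- list()
  best_end <- 0L
  for (a in seq_len(k)) {
    b <- reach[a]
    if (b > best_end || length(ivals) == 0L) {
      ivals[[length(ivals) + 1L]] <- c(a, b)
      best_end <- b
    }
  }
  lab <- rep("", k)
  for (ix in seq_along(ivals)) {
    rng <- ivals[[ix]]
    for (g in rng[1]:rng[2]) lab[g] <- paste0(lab[g], letters[ix])
  }
  lab
}

#' Removal summary table
#'
#' Per treatment x layer means, standard deviations and removal
#' efficiencies, plus the treatment-average degradation rate (the removal
#' efficiency of the mean residual across layers) with Duncan letters
#' comparing treatments within each analyte.
#'
#' @param conc data frame with columns `treatment`, `layer`, `replicate`,
#'   `analyte`, `concentration_mg_kg`, `spike_mg_kg` (see
#'   [read_concentrations()]).
#' @param alpha significance level for the letters.
#' @return A list of two data frames: `by_layer` and `by_treatment`.
#' @export
removal_summary <- function(conc, alpha = 0.05) {
  need <- c("treatment", "layer", "replicate", "analyte",
            "concentration_mg_kg", "spike_mg_kg")
  if (!all(need %in% names(conc))) stop("missing concentration columns")
  spl <- split(conc, conc[c("layer", "treatment", "analyte")], drop = TRUE)
  by_layer <- do.call(rbind, lapply(spl, function(d) {
    data.frame(analyte = d$analyte[1], treatment = d$treatment[1],
               layer = d$layer[1],
               mean_mg_kg = mean(d$concentration_mg_kg),
               sd_mg_kg = sd(d$concentration_mg_kg),
               removal_pct = removal_efficiency(d$spike_mg_kg[1],
                                                mean(d$concentration_mg_kg)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_layer) <- NULL

  by_treatment <- do.call(rbind, lapply(
    split(conc, conc$analyte), function(d) {
      # replicate-level residuals averaged over layers -> per-replicate beta
      agg <- tapply(d$concentration_mg_kg,
                    list(d$treatment, d$replicate), mean)
      betas <- removal_efficiency(d$spike_mg_kg[1], as.vector(agg))
      trt <- rep(rownames(agg), times = ncol(agg))
      keep <- !is.na(betas)
      led <- duncan_letters(betas[keep], trt[keep], alpha)
      data.frame(analyte = d$analyte[1], treatment = led$group,
                 removal_pct = led$mean, letters = led$letters,
                 stringsAsFactors = FALSE)
    }))
  rownames(by_treatment) <- NULL
  list(by_layer = by_layer, by_treatment = by_treatment)
}
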