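# Independent reference implementations used to cross-check the package.
# These deliberately share no code with R/: the Duncan oracle applies the
# range-test definition directly, the MCODE oracle works on bitmask
# adjacency with exhaustive subset enumeration, and the Spearman oracle is
# a Monte-Carlo permutation test.

# ---- Duncan multiple range test, definitional route ----
# A pair of means is non-significant iff SOME enclosing range of the
# sorted means (including the pair's own range) has spread within the
# least significant range for its span. Letters are the maximal
# non-significant intervals of the sorted means.
oracle_duncan <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  means <- tapply(values, g, mean)
  n <- tapply(values, g, length)
  fit <- lm(values ~ g)
  ms <- sum(resid(fit)^2) / fit$df.residual
  dfree <- fit$df.residual
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  nh <- 1 / mean(1 / n)
  lsr <- vapply(2:k, function(p)
    qtukey((1 - alpha)^(p - 1), p, dfree) * sqrt(ms / nh), numeric(1))
  pair_ns <- function(i, j) {
    for (a in seq_len(i)) for (b in j:k)
      if (b > a && m[a] - m[b] <= lsr[b - a]) return(TRUE)
    i == j
  }
  reach <- vapply(seq_len(k), function(a) {
    b <- a
    for (j in seq_len(k)[-seq_len(a)]) if (pair_ns(a, j)) b <- j
    b
  }, numeric(1))
  # reach is monotone; letter intervals are the maximal [a, reach(a)]
  lab <- rep("", k)
  li <- 0L
  last_end <- 0L
  for (a in seq_len(k)) {
    if (reach[a] > last_end || a == 1L) {
      li <- li + 1L
      lab[a:reach[a]] <- paste0(lab[a:reach[a]], letters[li])
      last_end <- reach[a]
    }
  }
  data.frame(group = names(m), mean = unname(m), letters = lab,
             stringsAsFactors = FALSE)
}

# ---- MCODE on bitmask adjacency, exhaustive subset enumeration ----
bit_of <- function(v) bitwShiftL(1L, v - 1L)
popcount <- function(mask, n) sum(bitwAnd(mask, bit_of(seq_len(n))) != 0L)
mask_members <- function(mask, n) which(bitwAnd(mask, bit_of(seq_len(n))) != 0L)

# adjacency masks from an igraph object (vertices 1..n)
adj_masks <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  nbr <- integer(n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    nbr[a] <- bitwOr(nbr[a], bit_of(b))
    nbr[b] <- bitwOr(nbr[b], bit_of(a))
  }
  nbr
}

mask_edges <- function(nbr, mask, n) {
  sum(vapply(mask_members(mask, n),
             function(v) popcount(bitwAnd(nbr[v], mask), n), numeric(1))) / 2
}

mask_connected <- function(nbr, mask, n, start) {
  reach <- bit_of(start)
  repeat {
    nxt <- reach
    for (v in mask_members(reach, n))
      nxt <- bitwOr(nxt, bitwAnd(nbr[v], mask))
    if (nxt == reach) break
    reach <- nxt
  }
  reach == mask
}

# iteratively prune vertices of within-subset degree < k
mask_core <- function(nbr, mask, n, k) {
  repeat {
    drop <- 0L
    for (v in mask_members(mask, n))
      if (popcount(bitwAnd(nbr[v], mask), n) < k) drop <- bitwOr(drop, bit_of(v))
    if (drop == 0L) break
    mask <- bitwAnd(mask, bitwNot(drop))
    if (mask == 0L) break
  }
  mask
}

oracle_mcode_weights <- function(nbr, n) {
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (nbr[v] == 0L) next
    nh <- bitwOr(nbr[v], bit_of(v))
    k <- 0L
    core <- nh
    repeat {
      nxt <- mask_core(nbr, nh, n, k + 1L)
      if (nxt == 0L) break
      k <- k + 1L
      core <- nxt
    }
    m <- popcount(core, n)
    dens <- if (m > 1) mask_edges(nbr, core, n) / (m * (m - 1) / 2) else 0
    w[v] <- k * dens
  }
  w
}

# Full oracle: seeds in descending weight (name ties lexicographic),
# per-seed module found by exhaustive enumeration over subsets of the
# admissible unassigned vertices (largest connected subset containing the
# seed), then k-core filter, haircut and density x size scoring.
oracle_mcode <- function(g, degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE) {
  n <- igraph::vcount(g)
  nbr <- adj_masks(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  w <- oracle_mcode_weights(nbr, n)
  deg <- vapply(seq_len(n), function(v) popcount(nbr[v], n), numeric(1))
  assigned <- 0L
  mods <- list()
  for (s in order(-w, nm)) {
    if (bitwAnd(assigned, bit_of(s)) != 0L || deg[s] < degree_cutoff) next
    avail <- bit_of(s)
    for (v in seq_len(n))
      if (v != s && bitwAnd(assigned, bit_of(v)) == 0L &&
          w[v] >= w[s] * (1 - node_score_cutoff))
        avail <- bitwOr(avail, bit_of(v))
    # enumerate submasks of avail containing s; keep the largest connected
    best <- bit_of(s)
    best_size <- 1L
    sub <- avail
    repeat {
      if (bitwAnd(sub, bit_of(s)) != 0L && popcount(sub, n) > best_size &&
          mask_connected(nbr, sub, n, s)) {
        best <- sub
        best_size <- popcount(sub, n)
      }
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, avail)
    }
    assigned <- bitwOr(assigned, best)
    # finalize
    if (popcount(best, n) < 2L) next
    if (mask_core(nbr, best, n, k_core) == 0L) next
    mod <- best
    if (haircut) {
      for (v in mask_members(best, n))
        if (popcount(bitwAnd(nbr[v], best), n) < 2)
          mod <- bitwAnd(mod, bitwNot(bit_of(v)))
    }
    msize <- popcount(mod, n)
    if (msize < 2L) next
    dens <- mask_edges(nbr, mod, n) / (msize * (msize - 1) / 2)
    mods[[length(mods) + 1L]] <- list(
      members = sort(nm[mask_members(mod, n)]),
      score = dens * msize, seed = nm[s])
  }
  ord <- order(-vapply(mods, `[[`, numeric(1), "score"),
               vapply(mods, `[[`, character(1), "seed"))
  mods[ord]
}

# ---- Monte-Carlo permutation p-value for Spearman's rho ----
oracle_spearman_p <- function(x, y, B = 2000, seed = 7) {
  set.seed(seed)
  obs <- abs(cor(x, y, method = "spearman"))
  perm <- replicate(B, abs(cor(x, sample(y), method = "spearman")))
  (1 + sum(perm >= obs - 1e-12)) / (B + 1)
}

# shorthand: undirected edge keys
edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))
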