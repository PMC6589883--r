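#' MCODE node weights
#'
#' For each node v, take the induced subgraph on the closed neighborhood
#' N\[v\], find its highest k-core, and set
#' weight(v) = k * density(highest k-core). Isolated nodes get weight 0.
#'
#' @param net an `igraph` object.
#' @return Named numeric vector of node weights.
#' @export
mcode_weights <- function(net) {
  stopifnot(igraph::is_igraph(net))
  nm <- igraph::V(net)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(net)))
    igraph::V(net)$name <- nm
  }
  w <- setNames(numeric(length(nm)), nm)
  for (v in seq_along(nm)) {
    nb <- igraph::neighbors(net, v)
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(net, c(v, nb))
    core <- igraph::coreness(sub)
    k <- max(core)
    hc <- igraph::induced_subgraph(sub, which(core == k))
    w[v] <- k * igraph::edge_density(hc)
  }
  w
}

#' MCODE module detection
#'
#' Reimplementation of the molecular-complex-detection algorithm used for
#' dense-submodule discovery in co-occurrence networks, with the published
#' standard parameters as defaults. Node weights combine the highest
#' k-core of each node's closed neighborhood with its density
#' ([mcode_weights()]); seeds are processed in descending weight (ties
#' broken lexicographically by node name for determinism); a module grows
#' from its seed by admitting every reachable, still unassigned neighbor
#' whose weight is at least `(1 - node_score_cutoff)` times the seed
#' weight, up to `max_depth` steps from the seed. Modules not containing a
#' `k_core`-core are discarded; `haircut` then prunes members left with
#' fewer than two within-module neighbors. The module score is
#' density x size; modules are returned in decreasing score.
#'
#' @param net an `igraph` object (>= 1 edge for any module to exist).
#' @param degree_cutoff minimum degree for a node to seed or join a module.
#' @param node_score_cutoff admission slack relative to the seed weight.
#' @param k_core minimum core a module must contain.
#' @param max_depth maximum distance from the seed during expansion.
#' @param haircut prune singly-connected module members (default `TRUE`).
#' @param fluff unsupported flag kept for interface compatibility; must be
#'   `FALSE`.
#' @return A list of modules, each a list with `members` (character),
#'   `seed`, `score`, `density`, `size`; classed `mcode_result`.
#' @export
mcode <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE,
                  fluff = FALSE) {
  stopifnot(igraph::is_igraph(net))
  if (isTRUE(fluff)) stop("fluff expansion is not implemented")
  if (igraph::ecount(net) == 0L)
    return(structure(list(), class = "mcode_result"))
  if (is.null(igraph::V(net)$name))
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  nm <- igraph::V(net)$name
  w <- mcode_weights(net)
  deg <- igraph::degree(net)
  seeds <- order(-w, nm)                       # descending weight, name ties
  seeds <- seeds[deg[seeds] >= degree_cutoff]
  assigned <- rep(FALSE, length(nm))
  adj <- igraph::as_adj_list(net)

  modules <- list()
  for (s in seeds) {
    if (assigned[s]) next
    thresh <- w[s] * (1 - node_score_cutoff)
    members <- s
    depth <- setNames(0L, s)
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (v in frontier) {
        if (depth[as.character(v)] >= max_depth) next
        for (u in as.integer(adj[[v]])) {
          if (assigned[u] || u %in% members) next
          if (w[u] >= thresh) {
            members <- c(members, u)
            depth[as.character(u)] <- depth[as.character(v)] + 1L
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    assigned[members] <- TRUE
    mod <- finalize_module(net, members, k_core, haircut)
    if (!is.null(mod)) {
      mod$seed <- nm[s]
      modules[[length(modules) + 1L]] <- mod
    }
  }
  ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
               vapply(modules, `[[`, character(1), "seed"))
  structure(modules[ord], class = "mcode_result")
}

# k-core filter + haircut + scoring shared by mcode() and its tests
finalize_module <- function(net, members, k_core, haircut) {
  sub <- igraph::induced_subgraph(net, members)
  if (igraph::vcount(sub) < 2L) return(NULL)
  if (max(igraph::coreness(sub)) < k_core) return(NULL)
  if (haircut) {
    keep <- igraph::degree(sub) >= 2
    sub <- igraph::induced_subgraph(sub, which(keep))
  }
  n <- igraph::vcount(sub)
  if (n < 2L) return(NULL)
  dens <- igraph::edge_density(sub)
  list(members = sort(igraph::V(sub)$name), score = dens * n,
       density = dens, size = n)
}

#' @export
print.mcode_result <- function(x, ...) {
  cat("<mcode_result>", length(x), "module(s)\n")
  for (i in seq_along(x)) {
    cat(sprintf("  %d. score %.3f, %d nodes (seed %s): %s\n", i,
                x[[i]]$score, x[[i]]$size, x[[i]]$seed,
                paste(x[[i]]$members, collapse = ", ")))
  }
  invisible(x)
}
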