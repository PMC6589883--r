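#' Spearman rank-correlation matrix with p-values
#'
#' All pairwise Spearman correlations within (and, when a gene table is
#' given, between) microbial taxa and target genes. Ties are handled by
#' mid-ranks. Two-sided p-values come from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) by default; for fewer than 10
#' samples the exact permutation distribution is used instead
#' (via [stats::cor.test()]).
#'
#' @param table abundance table (data frame, see [abundance_matrix()]) or
#'   features x samples matrix.
#' @param gene_table optional second features x samples table (e.g.
#'   normalized gene abundances) with matching sample columns; its rows are
#'   appended to the feature set.
#' @param p_method `"auto"` (exact permutation when n < 10, else t
#'   approximation), `"t"`, or `"exact"`.
#' @return List with `rho` and `p` matrices (features x features, diagonal
#'   p = NA) and the sample count `n`.
#' @export
spearman_matrix <- function(table, gene_table = NULL,
                            p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  m <- abundance_matrix(table)
  if (!is.null(gene_table)) {
    g <- abundance_matrix(gene_table)
    if (ncol(g) != ncol(m) || !all(colnames(g) == colnames(m)))
      stop("sample columns of the two tables must match")
    m <- rbind(m, g)
  }
  n <- ncol(m)
  if (n < 4L) stop("need >= 4 samples")
  v <- apply(m, 1, function(x) diff(range(x)) > 0)
  if (any(!v)) {
    warning("dropping ", sum(!v), " zero-variance feature(s)")
    m <- m[v, , drop = FALSE]
  }
  rho <- cor(t(m), method = "spearman")
  use_exact <- p_method == "exact" || (p_method == "auto" && n < 10L)
  if (use_exact) {
    k <- nrow(m)
    p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      pv <- suppressWarnings(
        cor.test(m[i, ], m[j, ], method = "spearman", exact = TRUE)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  } else {
    r <- rho
    diag(r) <- 0
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p[abs(r) >= 1] <- 0
    diag(p) <- NA_real_
  }
  list(rho = rho, p = p, n = n)
}

#' Build a co-occurrence network from correlation matrices
#'
#' Draws an undirected edge for every off-diagonal feature pair whose
#' (optionally multiplicity-adjusted) p-value is below `alpha`; each edge
#' carries rho, p and its sign. Following the source analysis convention,
#' no magnitude threshold and no multiple-testing correction are applied
#' by default; both are available.
#'
#' @param rho,p square correlation and p-value matrices (or the list
#'   returned by [spearman_matrix()] as `rho`, with `p` missing).
#' @param alpha edge significance level (default 0.05).
#' @param p_adjust method passed to [stats::p.adjust()] over the upper
#'   triangle (default `"none"`; e.g. `"BH"`, `"bonferroni"`). A note is
#'   emitted either way.
#' @param rho_min minimum `|rho|` for an edge (default 0 = off).
#' @param abundance optional named vector of node mean abundances.
#' @param node_meta optional data frame (`node`, plus e.g. `kingdom` or
#'   `gene_class`) of node annotations.
#' @return An `igraph` object; edge attributes `rho`, `p`, `sign`.
#' @export
build_network <- function(rho, p, alpha = 0.05, p_adjust = "none",
                          rho_min = 0, abundance = NULL, node_meta = NULL) {
  if (is.list(rho) && missing(p)) {
    p <- rho$p
    rho <- rho$rho
  }
  stopifnot(all(dim(rho) == dim(p)))
  k <- nrow(rho)
  nodes <- rownames(rho)
  if (is.null(nodes)) nodes <- paste0("f", seq_len(k))
  ut <- upper.tri(p)
  padj <- p
  padj[ut] <- p.adjust(p[ut], method = p_adjust)
  if (p_adjust == "none") {
    message("note: raw p-values used for edge calls (no multiple-testing correction)")
  }
  sel <- which(ut & padj < alpha & abs(rho) >= rho_min, arr.ind = TRUE)
  edges <- data.frame(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                      rho = rho[sel], p = padj[sel],
                      sign = ifelse(rho[sel] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(abundance))
    igraph::V(g)$abundance <- unname(abundance[nodes])
  if (!is.null(node_meta)) {
    for (col in setdiff(names(node_meta), "node"))
      igraph::vertex_attr(g, col) <-
        node_meta[[col]][match(nodes, node_meta$node)]
  }
  g
}

#' Keystone filter
#'
#' The two-step filter used to isolate putative keystone (functional)
#' taxa: (1) remove every negative edge; (2) remove every node whose mean
#' abundance in the treatment is not higher than in the matched
#' non-antibiotic control. Nodes without a control abundance are dropped
#' with a warning. Isolated nodes are dropped by default.
#'
#' @param net an `igraph` co-occurrence network with edge attribute `sign`.
#' @param treatment_abundance,control_abundance named numeric vectors of
#'   mean abundances per node.
#' @param drop_isolated drop nodes left without edges (default `TRUE`).
#' @return The filtered `igraph` subgraph.
#' @export
keystone_filter <- function(net, treatment_abundance, control_abundance,
                            drop_isolated = TRUE) {
  stopifnot(igraph::is_igraph(net))
  g <- igraph::delete_edges(net, igraph::E(net)[igraph::E(net)$sign == "negative"])
  nm <- igraph::V(g)$name
  missing_ctrl <- !(nm %in% names(control_abundance))
  if (any(missing_ctrl))
    warning("dropping ", sum(missing_ctrl), " node(s) without control abundance")
  enriched <- !missing_ctrl &
    unname(treatment_abundance[nm] > control_abundance[nm])
  enriched[is.na(enriched)] <- FALSE
  g <- igraph::induced_subgraph(g, which(enriched))
  if (drop_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

#' Network topology report
#'
#' Clustering coefficient (mean local clustering over nodes with degree
#' >= 2), average number of neighbours 2E/N, density 2E/(N(N-1)), the
#' number of shortest paths (count of ordered connected pairs, the
#' convention of common network viewers) and the characteristic path
#' length (mean geodesic over connected pairs), plus node/edge counts and
#' the positive-edge fraction.
#'
#' @param net an `igraph` object (edge attribute `sign` optional).
#' @return One-row data frame of topology parameters.
#' @export
topology <- function(net) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n == 0L) {
    return(data.frame(n_nodes = 0L, n_edges = 0L, clustering = NA_real_,
                      avg_neighbors = NA_real_, density = NA_real_,
                      shortest_path_pairs = 0L,
                      char_path_length = NA_real_,
                      positive_edge_fraction = NA_real_))
  }
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  deg <- igraph::degree(net)
  clust <- if (any(deg >= 2)) mean(loc[deg >= 2]) else 0
  d <- igraph::distances(net)
  finite_off <- is.finite(d) & row(d) != col(d)
  pos_frac <- if (e > 0 && !is.null(igraph::E(net)$sign))
    mean(igraph::E(net)$sign == "positive") else NA_real_
  data.frame(
    n_nodes = n, n_edges = e, clustering = clust,
    avg_neighbors = 2 * e / n,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    shortest_path_pairs = sum(finite_off),
    char_path_length = if (any(finite_off)) mean(d[finite_off]) else NA_real_,
    positive_edge_fraction = pos_frac)
}

#' Export a co-occurrence network
#'
#' Writes the network as a canonical, byte-stable edge-list TSV
#' (`source`, `target`, `rho`, `p`, `sign`; lexicographically sorted with
#' source < target), as SIF (`source <sign> target`, attribute-free), or
#' as GraphML. Edge-list and GraphML round-trip through [read_network()]
#' to an identical network.
#'
#' @param net `igraph` network with edge attributes `rho`, `p`, `sign`.
#' @param path output file path.
#' @param format `"edgelist"`, `"sif"`, or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(net))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(net, what = "edges")
  if (nrow(el) > 0L) {
    swap <- el$from > el$to
    tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
    el <- el[order(el$from, el$to), , drop = FALSE]
  }
  if (format == "edgelist") {
    iso <- setdiff(igraph::V(net)$name, c(el$from, el$to))
    out <- data.frame(source = el$from, target = el$to,
                      rho = if (nrow(el)) el$rho else numeric(),
                      p = if (nrow(el)) el$p else numeric(),
                      sign = if (nrow(el)) el$sign else character())
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("source", "target", "rho", "p", "sign"),
                     collapse = "\t"), con)
    if (nrow(out) > 0L)
      writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%s", out$source, out$target,
                         out$rho, out$p, out$sign), con)
    if (length(iso) > 0L)
      writeLines(sprintf("%s\t\t\t\t", sort(iso)), con)
  } else {  # sif
    lines <- if (nrow(el) > 0L)
      sprintf("%s\t%s\t%s", el$from, el$sign, el$to) else character()
    iso <- setdiff(igraph::V(net)$name, c(el$from, el$to))
    writeLines(c(lines, sort(iso)), path)
  }
  invisible(path)
}

#' Read back an exported network
#'
#' @param path file written by [export_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return An `igraph` network.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    source = "character", target = "character", rho = "numeric",
    p = "numeric", sign = "character"))
  iso <- d$source[is.na(d$rho) | d$target == ""]
  d <- d[!(is.na(d$rho) | d$target == ""), , drop = FALSE]
  nodes <- sort(unique(c(d$source, d$target, iso)))
  igraph::graph_from_data_frame(
    data.frame(from = d$source, to = d$target, rho = d$rho, p = d$p,
               sign = d$sign, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
}
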