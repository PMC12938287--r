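# Bipartite transfer-entropy networks. Pairs whose T M->F falls inside the
# interquartile band of the condition's pooled TE distribution receive an
# (undirected) edge; the balance of shortest-path betweenness centrality
# between the fibroblast and macrophage parts (the F/M ratio) summarises
# which cell type is topologically central.

#' Quartile edge criterion from pooled TE values
#'
#' The most likely TE values of a condition define its edge band: lower and
#' upper bounds are the first and third quartiles (linear-interpolation
#' quantiles) of the pooled, defined TE entries. The distribution mode
#' (midpoint of the tallest of 20 histogram bins over the value range) is
#' reported as a diagnostic reference point.
#'
#' @param te_values Numeric vector of defined TE entries (NAs dropped).
#' @return A list of class `edge_criterion` with `lower`, `upper`, `mode`
#'   and `n`.
#' @examples
#' edge_criterion(1:8)  # lower 2.75, upper 6.25
#' @export
edge_criterion <- function(te_values) {
  v <- te_values[!is.na(te_values)]
  if (length(v) < 4L) {
    stop("need at least 4 defined TE values to form the quartile criterion",
         call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  if (diff(range(v)) > 0) {
    h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = 21L),
                        plot = FALSE)
    mode <- h$mids[which.max(h$counts)]
  } else {
    mode <- v[1L]
  }
  structure(list(lower = q[1L], upper = q[2L], mode = mode, n = length(v)),
            class = "edge_criterion")
}

#' @export
print.edge_criterion <- function(x, ...) {
  cat(sprintf("<edge_criterion> [%.4g, %.4g] (mode %.4g, n = %d)\n",
              x$lower, x$upper, x$mode, x$n))
  invisible(x)
}

#' Build the bipartite TE network
#'
#' Creates an undirected bipartite graph with one node per macrophage and
#' fibroblast slot; an edge joins (m, f) exactly when the pair's TE is
#' defined and lies within `criterion$lower .. criterion$upper` (inclusive).
#' Isolated slots remain as nodes.
#'
#' @param te_tbl A `te_table` from [pairwise_te()].
#' @param criterion An [edge_criterion()].
#' @return An igraph graph with vertex attributes `name` (`"M<slot>"` /
#'   `"F<slot>"`), `kind` and `type` (bipartite flag), and edge attribute
#'   `te`.
#' @export
build_te_network <- function(te_tbl, criterion) {
  m_slots <- sort(unique(te_tbl$m_slot))
  f_slots <- sort(unique(te_tbl$f_slot))
  nodes <- data.frame(
    name = c(paste0("M", m_slots), paste0("F", f_slots)),
    kind = rep(c("macrophage", "fibroblast"),
               c(length(m_slots), length(f_slots))),
    type = rep(c(FALSE, TRUE), c(length(m_slots), length(f_slots)))
  )
  keep <- which(!is.na(te_tbl$te) &
                  te_tbl$te >= criterion$lower & te_tbl$te <= criterion$upper)
  edges <- data.frame(
    from = sprintf("M%d", as.integer(te_tbl$m_slot[keep])),
    to = sprintf("F%d", as.integer(te_tbl$f_slot[keep])),
    te = te_tbl$te[keep]
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Normalised betweenness centrality per node
#'
#' Shortest-path betweenness on the unweighted graph, normalised by
#' (n - 1)(n - 2) / 2 for n nodes; isolated nodes score 0.
#'
#' @param network An igraph graph from [build_te_network()].
#' @return A tibble (node, kind, betweenness).
#' @export
network_betweenness <- function(network) {
  b <- igraph::betweenness(network, directed = FALSE, normalized = TRUE,
                           weights = NA)
  tibble::tibble(
    node = igraph::V(network)$name,
    kind = igraph::V(network)$kind,
    betweenness = unname(b)
  )
}

#' Fibroblast-to-macrophage centrality ratio
#'
#' F/M: the summed normalised betweenness of fibroblast nodes divided by the
#' summed betweenness of macrophage nodes. Values above 1 indicate topology
#' centred on the fibroblast part (the normal, fully-recovering inflammation
#' course); values below 1 indicate macrophage-centred topology
#' (inflammaging). Undefined (NA) when the macrophage sum is 0.
#'
#' @param network An igraph graph from [build_te_network()], or a
#'   betweenness tibble from [network_betweenness()].
#' @return A single number, or `NA_real_` when undefined.
#' @export
fm_ratio <- function(network) {
  b <- if (inherits(network, "igraph")) network_betweenness(network) else network
  fsum <- sum(b$betweenness[b$kind == "fibroblast"])
  msum <- sum(b$betweenness[b$kind == "macrophage"])
  if (msum == 0) return(NA_real_)
  fsum / msum
}

#' Summarise TE networks for one experimental condition
#'
#' Pools the defined TE entries of all replicate TE tables to form a single
#' quartile edge criterion for the condition, then builds one network and
#' one F/M ratio per replicate.
#'
#' @param te_tables List of `te_table`s, one per replicate.
#' @return A list of class `condition_networks`: `criterion`, `networks`
#'   (list of igraph), `replicates` tibble (replicate, n_edges, f_sum,
#'   m_sum, fm_ratio), `betweenness` (pooled per-node tibble with replicate
#'   column), `mean_fm` and `se_fm` (mean and standard error over replicates
#'   with defined F/M).
#' @export
condition_summary <- function(te_tables) {
  stopifnot(length(te_tables) >= 1L)
  pooled <- unlist(lapply(te_tables, function(x) x$te[!is.na(x$te)]))
  crit <- edge_criterion(pooled)
  networks <- lapply(te_tables, build_te_network, criterion = crit)
  btw <- purrr::imap(networks, function(g, i) {
    dplyr::mutate(network_betweenness(g), replicate = i)
  }) |> purrr::list_rbind()
  reps <- purrr::imap(networks, function(g, i) {
    b <- network_betweenness(g)
    tibble::tibble(
      replicate = i,
      n_edges = igraph::ecount(g),
      f_sum = sum(b$betweenness[b$kind == "fibroblast"]),
      m_sum = sum(b$betweenness[b$kind == "macrophage"]),
      fm_ratio = fm_ratio(b)
    )
  }) |> purrr::list_rbind()
  fm <- reps$fm_ratio[!is.na(reps$fm_ratio)]
  structure(
    list(criterion = crit, networks = networks, replicates = reps,
         betweenness = btw,
         mean_fm = if (length(fm)) mean(fm) else NA_real_,
         se_fm = if (length(fm) > 1L) stats::sd(fm) / sqrt(length(fm)) else 0),
    class = "condition_networks"
  )
}

#' @export
print.condition_networks <- function(x, ...) {
  cat("<condition_networks>\n")
  cat(sprintf("  criterion [%.4g, %.4g] from %d pooled TE values\n",
              x$criterion$lower, x$criterion$upper, x$criterion$n))
  cat(sprintf("  %d replicates, mean F/M = %.3f (se %.3f)\n",
              nrow(x$replicates), x$mean_fm, x$se_fm))
  invisible(x)
}

#' Export a TE network
#'
#' Writes the graph as GraphML and the thresholded pairs as an edge-list TSV
#' (m_slot, f_slot, te).
#'
#' @param network igraph graph from [build_te_network()].
#' @param graphml,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, `NULL`.
#' @export
write_te_network <- function(network, graphml = NULL, tsv = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(network, graphml, format = "graphml")
  }
  if (!is.null(tsv)) {
    e <- igraph::as_data_frame(network, what = "edges")
    utils::write.table(
      data.frame(m_slot = sub("^M", "", e$from),
                 f_slot = sub("^F", "", e$to), te = e$te),
      tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
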