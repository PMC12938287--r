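# Independent brute-force oracles used to cross-check the plug-in
# information estimators and the graph centrality. These deliberately use
# naive explicit loops over the full joint tables / all node pairs, sharing
# no code with the implementations they check.

oracle_entropy <- function(...) {
  x <- do.call(paste, list(...))
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) - oracle_entropy(x, y)
}

# I(X;Y|Z) by direct summation over the joint probability cube
oracle_cmi <- function(x, y, z) {
  n <- length(x)
  total <- 0
  for (zv in unique(z)) {
    sel <- z == zv
    pz <- sum(sel) / n
    xs <- x[sel]; ys <- y[sel]
    for (xv in unique(xs)) for (yv in unique(ys)) {
      pxyz <- sum(xs == xv & ys == yv) / sum(sel)
      if (pxyz > 0) {
        px <- sum(xs == xv) / sum(sel)
        py <- sum(ys == yv) / sum(sel)
        total <- total + pz * pxyz * log2(pxyz / (px * py))
      }
    }
  }
  total
}

# TE source -> target from aligned series, by building the lagged triples
# explicitly and summing Eq-style over the joint table
oracle_te <- function(source, target) {
  n <- length(target)
  oracle_cmi(target[-1], source[-n], target[-n])
}

# Exact betweenness by the pair-composition identity over BFS shortest-path
# counts: sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t).
# adj: symmetric logical/0-1 matrix, no self loops.
oracle_betweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- d
            nxt <- c(nxt, v)
          }
          if (dist[s, v] == d) sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(dist[s, t])) next
      if (dist[s, v] + dist[v, t] == dist[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (normalized) b / ((n - 1) * (n - 2) / 2) else b
}

# small, quick configuration for unit-level simulation tests
tiny_params <- function(...) {
  defaults <- list(stimulus = 0.4, preset = "N", grid_rows = 30L,
                   grid_cols = 30L, n_iterations = 60L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}
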