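# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: dense linear algebra instead of sparse solves,
# igraph instead of the chamfer sweep, exhaustive enumeration instead of
# rank formulas.

# Dense Laplacian pseudo-inverse current solve on a lattice edge list.
dense_current_oracle <- function(graph, s, t) {
  e <- graph$edges
  n <- graph$n_nodes
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(e))) {
    L[e$i[k], e$j[k]] <- L[e$i[k], e$j[k]] - e$conductance[k]
    L[e$j[k], e$i[k]] <- L[e$j[k], e$i[k]] - e$conductance[k]
  }
  diag(L) <- -rowSums(L)
  inj <- numeric(n); inj[s] <- 1; inj[t] <- -1
  v <- drop(MASS::ginv(L) %*% inj)
  ce <- e$conductance * abs(v[e$i] - v[e$j])
  cur <- numeric(n)
  for (k in seq_len(nrow(e))) {
    cur[e$i[k]] <- cur[e$i[k]] + ce[k] / 2
    cur[e$j[k]] <- cur[e$j[k]] + ce[k] / 2
  }
  cur[c(s, t)] <- 1
  list(currents = cur, effective_resistance = v[s] - v[t])
}

# igraph shortest-path distances on the weighted 8-neighbour lattice.
dijkstra_distance_oracle <- function(feature_raster) {
  v <- raster_values(feature_raster)
  nr <- nrow(v); nc <- ncol(v); cs <- feature_raster$cell_size
  id <- function(r, c) (r - 1) * nc + c
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1)); w <- c(w, cs) }
    if (r < nr) { from <- c(from, id(r, c)); to <- c(to, id(r + 1, c)); w <- c(w, cs) }
    if (r < nr && c < nc) { from <- c(from, id(r, c)); to <- c(to, id(r + 1, c + 1)); w <- c(w, sqrt(2) * cs) }
    if (r < nr && c > 1) { from <- c(from, id(r, c)); to <- c(to, id(r + 1, c - 1)); w <- c(w, sqrt(2) * cs) }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  feats <- which(t(v) == 1)
  d <- igraph::distances(g, v = feats)
  apply(d, 2, min)[seq_len(nr * nc)]
}

# Exhaustive presence/absence pair counting AUC.
pairwise_auc_oracle <- function(pred, truth) {
  pos <- pred[truth == 1]; neg <- pred[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Count of connected components of the cells where mask is TRUE
# (8-connectivity via igraph).
component_count_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(t(mask))
  if (length(cells) == 0) return(0)
  idx <- match(seq_len(nr * nc), cells)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    a <- (r - 1) * nc + c
    for (d in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2]) {
        from <- c(from, idx[a]); to <- c(to, idx[(r2 - 1) * nc + c2])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$no
}

# Small uniform / random resistance fixtures shared across circuit tests.
uniform_raster <- function(nr, nc, value = 1, cell_size = 1)
  cs_raster(matrix(value, nr, nc), cell_size = cell_size)

random_resistance <- function(nr, nc, seed, lo = 1, hi = 50) {
  set.seed(seed)
  cs_raster(matrix(runif(nr * nc, lo, hi), nr, nc))
}

# Layer values at occurrence locations (direct matrix indexing).
extract_at <- function(stack, occ, layer) {
  rc <- point_to_cell(stack$layers[[1]], occ$x, occ$y)
  raster_values(stack$layers[[layer]])[cbind(rc$row, rc$col)]
}
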