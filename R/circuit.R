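#' @title Circuit-theory connectivity solver
#' @description A from-scratch raster circuit model: the resistance surface
#'   becomes an 8-neighbour resistor lattice, current is injected between
#'   many perimeter node pairs by solving the reduced graph-Laplacian
#'   system, and per-cell currents are accumulated over all pairs
#'   (omnidirectional flow). A uniform-resistance null model removes the
#'   geometric bias that node placement and landscape shape impose.
#' @name circuit
NULL

#' Pad a resistance surface with an empirically sampled buffer
#'
#' Adds `ceil(fraction * max(n_rows, n_cols))` cells on every side, filled
#' by sampling with replacement from the empirical distribution of the core
#' raster's (non-nodata) values. Placing current-injection nodes on this
#' buffer, rather than the core edge, keeps node-proximity artefacts out of
#' the study extent; the empirical fill avoids biasing flow through an
#' artificially cheap or expensive frame.
#'
#' @param resistance core `cs_raster`.
#' @param fraction buffer width as a fraction of the larger grid dimension.
#' @param seed integer RNG seed for the buffer fill.
#' @return buffered `cs_raster` with attribute `buffer_width` (cells).
#' @export
add_buffer <- function(resistance, fraction = 0.20, seed = 1) {
  if (fraction <= 0) stop("buffer fraction must be positive")
  v <- resistance$values
  pool <- v[!is.na(v)]
  if (length(pool) == 0) stop("add_buffer: core raster is empty")
  nr <- nrow(v); nc <- ncol(v)
  w <- as.integer(ceiling(fraction * max(nr, nc)))
  out <- matrix(NA_real_, nr + 2 * w, nc + 2 * w)
  n_buf <- length(out) - length(v)
  fill <- with_seed(seed, sample(pool, n_buf, replace = TRUE))
  out[] <- NA
  out[(w + 1):(w + nr), (w + 1):(w + nc)] <- NA  # core placed below
  buf_mask <- matrix(TRUE, nrow(out), ncol(out))
  buf_mask[(w + 1):(w + nr), (w + 1):(w + nc)] <- FALSE
  out[buf_mask] <- fill
  out[(w + 1):(w + nr), (w + 1):(w + nc)] <- v
  res <- cs_raster(out, cell_size = resistance$cell_size,
                   origin = resistance$origin - w * resistance$cell_size,
                   nodata = resistance$nodata)
  attr(res, "buffer_width") <- w
  res
}

#' Crop a buffered map back to the core extent
#'
#' @param map `cs_raster` produced on a buffered grid.
#' @param buffer_width the width (cells) added by [add_buffer()].
#' @return `cs_raster` restricted to the core window.
#' @export
crop_buffer <- function(map, buffer_width) {
  w <- as.integer(buffer_width)
  if (w == 0) return(map)
  v <- map$values
  if (2 * w >= nrow(v) || 2 * w >= ncol(v))
    stop("buffer width does not match the raster dimensions")
  core <- v[(w + 1):(nrow(v) - w), (w + 1):(ncol(v) - w), drop = FALSE]
  cs_raster(core, cell_size = map$cell_size,
            origin = map$origin + w * map$cell_size, nodata = map$nodata)
}

#' Evenly spaced perimeter terminal nodes
#'
#' `n` cells on the outermost ring of the raster, evenly spaced by perimeter
#' arc position starting from a seeded random offset, so repeated runs with
#' different seeds rotate the node set around the landscape.
#'
#' @param buffered `cs_raster` (typically the buffered resistance surface).
#' @param n number of terminals (>= 2).
#' @param seed integer RNG seed for the rotational offset.
#' @return integer vector of row-major cell indices, class `cs_nodes`, with
#'   attribute `rc` (row/col matrix).
#' @export
place_nodes <- function(buffered, n = 25, seed = 1) {
  if (n < 2) stop("need at least two terminals")
  nr <- nrow(buffered$values); nc <- ncol(buffered$values)
  # perimeter ring, clockwise from the north-west corner
  ring <- rbind(
    cbind(1, seq_len(nc)),
    if (nr > 1) cbind(seq(2, nr), nc),
    if (nr > 1) cbind(nr, seq(nc - 1, 1)),
    if (nc > 1 && nr > 2) cbind(seq(nr - 1, 2), 1))
  P <- nrow(ring)
  if (n > P) stop("more terminals than perimeter cells")
  offset <- with_seed(seed, sample.int(P, 1) - 1L)
  pos <- (offset + floor((seq_len(n) - 1) * P / n)) %% P + 1L
  rc <- ring[pos, , drop = FALSE]
  idx <- (rc[, 1] - 1L) * nc + rc[, 2]
  structure(as.integer(idx), class = "cs_nodes", rc = rc)
}

#' Number of unordered terminal pairs
#' @param nodes `cs_nodes` or an integer count.
#' @return integer `choose(n, 2)`.
#' @export
n_node_pairs <- function(nodes) {
  n <- if (length(nodes) > 1 || inherits(nodes, "cs_nodes")) length(nodes)
  else as.integer(nodes)
  choose(n, 2)
}

#' Build the resistor lattice of a resistance surface
#'
#' Nodes are the non-nodata cells; every 8-neighbour pair is joined by a
#' resistor whose conductance is the arithmetic mean of the two cell
#' conductances `1/R`, divided by `sqrt(2)` for diagonal neighbours (the
#' standard raster circuit-model convention: a diagonal step is longer, so
#' the same material conducts less).
#'
#' @param resistance `cs_raster` with positive values.
#' @return object of class `cs_lattice`: node index map, edge list
#'   (`i`, `j`, `conductance`), grid shape and cell geometry.
#' @export
build_lattice <- function(resistance) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least two non-nodata cells")
  if (any(v[ok] <= 0)) stop("resistances must be positive")
  idx <- which(t(ok))                      # row-major cell indices
  node_of_vec <- rep(NA_integer_, nr * nc)
  node_of_vec[idx] <- seq_along(idx)
  g <- 1 / as.vector(t(v))                 # row-major conductances (NA ok)
  edges_i <- integer(0); edges_j <- integer(0); edges_c <- numeric(0)
  # neighbour offsets covering each undirected pair once: E, S, SE, SW
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(0.5)),
               c(1L, -1L, sqrt(0.5)))
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    valid <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    a <- which(valid)
    b <- (r2[valid] - 1L) * nc + c2[valid]
    keep <- !is.na(node_of_vec[a]) & !is.na(node_of_vec[b])
    a <- a[keep]; b <- b[keep]
    cond <- (g[a] + g[b]) / 2 * o[3]
    edges_i <- c(edges_i, node_of_vec[a])
    edges_j <- c(edges_j, node_of_vec[b])
    edges_c <- c(edges_c, cond)
  }
  structure(list(
    n_nodes = length(idx), cell_index = idx, node_of = node_of_vec,
    edges = data.frame(i = edges_i, j = edges_j, conductance = edges_c),
    shape = c(nr, nc), cell_size = resistance$cell_size,
    origin = resistance$origin, nodata = resistance$nodata),
    class = "cs_lattice")
}

#' @export
print.cs_lattice <- function(x, ...) {
  cat(sprintf("<cs_lattice> %d nodes, %d edges on a %d x %d grid\n",
              x$n_nodes, nrow(x$edges), x$shape[1], x$shape[2]))
  invisible(x)
}

# Sparse graph Laplacian of a lattice.
lattice_laplacian <- function(graph) {
  e <- graph$edges
  n <- graph$n_nodes
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

# Half-incidence operator: node current = 0.5 * sum of |edge currents| on
# incident edges, as an (n x m) sparse matrix applied to |edge current|.
half_incidence <- function(graph) {
  e <- graph$edges
  m <- nrow(e)
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(seq_len(m), seq_len(m)),
                       x = rep(0.5, 2 * m), dims = c(graph$n_nodes, m))
}

# Connected components of the lattice (union-find, iterative).
lattice_components <- function(graph) {
  parent <- seq_len(graph$n_nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_len(nrow(graph$edges))) {
    ra <- find(graph$edges$i[k]); rb <- find(graph$edges$j[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(graph$n_nodes), find, integer(1))
}

# Factorised solver context: reference node grounded, Cholesky of the
# reduced Laplacian reused across all pairs.
solver_context <- function(graph, ref_node) {
  L <- lattice_laplacian(graph)
  keep <- setdiff(seq_len(graph$n_nodes), ref_node)
  Lr <- L[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE, perm = TRUE)
  list(ch = ch, keep = keep, ref = ref_node,
       pos = stats::setNames(seq_along(keep), keep))
}

# Node voltages for unit current injected at `s`, withdrawn at `t`
# (reference grounded; voltages are unique up to that constant).
solve_voltages <- function(ctx, n_nodes, s, t) {
  b <- numeric(n_nodes - 1)
  if (s != ctx$ref) b[ctx$pos[[as.character(s)]]] <- 1
  if (t != ctx$ref) b[ctx$pos[[as.character(t)]]] <- -1
  v <- numeric(n_nodes)
  v[ctx$keep] <- as.numeric(Matrix::solve(ctx$ch, b, system = "A"))
  v
}

# Per-node current map for a voltage solution: half the sum of absolute
# incident edge currents, except terminals carry the injected unit.
node_currents <- function(graph, A_half, v, s, t) {
  e <- graph$edges
  ce <- e$conductance * abs(v[e$i] - v[e$j])
  cur <- as.numeric(A_half %*% ce)
  cur[c(s, t)] <- 1
  cur
}

#' Solve a single source-target current flow
#'
#' Injects one unit of current at `source` and grounds `target`, solving the
#' reduced Laplacian system. Returns node voltages, the per-cell current map
#' and the effective resistance `v_source - v_target`.
#'
#' @param graph `cs_lattice`.
#' @param source,target node indices (1-based, within the lattice).
#' @return list `voltages`, `current` (a `cs_raster`), `effective_resistance`.
#' @export
solve_pair <- function(graph, source, target) {
  if (source == target) stop("source and target must differ")
  comp <- lattice_components(graph)
  if (comp[source] != comp[target])
    stop(sprintf("terminals lie in different components (%d vs %d)",
                 comp[source], comp[target]))
  ctx <- solver_context(graph, target)
  v <- solve_voltages(ctx, graph$n_nodes, source, target)
  cur <- node_currents(graph, half_incidence(graph), v, source, target)
  list(voltages = v,
       current = lattice_to_raster(graph, cur),
       effective_resistance = v[source] - v[target])
}

lattice_to_raster <- function(graph, node_values) {
  out <- rep(NA_real_, prod(graph$shape))
  out[graph$cell_index] <- node_values
  cs_raster(matrix(out, graph$shape[1], graph$shape[2], byrow = TRUE),
            cell_size = graph$cell_size, origin = graph$origin,
            nodata = graph$nodata)
}

#' Cumulative omnidirectional current
#'
#' Sums the per-cell current over every unordered pair of terminals (25
#' terminals make 300 pairs). One Cholesky factorisation of the reduced
#' Laplacian is shared by all solves. The result approximates
#' direction-free movement density across the landscape.
#'
#' @param graph `cs_lattice`.
#' @param nodes `cs_nodes` of row-major cell indices (as from
#'   [place_nodes()]).
#' @return `cs_raster` of accumulated current, with attribute `n_solves`.
#' @export
cumulative_current <- function(graph, nodes) {
  terminals <- graph$node_of[as.integer(nodes)]
  if (any(is.na(terminals)))
    stop("some terminals fall on nodata cells")
  comp <- lattice_components(graph)
  if (length(unique(comp[terminals])) > 1)
    stop("terminals are not all in one connected component: components ",
         paste(sort(unique(comp[terminals])), collapse = ", "))
  ref <- terminals[1]
  ctx <- solver_context(graph, ref)
  A_half <- half_incidence(graph)
  total <- numeric(graph$n_nodes)
  pairs <- utils::combn(terminals, 2)
  for (k in seq_len(ncol(pairs))) {
    v <- solve_voltages(ctx, graph$n_nodes, pairs[1, k], pairs[2, k])
    total <- total + node_currents(graph, A_half, v, pairs[1, k], pairs[2, k])
  }
  out <- lattice_to_raster(graph, total)
  attr(out, "n_solves") <- ncol(pairs)
  out
}

#' Normalise a current map against the uniform-resistance null model
#'
#' Divides the species current map, cell by cell, by the cumulative current
#' of an all-ones resistance surface with the same shape, nodata pattern and
#' terminals. What survives is relative preference: geometry-driven current
#' concentration (node proximity, landscape outline) divides out. Cells
#' where the null current is below `eps` become nodata.
#'
#' @param current species `cs_raster` from [cumulative_current()].
#' @param graph_shape the species `cs_lattice` (supplies shape, geometry and
#'   nodata pattern for the null surface).
#' @param nodes the same `cs_nodes` used for the species run.
#' @param eps null-current floor below which the ratio is undefined.
#' @param null_current optional precomputed null map (reused across species
#'   sharing one geometry).
#' @return normalised `cs_raster` (dimensionless).
#' @export
null_normalise <- function(current, graph_shape, nodes, eps = 1e-12,
                           null_current = NULL) {
  stopifnot(inherits(graph_shape, "cs_lattice"))
  if (!identical(dim(current$values), as.integer(graph_shape$shape)) &&
      !identical(dim(current$values), graph_shape$shape))
    stop("current map shape does not match the lattice shape")
  if (is.null(null_current))
    null_current <- null_model_current(graph_shape, nodes)
  stop_if_geometry_differs(current, null_current, "current and null maps")
  ratio <- current$values / null_current$values
  ratio[!is.na(null_current$values) & null_current$values < eps] <- NA
  raster_like(current, ratio)
}

#' Cumulative current of the uniform (all-ones) null landscape
#'
#' @param graph_shape `cs_lattice` of the species run (shape and nodata
#'   pattern are reused; resistances are replaced by 1 everywhere).
#' @param nodes `cs_nodes` terminal set.
#' @return `cs_raster` of null currents.
#' @export
null_model_current <- function(graph_shape, nodes) {
  ones <- rep(NA_real_, prod(graph_shape$shape))
  ones[graph_shape$cell_index] <- 1
  null_res <- cs_raster(matrix(ones, graph_shape$shape[1],
                               graph_shape$shape[2], byrow = TRUE),
                        cell_size = graph_shape$cell_size,
                        origin = graph_shape$origin,
                        nodata = graph_shape$nodata)
  cumulative_current(build_lattice(null_res), nodes)
}
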