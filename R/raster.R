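#' Lightweight in-memory raster
#'
#' A `cs_raster` holds a rectangular grid of values together with the minimal
#' geometry the pipeline needs: the cell edge length in metres and the (x, y)
#' coordinate of the lower-left corner. Row 1 of the value matrix is the
#' *northern* edge of the grid (the usual raster convention), so the cell at
#' row `r`, column `c` has its centre at
#' `x = x0 + (c - 0.5) * cell_size`, `y = y0 + (nrow - r + 0.5) * cell_size`.
#' Missing cells are stored as `NA`; the `nodata` field only records the
#' sentinel used when the raster is written to disk.
#'
#' @param values numeric matrix (row 1 = north). Integer category codes are
#'   stored as numeric.
#' @param cell_size positive cell edge length in metres.
#' @param origin numeric length-2, (x0, y0) of the lower-left corner.
#' @param nodata sentinel written in place of `NA` on file output.
#' @return object of class `cs_raster`.
#' @export
cs_raster <- function(values, cell_size = 1, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("raster must have positive dimensions")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("all non-nodata raster values must be finite")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin[1:2]), nodata = nodata),
    class = "cs_raster")
}

#' @export
print.cs_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cs_raster> %d x %d cells, cell_size = %g m, origin = (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all nodata\n")
  invisible(x)
}

#' @export
dim.cs_raster <- function(x) dim(x$values)

#' Extract the value matrix of a raster
#' @param x a `cs_raster`.
#' @return numeric matrix (`NA` = nodata).
#' @export
raster_values <- function(x) {
  stopifnot(inherits(x, "cs_raster"))
  x$values
}

#' Construct a raster sharing the geometry of a template
#' @param template `cs_raster` supplying geometry.
#' @param values matrix of the same shape.
#' @return `cs_raster`.
#' @export
raster_like <- function(template, values) {
  cs_raster(values, cell_size = template$cell_size,
            origin = template$origin, nodata = template$nodata)
}

#' Do two rasters share grid geometry?
#' @param a,b `cs_raster` objects.
#' @param tol numeric tolerance on cell size and origin.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b))
    stop(sprintf("%s do not share grid geometry", what))
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param x a `cs_raster`.
#' @return data.frame with columns `row`, `col`, `x`, `y`, one row per cell in
#'   row-major (north-to-south, west-to-east) order.
#' @export
cell_centres <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  data.frame(row = rows, col = cols,
             x = x$origin[1] + (cols - 0.5) * x$cell_size,
             y = x$origin[2] + (nr - rows + 0.5) * x$cell_size)
}

#' Map point coordinates to raster row/column
#'
#' Points on the shared edge between two cells are assigned to the
#' higher-index cell, except on the outer grid boundary.
#'
#' @param x a `cs_raster`.
#' @param px,py numeric vectors of point coordinates (metres).
#' @return data.frame with `row`, `col` (`NA` for points outside the extent).
#' @export
point_to_cell <- function(x, px, py) {
  nr <- nrow(x$values); nc <- ncol(x$values); cs <- x$cell_size
  fx <- (px - x$origin[1]) / cs
  fy <- (py - x$origin[2]) / cs
  col <- floor(fx) + 1
  row <- nr - floor(fy)
  col[px == x$origin[1] + nc * cs] <- nc   # points on the east edge
  row[py == x$origin[2] + nr * cs] <- 1    # points on the north edge
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(fx) | !is.finite(fy)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# ---- raster stacks ---------------------------------------------------------

#' Ordered collection of co-registered rasters
#'
#' @param layers list of `cs_raster` objects sharing geometry.
#' @param names unique character layer names.
#' @return object of class `cs_stack`.
#' @export
raster_stack <- function(layers, names = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names)) names <- paste0("layer", seq_along(layers))
  if (anyDuplicated(names)) stop("layer names must be unique")
  if (length(names) != length(layers)) stop("one name per layer required")
  for (l in layers) {
    if (!inherits(l, "cs_raster")) stop("all layers must be cs_raster objects")
    stop_if_geometry_differs(layers[[1]], l, "stack layers")
  }
  structure(list(layers = stats::setNames(layers, names), names = names),
            class = "cs_stack")
}

#' @export
print.cs_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("<cs_stack> %d layers of %d x %d cells: %s\n",
              length(x$layers), d[1], d[2], paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @export
length.cs_stack <- function(x) length(x$layers)

#' Stack values as a cell-by-layer matrix
#'
#' @param stack a `cs_stack`.
#' @return numeric matrix, one column per layer, cells in row-major order.
#' @export
stack_matrix <- function(stack) {
  m <- vapply(stack$layers,
              function(l) as.vector(t(l$values)),
              numeric(length(stack$layers[[1]]$values)))
  colnames(m) <- stack$names
  m
}

#' Subset layers of a stack
#' @param stack a `cs_stack`.
#' @param which character names or integer indices.
#' @return `cs_stack`.
#' @export
stack_subset <- function(stack, which) {
  if (is.character(which)) {
    missing <- setdiff(which, stack$names)
    if (length(missing))
      stop("unknown layer(s): ", paste(missing, collapse = ", "))
  }
  raster_stack(unname(stack$layers[which]),
               names = if (is.character(which)) which else stack$names[which])
}

# ---- file I/O --------------------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text format: a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#'
#' @param x a `cs_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path) {
  stopifnot(inherits(x, "cs_raster"))
  v <- x$values
  v[is.na(v)] <- x$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %.10g", x$nodata)), con)
  utils::write.table(format(v, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return `cs_raster` (nodata cells as `NA`).
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  m <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = vals["nrows"], ncol = vals["ncols"], byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  cs_raster(m, cell_size = vals["cellsize"],
            origin = c(vals["xllcorner"], vals["yllcorner"]),
            nodata = vals["nodata_value"])
}

#' Write an occurrence table as CSV
#'
#' Columns `x,y,presence,fold` (fold written as `NA` when unset).
#'
#' @param occ occurrence data.frame (see [gen_occurrences()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(all(c("x", "y", "presence") %in% names(occ)))
  if (is.null(occ$fold)) occ$fold <- NA_integer_
  utils::write.csv(occ[, c("x", "y", "presence", "fold")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV
#' @param path file path.
#' @return data.frame with columns `x`, `y`, `presence`, `fold`.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "presence") %in% names(occ)))
  if (is.null(occ$fold)) occ$fold <- NA_integer_
  if (!all(occ$presence %in% c(0, 1))) stop("presence must be 0 or 1")
  occ
}

# ---- internal helpers ------------------------------------------------------

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators never perturb user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic sub-seed derivation: a global seed plus a stage/species tag
# expands to an independent stream seed below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (seq_len(nchar(as.character(tag))) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
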