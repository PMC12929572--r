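#' Define a regular analysis grid
#'
#' A flat metric plane of square cells. The origin is the south-west corner of
#' the grid; row 1 is the northernmost row, column 1 the westernmost column,
#' and values are sampled at cell centres with half-open cell intervals (a
#' point on a cell's west/south edge belongs to that cell).
#'
#' @param n_rows,n_cols number of rows and columns (>= 1).
#' @param cell_size cell edge length in metres.
#' @param origin_x,origin_y coordinates of the south-west corner, metres.
#' @param lat_range latitude band (degrees, south negative) mapped affinely
#'   onto rows; used to derive solar geometry (day length, zenith angle) for
#'   each row without full projection machinery. The first element is the
#'   southern edge. Default matches a subtropical Southern-Hemisphere city.
#' @param crs_note free-text note on the coordinate system.
#' @return an object of class `grid_definition`.
#' @export
grid_definition <- function(n_rows, n_cols, cell_size = 500,
                            origin_x = 0, origin_y = 0,
                            lat_range = c(-24.1, -23.3),
                            crs_note = "local metric plane") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(lat_range) == 2)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = as.numeric(cell_size),
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    lat_range = as.numeric(lat_range), crs_note = crs_note
  ), class = "grid_definition")
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("<grid_definition> %d x %d cells, %.0f m, origin (%.0f, %.0f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Grid area in square kilometres
#'
#' @param grid a [grid_definition()], or a cell count when `cell_size` is
#'   given explicitly (useful for non-rectangular study domains where only the
#'   number of retained cells is known).
#' @param cell_size cell edge in metres; taken from `grid` when omitted.
#' @return area in km^2.
#' @examples
#' grid_area_km2(24853, cell_size = 500)  # 6213.25
#' @export
grid_area_km2 <- function(grid, cell_size = NULL) {
  if (inherits(grid, "grid_definition")) {
    n <- n_cells(grid); cs <- grid$cell_size
  } else {
    n <- as.numeric(grid)
    cs <- cell_size %||% stop_gridta("cell_size needed with a bare cell count")
  }
  n * (cs / 1000)^2
}

# cell-centre coordinates; row 1 = north
cell_centre_x <- function(grid, col) grid$origin_x + (col - 0.5) * grid$cell_size
cell_centre_y <- function(grid, row) grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size

# latitude of a row centre via the affine row -> latitude map
row_latitude <- function(grid, row) {
  lat_s <- min(grid$lat_range); lat_n <- max(grid$lat_range)
  frac <- (grid$n_rows - row + 0.5) / grid$n_rows  # 0 at south edge, 1 north
  lat_s + frac * (lat_n - lat_s)
}

# point -> (row, col); NA outside the grid; half-open intervals
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol
}

#' Create a raster stack
#'
#' The in-memory container for every gridded predictor and prediction surface:
#' a `(time, row, col)` numeric array on a [grid_definition()], with `NA` for
#' missing cells. Static layers have a single time slice.
#'
#' @param grid a [grid_definition()].
#' @param times ordered `Date` vector (length 1 for static layers).
#' @param values numeric array `length(times) x n_rows x n_cols`, or a matrix
#'   `n_rows x n_cols` for a single slice, or a scalar to fill.
#' @param feature_name catalog key, e.g. `"t2m"`.
#' @param units free-text units, e.g. `"degC"`.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(grid, times, values, feature_name = "layer",
                         units = "") {
  stopifnot(inherits(grid, "grid_definition"))
  times <- as_date(times)
  if (is.unsorted(times, strictly = TRUE))
    stop_gridta("times must be strictly increasing")
  nt <- length(times)
  if (length(values) == 1L)
    values <- array(values, dim = c(nt, grid$n_rows, grid$n_cols))
  if (is.matrix(values)) {
    stopifnot(nt == 1L)
    values <- array(values, dim = c(1L, nrow(values), ncol(values)))
  }
  if (!identical(dim(values), c(nt, grid$n_rows, grid$n_cols)))
    stop_gridta(sprintf(
      "values must be a %d x %d x %d array for feature '%s'",
      nt, grid$n_rows, grid$n_cols, feature_name))
  structure(list(grid = grid, times = times, values = values,
                 feature_name = feature_name, units = units),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_stack> '%s' [%s] %d slice(s) on %d x %d grid, %.1f%% missing\n",
    x$feature_name, x$units, length(x$times), x$grid$n_rows, x$grid$n_cols,
    100 * mean(is.na(v))))
  invisible(x)
}

is_static <- function(stack) length(stack$times) == 1L

# slice as an n_rows x n_cols matrix
stack_slice <- function(stack, t_index) {
  matrix(stack$values[t_index, , ], stack$grid$n_rows, stack$grid$n_cols)
}

# value at (date, row, col); static stacks broadcast over dates
stack_value_at <- function(stack, dates, row, col) {
  if (is_static(stack)) ti <- rep(1L, length(dates))
  else ti <- match(as_date(dates), stack$times)
  idx <- cbind(ti, row, col)
  out <- rep(NA_real_, length(dates))
  ok <- complete.cases(idx)
  out[ok] <- stack$values[idx[ok, , drop = FALSE]]
  out
}

#' Convert a raster stack to a long data frame
#'
#' @param x a `raster_stack`.
#' @param row,optional unused, for the generic signature.
#' @param ... unused.
#' @return a data frame with columns `date`, `row`, `col`, `value`.
#' @export
as.data.frame.raster_stack <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  nt <- length(x$times); nr <- x$grid$n_rows; nc <- x$grid$n_cols
  data.frame(
    date = rep(x$times, times = nr * nc),
    row = rep(rep(seq_len(nr), each = nt), times = nc),
    col = rep(seq_len(nc), each = nt * nr),
    value = as.vector(x$values)
  )
}

#' Write/read a raster stack as plain text
#'
#' Serializes a stack as a long-format CSV (`date,row,col,value`) plus a JSON
#' header sidecar (`<path>.json`) carrying the grid definition, units and
#' feature name, so stacks round-trip losslessly through text files.
#'
#' @param stack a `raster_stack`.
#' @param path CSV file path.
#' @return `write_stack_csv` returns `path` invisibly; `read_stack_csv`
#'   returns the reconstructed `raster_stack`.
#' @export
write_stack_csv <- function(stack, path) {
  df <- as.data.frame(stack)
  df <- df[!is.na(df$value), ]
  write.csv(df, path, row.names = FALSE)
  hdr <- list(grid = unclass(stack$grid), times = format(stack$times),
              feature_name = stack$feature_name, units = stack$units)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- do.call(grid_definition, hdr$grid[c("n_rows", "n_cols", "cell_size",
                                           "origin_x", "origin_y")])
  g$lat_range <- hdr$grid$lat_range
  g$crs_note <- hdr$grid$crs_note
  times <- as.Date(hdr$times)
  df <- read.csv(path, colClasses = c(date = "Date"))
  vals <- array(NA_real_, dim = c(length(times), g$n_rows, g$n_cols))
  vals[cbind(match(df$date, times), df$row, df$col)] <- df$value
  raster_stack(g, times, vals, hdr$feature_name, hdr$units)
}
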