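#' Hexagonal territory grid
#'
#' Builds an offset-row tiling of `rows * cols` hexagonal territories.
#' "Diameter" is the flat-to-flat width of each hexagon, which equals the
#' distance between adjacent territory centers; every interior territory
#' (not on the outer edge of the array) has exactly six neighbors at that
#' distance. A 10 x 11 grid gives the 110-territory arena with 72 interior
#' territories used for population experiments.
#'
#' @param rows,cols Grid dimensions (each at least 3, so the grid has
#'   interior cells).
#' @param diameter Territory flat-to-flat width, m.
#' @return An object of class `hex_grid`: a list with `territories`
#'   (tibble: `id`, `row`, `col`, `x`, `y`, `degree`, `interior`),
#'   `adjacency` (list of integer neighbor ids), `rows`, `cols`,
#'   `diameter`, and `circumradius`.
#' @examples
#' g <- hex_grid(10, 11, 1000)
#' sum(g$territories$interior)  # 72
#' @export
hex_grid <- function(rows, cols, diameter) {
  if (rows < 3 || cols < 3) {
    abort("`rows` and `cols` must each be >= 3 (smaller grids have no interior cells).",
          class = "songscape_invalid_input")
  }
  if (diameter <= 0) {
    abort("`diameter` must be positive (m).", class = "songscape_invalid_input")
  }
  d <- diameter
  row_idx <- rep(seq_len(rows), each = cols)
  col_idx <- rep(seq_len(cols), times = rows)
  # even rows (1-based) are offset half a cell to the right
  x <- (col_idx - 1) * d + ifelse(row_idx %% 2 == 0, d / 2, 0)
  y <- (row_idx - 1) * d * sqrt(3) / 2

  id_of <- function(r, c) as.integer((r - 1) * cols + c)
  adjacency <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      # neighbor column pair in adjacent rows depends on row parity
      dc <- if (r %% 2 == 0) c(0L, 1L) else c(-1L, 0L)
      cand <- rbind(
        cbind(r, c - 1L), cbind(r, c + 1L),
        cbind(r - 1L, c + dc), cbind(r + 1L, c + dc)
      )
      keep <- cand[, 1] >= 1 & cand[, 1] <= rows &
              cand[, 2] >= 1 & cand[, 2] <= cols
      cand <- cand[keep, , drop = FALSE]
      adjacency[[id_of(r, c)]] <- sort(id_of(cand[, 1], cand[, 2]))
    }
  }
  degree <- lengths(adjacency)
  territories <- tibble::tibble(
    id = seq_len(rows * cols),
    row = row_idx, col = col_idx,
    x = x, y = y,
    degree = as.integer(degree),
    interior = degree == 6L
  )
  structure(
    list(territories = territories, adjacency = adjacency,
         rows = rows, cols = cols, diameter = d, circumradius = d / sqrt(3)),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d x %d = %d territories (%d interior), diameter %g m\n",
              x$rows, x$cols, x$rows * x$cols,
              sum(x$territories$interior), x$diameter))
  invisible(x)
}

#' Territory table of a hexagonal grid
#' @param x A [hex_grid()].
#' @param ... Unused.
#' @return The `territories` tibble.
#' @method as_tibble hex_grid
#' @export
as_tibble.hex_grid <- function(x, ...) x$territories

#' Test whether points lie inside a territory's hexagon
#'
#' @param grid A [hex_grid()].
#' @param territory_id Territory id.
#' @param x,y Point coordinates, m (vectorised).
#' @return Logical vector.
#' @export
hex_contains <- function(grid, territory_id, x, y) {
  stopifnot(inherits(grid, "hex_grid"))
  cx <- grid$territories$x[territory_id]
  cy <- grid$territories$y[territory_id]
  r_c <- grid$circumradius
  dx <- abs(x - cx)
  dy <- abs(y - cy)
  dx <= grid$diameter / 2 + 1e-9 & dy <= r_c - dx / sqrt(3) + 1e-9
}

#' Uniform random position within a territory
#'
#' Draws points uniformly over the closed hexagon of a territory by
#' rejection sampling from its bounding box (acceptance rate 3/4). Uses the
#' current RNG stream, so draws are reproducible under `set.seed()`.
#'
#' @param grid A [hex_grid()].
#' @param territory_id Territory id.
#' @param n Number of points.
#' @return A tibble with columns `x`, `y` (m).
#' @examples
#' set.seed(1)
#' random_position(hex_grid(3, 3, 1000), 5, n = 3)
#' @export
random_position <- function(grid, territory_id, n = 1) {
  stopifnot(inherits(grid, "hex_grid"))
  if (territory_id < 1 || territory_id > nrow(grid$territories)) {
    abort("invalid `territory_id`.", class = "songscape_invalid_input")
  }
  cx <- grid$territories$x[territory_id]
  cy <- grid$territories$y[territory_id]
  r_c <- grid$circumradius
  half_w <- grid$diameter / 2
  out_x <- numeric(n)
  out_y <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 8L)
    px <- runif(m, -half_w, half_w)
    py <- runif(m, -r_c, r_c)
    ok <- abs(py) <= r_c - abs(px) / sqrt(3)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out_x[got + seq_len(take)] <- px[idx]
      out_y[got + seq_len(take)] <- py[idx]
      got <- got + take
    }
  }
  tibble::tibble(x = cx + out_x, y = cy + out_y)
}

#' Euclidean distance between positions
#'
#' @param a,b Data frames with columns `x` and `y` (recycled row-wise).
#' @return Numeric vector of distances, m.
#' @examples
#' point_distance(data.frame(x = 0, y = 0), data.frame(x = 3, y = 4))  # 5
#' @export
point_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Plot a hexagonal territory grid
#'
#' @param object A [hex_grid()].
#' @param ... Unused.
#' @return A ggplot object showing territory centers, colored by
#'   interior/edge status.
#' @method autoplot hex_grid
#' @export
autoplot.hex_grid <- function(object, ...) {
  ggplot2::ggplot(object$territories,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$interior)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "interior",
                  title = sprintf("%d x %d hexagonal territory grid",
                                  object$rows, object$cols)) +
    ggplot2::theme_minimal()
}
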