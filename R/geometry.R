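#' Workspace geometry for the visual-matching task
#'
#' Describes the rectangular tablet workspace in which hand localization is
#' measured: 48.76 cm wide, 26.96 cm deep, with its near edge 20 cm in front
#' of the body midline, holding a 5 (row) x 20 (column) target matrix.
#'
#' @param width workspace width in mm (mediolateral extent).
#' @param depth workspace depth in mm (extent away from the body).
#' @param body_offset distance in mm from the body to the near workspace edge.
#' @param n_rows,n_cols target matrix dimensions (rows run away from the
#'   body, columns left to right).
#' @return an object of class `workspace_geometry`.
#' @examples
#' geom <- workspace_geometry()
#' grid <- make_target_grid(geom)
#' nrow(grid) # 100 targets
#' @export
workspace_geometry <- function(width = 487.6, depth = 269.6, body_offset = 200,
                               n_rows = 5, n_cols = 20) {
  if (width <= 0 || depth <= 0 || body_offset <= 0)
    stop_("invalid geometry: width, depth and body_offset must be positive")
  if (n_rows < 1 || n_cols < 1)
    stop_("invalid geometry: n_rows and n_cols must be at least 1")
  structure(
    list(width = width, depth = depth, body_offset = body_offset,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "workspace_geometry")
}

#' Lay out the target grid
#'
#' Targets sit at the centers of an `n_rows` x `n_cols` partition of the
#' workspace: column spacing is `width / n_cols` and row spacing is
#' `depth / n_rows` (24.38 mm and 53.92 mm for the default geometry), the x
#' coordinates are symmetric about the body midline (x = 0), and row 1 is the
#' row nearest the body.
#'
#' @param geometry a [workspace_geometry()].
#' @return a `target_grid` data frame with columns `row`, `col`, `x_mm`,
#'   `y_mm` and attributes `geometry`, `col_spacing`, `row_spacing`.
#' @export
make_target_grid <- function(geometry = workspace_geometry()) {
  if (!inherits(geometry, "workspace_geometry"))
    stop_("geometry must be a workspace_geometry object")
  col_spacing <- geometry$width / geometry$n_cols
  row_spacing <- geometry$depth / geometry$n_rows
  g <- expand.grid(col = seq_len(geometry$n_cols), row = seq_len(geometry$n_rows))
  grid <- data.frame(
    row = g$row,
    col = g$col,
    x_mm = -geometry$width / 2 + (g$col - 0.5) * col_spacing,
    y_mm = geometry$body_offset + (g$row - 0.5) * row_spacing)
  attr(grid, "geometry") <- geometry
  attr(grid, "col_spacing") <- col_spacing
  attr(grid, "row_spacing") <- row_spacing
  class(grid) <- c("target_grid", "data.frame")
  grid
}

#' @export
print.workspace_geometry <- function(x, ...) {
  cat(sprintf("workspace: %.1f x %.1f mm, %d cm from body, %d x %d targets\n",
              x$width, x$depth, round(x$body_offset / 10), x$n_rows, x$n_cols))
  invisible(x)
}

# x coordinates of the columns (left to right) and y depths of the rows
grid_col_x <- function(grid) sort(unique(grid$x_mm))
grid_row_y <- function(grid) sort(unique(grid$y_mm))
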