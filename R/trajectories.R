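#' Trajectory tables
#'
#' A trajectory table is the package's exchange format for tracked or
#' simulated cell paths: a `data.frame` with columns `cell_id` (integer),
#' `t_min` (time in minutes), `x_um` and `y_um` (positions in micrometres),
#' one row per cell per frame, ordered by cell then time. Each cell must sit
#' on its own regular time grid starting at its first frame; different cells
#' may use different grids (the step-process models advance each cell on its
#' own persistence clock).
#'
#' @param df data.frame with columns `cell_id`, `t_min`, `x_um`, `y_um`.
#' @return `df`, validated and ordered, with class `trajectory_table`.
#' @export
trajectory_table <- function(df) {
  need <- c("cell_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("trajectory table is missing column(s): %s", paste(miss, collapse = ", "))
  for (col in need) {
    if (!is.numeric(df[[col]]))
      stop_("trajectory column '%s' must be numeric", col)
    if (anyNA(df[[col]]))
      stop_("trajectory column '%s' contains missing values (first at row %d)",
            col, which(is.na(df[[col]]))[1L])
  }
  df <- df[order(df$cell_id, df$t_min), need, drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$cell_id)) {
    t <- df$t_min[df$cell_id == id]
    if (anyDuplicated(t))
      stop_("cell %s has duplicate time points", format(id))
    if (length(t) >= 3) {
      dt <- diff(t)
      if (max(dt) - min(dt) > 1e-6 * max(dt))
        stop_("cell %s is not on a regular time grid (missing frame?)", format(id))
    }
  }
  class(df) <- c("trajectory_table", "data.frame")
  df
}

# split into per-cell data.frames (list named by cell id), preserving order
split_cells <- function(traj) {
  split(as.data.frame(traj), traj$cell_id)
}

# sampling interval of one cell's grid
cell_dt <- function(tcell) {
  if (nrow(tcell) < 2) return(NA_real_)
  diff(tcell$t_min[1:2])
}

# assemble a trajectory table from position matrices (n_t x n_cells)
traj_from_matrices <- function(x, y, times, cell_ids = seq_len(ncol(x))) {
  n_t <- nrow(x); n_c <- ncol(x)
  df <- data.frame(
    cell_id = rep(cell_ids, each = n_t),
    t_min   = rep(times, times = n_c),
    x_um    = as.vector(x),
    y_um    = as.vector(y)
  )
  class(df) <- c("trajectory_table", "data.frame")
  df
}

#' Read / write trajectory tables
#'
#' Delimited-text serialisation with header `cell_id,t_min,x_um,y_um`.
#' Positions are written with one decimal (0.1 um, the first uncertain digit
#' of the weighted-centroid tracker), so a write/read round trip is lossless
#' at that stored precision.
#'
#' @param path file path.
#' @return [read_trajectories()] returns a validated [trajectory_table()].
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop_("no such trajectory file: %s", path)
  df <- tryCatch(
    read.csv(path, colClasses = "numeric"),
    error = function(e) {
      # re-read leniently to locate the offending line
      raw <- read.csv(path, colClasses = "character")
      for (col in intersect(c("cell_id", "t_min", "x_um", "y_um"), names(raw))) {
        bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
        if (length(bad))
          stop_("non-numeric value '%s' in column '%s' at line %d of %s",
                raw[[col]][bad[1L]], col, bad[1L] + 1L, path)
      }
      stop_("failed to parse %s: %s", path, conditionMessage(e))
    }
  )
  trajectory_table(df)
}

#' @param traj a [trajectory_table()].
#' @param digits decimal places used for the coordinates (default 1 = 0.1 um).
#' @rdname read_trajectories
#' @export
write_trajectories <- function(traj, path, digits = 1L) {
  traj <- trajectory_table(traj)
  out <- data.frame(
    cell_id = format(traj$cell_id, scientific = FALSE, trim = TRUE),
    t_min   = format(traj$t_min, scientific = FALSE, trim = TRUE),
    x_um    = formatC(traj$x_um, format = "f", digits = digits),
    y_um    = formatC(traj$y_um, format = "f", digits = digits)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trajectory_table <- function(x, ...) {
  ids <- unique(x$cell_id)
  cat(sprintf("<trajectory_table> %d cells, %d rows, t in [%g, %g] min\n",
              length(ids), nrow(x), min(x$t_min), max(x$t_min)))
  NextMethod()
}
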