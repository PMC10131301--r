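#' LiDAR point clouds
#'
#' A `point_cloud` is an N x 3 coordinate matrix (metres) with an optional
#' per-point pulse-deviation attribute. Pulse deviation is the scanner's
#' per-return waveform-shape quality metric: high values indicate
#' semi-returns, soft or partial targets, or noise.
#'
#' @param points numeric N x 3 matrix of x, y, z in metres.
#' @param deviation optional numeric vector of length N.
#' @param source_id free-text provenance label.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, deviation = NULL, source_id = "") {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0, 3)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(deviation) && length(deviation) != nrow(points))
    stop("deviation must have one value per point")
  structure(list(points = points, deviation = deviation,
                 source_id = source_id),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud '%s': %d points%s\n", x$source_id,
              nrow(x$points),
              if (is.null(x$deviation)) "" else ", with pulse deviation"))
  invisible(x)
}

#' Load a point cloud from an XYZ CSV file
#'
#' Reads the plain-text XYZ dialect: a CSV with columns `x`, `y`, `z` and
#' optionally `deviation` (header required). Coordinates are metres.
#' Malformed records raise an error naming the offending line.
#'
#' @param path file path.
#' @param format only `"xyz"` (the CSV dialect) is supported.
#' @return A [point_cloud()].
#' @export
load_point_cloud <- function(path, format = "xyz") {
  if (!file.exists(path)) stop("point-cloud file not found: ", path)
  format <- match.arg(format, "xyz")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("point-cloud CSV must have columns x, y, z (got: ",
         paste(names(df), collapse = ", "), ")")
  for (cn in intersect(c("x", "y", "z", "deviation"), names(df))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop("non-numeric value in column '", cn, "' at data line ", bad[1],
           " of ", path)
  }
  point_cloud(as.matrix(df[, c("x", "y", "z")]),
              deviation = if ("deviation" %in% names(df))
                as.numeric(df$deviation) else NULL,
              source_id = basename(path))
}

#' @rdname load_point_cloud
#' @param cloud a [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path) {
  df <- as.data.frame(cloud$points)
  names(df) <- c("x", "y", "z")
  if (!is.null(cloud$deviation)) df$deviation <- cloud$deviation
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a point cloud by pulse deviation
#'
#' Removes all points whose pulse deviation is strictly greater than
#' `max_dev` (default 15): returns with higher deviation typically
#' represent semi-returns, soft targets or noise. Points with deviation
#' exactly `max_dev` are kept.
#'
#' @param cloud a [point_cloud()] with a deviation attribute.
#' @param max_dev maximum pulse deviation kept (default 15).
#' @return The filtered [point_cloud()].
#' @export
filter_deviation <- function(cloud, max_dev = 15) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$deviation))
    stop("point cloud '", cloud$source_id, "' has no pulse-deviation ",
         "attribute; cannot apply the deviation filter")
  keep <- cloud$deviation <= max_dev
  point_cloud(cloud$points[keep, , drop = FALSE],
              deviation = cloud$deviation[keep],
              source_id = cloud$source_id)
}
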