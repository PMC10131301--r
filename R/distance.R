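#' Distance from bat positions to the nearest vegetation
#'
#' Euclidean nearest-neighbour distance from each position to the closest
#' vegetation voxel centre (the default, robust to isolated returns) or to
#' the closest raw cloud point (cloud-to-cloud mode). Queries go through a
#' kd-tree spatial index with exact search, so the result equals the
#' brute-force minimum. Positions and vegetation must be in the same
#' (LiDAR/scene) frame.
#'
#' @param positions a `bat_positions` data frame or n x 3 matrix.
#' @param vegetation an m x 3 matrix of vegetation voxel centres (see
#'   [vegetation_voxels()]), or a [point_cloud()] for cloud-to-cloud mode.
#' @param method `"index"` (kd-tree, default) or `"brute"` (O(n m) scan;
#'   mainly a verification path).
#' @return Numeric vector of distances in metres, one per position.
#' @export
distance_to_vegetation <- function(positions, vegetation,
                                   method = c("index", "brute")) {
  method <- match.arg(method)
  q <- if (is.data.frame(positions)) as.matrix(positions[, c("x", "y", "z")])
       else as.matrix(positions)
  v <- if (inherits(vegetation, "point_cloud")) vegetation$points
       else as.matrix(vegetation)
  if (nrow(v) == 0L)
    stop("no vegetation points/voxels: distances are undefined")
  if (nrow(q) == 0L) return(numeric(0))
  if (method == "index") {
    drop(RANN::nn2(v, q, k = 1, searchtype = "standard", eps = 0)$nn.dists)
  } else {
    apply(q, 1, function(p) sqrt(min(colSums((t(v) - p)^2))))
  }
}

#' Distance from bat positions to the lamppost
#'
#' Default mode is the horizontal (XY) distance to the lamppost's vertical
#' axis, which is independent of flight height; `"3d"` measures the
#' straight-line distance to the lamp head at `height` above the base.
#'
#' @param positions a `bat_positions` data frame or n x 3 matrix.
#' @param lamppost_base length-3 base point of the lamppost (metres, same
#'   frame as the positions).
#' @param mode `"horizontal"` (default) or `"3d"`.
#' @param height lamp head height above the base in metres (default 4,
#'   used only in `"3d"` mode).
#' @return Numeric vector of distances in metres.
#' @export
distance_to_lamppost <- function(positions, lamppost_base,
                                 mode = c("horizontal", "3d"), height = 4) {
  mode <- match.arg(mode)
  q <- if (is.data.frame(positions)) as.matrix(positions[, c("x", "y", "z")])
       else as.matrix(positions)
  b <- as.numeric(lamppost_base)
  if (mode == "horizontal") {
    sqrt((q[, 1] - b[1])^2 + (q[, 2] - b[2])^2)
  } else {
    head_pt <- b + c(0, 0, height)
    sqrt((q[, 1] - head_pt[1])^2 + (q[, 2] - head_pt[2])^2 +
           (q[, 3] - head_pt[3])^2)
  }
}
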