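#' Voxelise a point cloud
#'
#' Bins points into a cubic 3D grid. Each voxel is the half-open cube
#' [origin + i*edge, origin + (i+1)*edge) per axis, so a point exactly on a
#' cell boundary belongs to the higher-index cell; the voxel index is
#' floor((p - origin)/edge). Per-voxel point counts proxy local vegetation
#' density. The default 20 cm edge sits in the 10-25 cm band that resolves
#' canopy gaps without data redundancy.
#'
#' @param cloud a [point_cloud()].
#' @param edge voxel edge length in metres (default 0.20).
#' @param origin grid origin (length-3, metres). Default: the cloud's
#'   minimum corner snapped down to a multiple of `edge`, which makes voxel
#'   indices reproducible for a given cloud.
#' @return An object of class `voxel_grid`: list with `origin`, `edge`,
#'   `index` (M x 3 integer matrix of occupied voxel indices) and `counts`
#'   (length-M point counts, all >= 1). The counts sum to the number of
#'   points binned.
#' @export
voxelise <- function(cloud, edge = 0.20, origin = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(edge) || length(edge) != 1L || edge <= 0)
    stop("edge must be a single positive number")
  p <- cloud$points
  if (nrow(p) == 0L) {
    return(structure(list(origin = c(0, 0, 0), edge = edge,
                          index = matrix(integer(0), 0, 3),
                          counts = integer(0)),
                     class = "voxel_grid"))
  }
  if (is.null(origin))
    origin <- floor(apply(p, 2, min) / edge) * edge
  idx <- floor(sweep(p, 2, origin) / edge)
  storage.mode(idx) <- "integer"
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  ord_idx <- idx[first, , drop = FALSE]
  ord_key <- key[first]
  counts <- as.integer(tab[ord_key])
  structure(list(origin = as.numeric(origin), edge = edge,
                 index = ord_idx, counts = counts),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d occupied voxels, edge %.2f m, %d points\n",
              nrow(x$index), x$edge, sum(x$counts)))
  invisible(x)
}

#' Centres of voxels meeting a vegetation threshold
#'
#' Voxels containing at least `min_count` points are marked as vegetation
#' voxels (inclusive threshold, default 10): the count threshold preserves
#' fine-scale vegetation while discarding background voxels holding
#' isolated points.
#'
#' @param grid a [voxelise()] result.
#' @param min_count minimum point count, inclusive (default 10).
#' @return Numeric M x 3 matrix of voxel centre coordinates in metres
#'   (possibly 0 rows).
#' @export
vegetation_voxels <- function(grid, min_count = 10) {
  stopifnot(inherits(grid, "voxel_grid"))
  keep <- grid$counts >= min_count
  centres <- sweep((grid$index[keep, , drop = FALSE] + 0.5) * grid$edge,
                   2, grid$origin, "+")
  colnames(centres) <- c("x", "y", "z")
  centres
}

#' Read / write a voxel grid as CSV
#'
#' Plain CSV of `i`, `j`, `k`, `count` with the origin and edge in header
#' comments, plus [voxel_centres_cloud()] to export occupied-voxel centres
#' as an XYZ point cloud.
#'
#' @param grid a `voxel_grid`.
#' @param path file path.
#' @return For `read_voxel_grid`, a `voxel_grid`.
#' @export
write_voxel_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin: %.9g %.9g %.9g", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("# edge: %.9g", grid$edge)), con)
  df <- data.frame(i = grid$index[, 1], j = grid$index[, 2],
                   k = grid$index[, 3], count = grid$counts)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  hdr <- readLines(path, n = 2L)
  origin <- as.numeric(strsplit(trimws(sub("# origin:", "", hdr[1])),
                                " +")[[1]])
  edge <- as.numeric(trimws(sub("# edge:", "", hdr[2])))
  df <- utils::read.csv(path, comment.char = "#")
  idx <- as.matrix(df[, c("i", "j", "k")])
  storage.mode(idx) <- "integer"
  structure(list(origin = origin, edge = edge, index = idx,
                 counts = as.integer(df$count)),
            class = "voxel_grid")
}

#' @rdname write_voxel_grid
#' @export
voxel_centres_cloud <- function(grid) {
  centres <- sweep((grid$index + 0.5) * grid$edge, 2, grid$origin, "+")
  point_cloud(centres, source_id = "voxel_centres")
}
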