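#' Rigid-body transforms between the array and LiDAR frames
#'
#' A `rigid_transform` maps source-frame coordinates into target-frame
#' coordinates as x' = R x + t with R a proper rotation (orthonormal,
#' det +1 - translation and rotation only, no scaling or reflection) and t
#' a translation in metres.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation in metres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1); reflections are not rigid ",
         "motions of the scene")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("Rigid transform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) m\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.null(attr(x, "rmsd")))
    cat(sprintf("  fit RMSD: %.4f m over %d reference points\n",
                attr(x, "rmsd"), attr(x, "n_points")))
  invisible(x)
}

#' Fit a rigid-body transform from point correspondences
#'
#' Least-squares optimal rotation + translation (orthogonal Procrustes /
#' Kabsch solution via SVD of the cross-covariance, with the smallest
#' singular direction sign-corrected so that reflections are excluded)
#' mapping `source` points onto `target` points. Used to align acoustic
#' positions (array frame) with the vegetation scan (LiDAR frame) from the
#' array's frame reference points, which are visible in both datasets. At
#' least three non-collinear correspondences are required; the frame
#' conventionally provides five (the arm ends and the centre).
#'
#' @param source,target n x 3 matrices of paired points (metres), n >= 3.
#'   Alternatively `source` may be a correspondence data frame with columns
#'   `label`, `src_x`, `src_y`, `src_z`, `dst_x`, `dst_y`, `dst_z` (as read
#'   by [read_correspondences()]).
#' @param rmsd_warn post-fit RMSD in metres above which a warning is
#'   emitted as an alignment quality flag (default 0.05).
#' @return A [rigid_transform()] with attributes `rmsd` (post-fit
#'   root-mean-square distance over the correspondences, metres) and
#'   `n_points`.
#' @export
fit_rigid_transform <- function(source, target = NULL, rmsd_warn = 0.05) {
  if (is.data.frame(source) && is.null(target)) {
    target <- as.matrix(source[, c("dst_x", "dst_y", "dst_z")])
    source <- as.matrix(source[, c("src_x", "src_y", "src_z")])
  }
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target) || ncol(source) != 3L ||
      ncol(target) != 3L)
    stop("source and target must be paired n x 3 matrices")
  n <- nrow(source)
  if (n < 3L) stop("at least 3 point correspondences are required")
  if (anyDuplicated(source) || anyDuplicated(target))
    stop("degenerate configuration: duplicated reference points")
  cs <- colMeans(source); ct <- colMeans(target)
  A <- sweep(source, 2, cs); B <- sweep(target, 2, ct)
  if (qr(A, tol = 1e-10)$rank < 2L)
    stop("degenerate configuration: reference points are collinear")
  H <- crossprod(A, B)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ct - drop(R %*% cs)
  tf <- rigid_transform(R, t_vec)
  res <- target - (source %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE))
  rmsd <- sqrt(mean(rowSums(res^2)))
  attr(tf, "rmsd") <- rmsd
  attr(tf, "n_points") <- n
  if (rmsd > rmsd_warn)
    warning(sprintf("alignment RMSD %.3f m exceeds %.3f m: check the ",
                    rmsd, rmsd_warn),
            "reference-point correspondences")
  tf
}

#' Apply a rigid transform
#'
#' Maps points or localised positions into the target frame as
#' x' = R x + t. For `bat_positions`, only the coordinates change: a rigid
#' motion preserves distances, so the error estimates are carried over
#' unchanged, and the frame attribute is updated.
#'
#' @param tf a [rigid_transform()].
#' @param x an n x 3 matrix, a [point_cloud()], or a `bat_positions` data
#'   frame.
#' @param frame frame label recorded on transformed positions (default
#'   "scene").
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(tf, x, frame = "scene") {
  stopifnot(inherits(tf, "rigid_transform"))
  tr <- function(m) sweep(m %*% t(tf$rotation), 2, tf$translation, "+")
  if (inherits(x, "point_cloud"))
    return(point_cloud(tr(x$points), x$deviation, x$source_id))
  if (is.data.frame(x)) {
    m <- tr(as.matrix(x[, c("x", "y", "z")]))
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    attr(x, "frame") <- frame
    return(x)
  }
  tr(as.matrix(x))
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return The inverse transform (Rᵀ, -Rᵀ t).
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -drop(t(tf$rotation) %*% tf$translation))
}

#' Read / write transforms and correspondence tables
#'
#' Transforms are stored as JSON with the nine rotation entries row-major
#' and the three translation entries in metres. Correspondences are CSV
#' with columns `label`, `src_x`, `src_y`, `src_z`, `dst_x`, `dst_y`,
#' `dst_z`.
#'
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()];
#'   `read_correspondences` a data frame.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(tf$rotation)),
         translation = tf$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                  obj$translation)
}

#' @rdname write_transform
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "src_x", "src_y", "src_z", "dst_x", "dst_y", "dst_z")
  if (!all(need %in% names(df)))
    stop("correspondence CSV must have columns ",
         paste(need, collapse = ", "))
  df
}

#' @rdname write_transform
#' @param corr correspondence data frame.
#' @export
write_correspondences <- function(corr, path) {
  utils::write.csv(corr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
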