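#' Microphone array geometry
#'
#' A `mic_array` holds the fixed 3D geometry of an ultrasonic microphone
#' array in its own coordinate frame (origin at the frame centre, z up,
#' metres): the microphone positions, the index of the reference microphone
#' against which all time-of-arrival differences (TOADs) are measured, and a
#' set of labelled frame reference points used for co-registration with a
#' LiDAR scan.
#'
#' @param mic_positions numeric 8 x 3 matrix of microphone coordinates in
#'   metres (array frame).
#' @param reference_index integer index (1-8) of the reference microphone;
#'   by convention the top microphone of the frame.
#' @param reference_points numeric n x 3 matrix (n >= 3, conventionally 5:
#'   the frame arm ends and the centre) of co-registration reference points,
#'   with rownames as labels.
#'
#' @return An object of class `mic_array` with components `mic_positions`,
#'   `reference_index`, `reference_points`, `aperture` (largest pairwise
#'   microphone distance, metres) and `centre` (microphone centroid).
#'
#' @details The array must have exactly 8 microphones and they must not be
#'   coplanar: four non-coplanar microphones are the minimum for a unique 3D
#'   solution, and the four extra microphones make the array overdetermined,
#'   which is what permits residual-based localisation error assessment.
#'
#' @seealso [default_array()], [read_array_geometry()]
#' @export
mic_array <- function(mic_positions, reference_index, reference_points) {
  mic_positions <- as.matrix(mic_positions)
  storage.mode(mic_positions) <- "double"
  if (nrow(mic_positions) != 8L || ncol(mic_positions) != 3L)
    stop("mic_positions must be an 8 x 3 matrix (eight microphones)")
  if (!all(is.finite(mic_positions)))
    stop("mic_positions must be finite")
  reference_index <- as.integer(reference_index)
  if (length(reference_index) != 1L || reference_index < 1L ||
      reference_index > 8L)
    stop("reference_index must be a single index in 1..8")
  reference_points <- as.matrix(reference_points)
  storage.mode(reference_points) <- "double"
  if (ncol(reference_points) != 3L || nrow(reference_points) < 3L)
    stop("reference_points must be an n x 3 matrix with n >= 3")
  centred <- sweep(mic_positions, 2, colMeans(mic_positions))
  if (qr(centred)$rank < 3L)
    stop("microphone positions are coplanar; a unique 3D solution requires ",
         "non-coplanar microphones")
  structure(
    list(
      mic_positions = mic_positions,
      reference_index = reference_index,
      reference_points = reference_points,
      aperture = max(stats::dist(mic_positions)),
      centre = colMeans(mic_positions)
    ),
    class = "mic_array"
  )
}

#' Default T-frame array geometry
#'
#' The package's documented default eight-microphone T-frame: four
#' microphones at the ends of two horizontal 2 m arms, one at the top of the
#' vertical arm (the reference microphone), and three more on the frame,
#' giving a 2.0 m aperture and a non-coplanar, overdetermined layout. Five
#' frame reference points (three horizontal arm ends, the top and the
#' centre) are carried for LiDAR co-registration.
#'
#' @return A [mic_array()].
#' @examples
#' arr <- default_array()
#' arr$aperture  # 2 m
#' @export
default_array <- function() {
  mics <- rbind(
    c( 1.0, 0.0, 0.0),
    c(-1.0, 0.0, 0.0),
    c( 0.0, 1.0, 0.0),
    c( 0.0, -1.0, 0.0),
    c( 0.0, 0.0, 1.0),   # top microphone, reference
    c( 0.0, 0.0, 0.5),
    c( 0.5, 0.0, 0.5),
    c( 0.0, 0.5, 0.5)
  )
  rownames(mics) <- paste0("mic", 1:8)
  refpts <- rbind(
    centre  = c(0, 0, 0),
    end_xp  = c(1, 0, 0),
    end_xm  = c(-1, 0, 0),
    end_yp  = c(0, 1, 0),
    end_top = c(0, 0, 1)
  )
  mic_array(mics, reference_index = 5L, reference_points = refpts)
}

#' @export
print.mic_array <- function(x, ...) {
  cat("Microphone array: 8 microphones, aperture",
      format(x$aperture, digits = 4), "m\n")
  cat("Reference microphone:", x$reference_index,
      sprintf("(z = %.2f m)\n", x$mic_positions[x$reference_index, 3]))
  cat("Frame reference points:", nrow(x$reference_points), "\n")
  invisible(x)
}

#' Read / write an array geometry file
#'
#' The geometry file is a CSV with columns `kind` (`mic` or `ref`), `label`,
#' `x`, `y`, `z` (metres). `mic` rows are ordered by channel; the reference
#' microphone is marked with label `reference`. `ref` rows carry the frame
#' reference points.
#'
#' @param path file path.
#' @return For `read_array_geometry`, a [mic_array()].
#' @export
read_array_geometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("geometry file must have columns ", paste(need, collapse = ", "))
  mics <- df[df$kind == "mic", , drop = FALSE]
  refs <- df[df$kind == "ref", , drop = FALSE]
  ref_idx <- which(mics$label == "reference")
  if (length(ref_idx) != 1L)
    stop("exactly one mic row must be labelled 'reference'")
  rp <- as.matrix(refs[, c("x", "y", "z")])
  rownames(rp) <- refs$label
  mic_array(as.matrix(mics[, c("x", "y", "z")]), ref_idx, rp)
}

#' @rdname read_array_geometry
#' @param array a [mic_array()].
#' @export
write_array_geometry <- function(array, path) {
  labels <- rep("", 8)
  labels[array$reference_index] <- "reference"
  df <- rbind(
    data.frame(kind = "mic", label = labels,
               x = array$mic_positions[, 1], y = array$mic_positions[, 2],
               z = array$mic_positions[, 3]),
    data.frame(kind = "ref", label = rownames(array$reference_points),
               x = array$reference_points[, 1],
               y = array$reference_points[, 2],
               z = array$reference_points[, 3])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
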