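#' Build a positions table
#'
#' Constructor/validator for the `bat_positions` data frame used across the
#' package: one row per localised call with coordinates in metres, the
#' localisation error estimates, and bookkeeping columns. The coordinate
#' frame ("array" or "scene") is carried as an attribute and written as a
#' header comment by [write_positions()].
#'
#' @param df data frame with at least `time`, `x`, `y`, `z`; missing
#'   bookkeeping columns are added as `NA`.
#' @param frame coordinate frame label (default "array").
#' @return A `bat_positions` data frame.
#' @export
bat_positions <- function(df, frame = "array") {
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("positions need columns ", paste(need, collapse = ", "))
  extras <- c("radial_error", "tangential_error", "max_toad_error",
              "residual_rms", "n_mics", "valid", "guild", "track_id")
  for (cn in extras) if (!cn %in% names(df))
    df[[cn]] <- if (cn == "valid") TRUE
                else if (cn == "guild") NA_character_ else NA_real_
  class(df) <- c("bat_positions", "data.frame")
  attr(df, "frame") <- frame
  df
}

#' @export
print.bat_positions <- function(x, ...) {
  cat(sprintf("%d bat position(s) [%s frame]\n", nrow(x),
              attr(x, "frame") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.bat_positions <- function(x, ...) {
  graphics::plot(x$x, x$y, asp = 1, xlab = "x (m)", ylab = "y (m)",
                 pch = 16, col = "steelblue",
                 main = "Bat positions (top view)", ...)
}

#' Filter localised positions by range and error
#'
#' Applies the standard quality rules for combining acoustic positions with
#' fine-scale vegetation data: positions within `min_range` of the array
#' centre are excluded (localisation close to the frame is unreliable), and
#' a position is excluded if \emph{either} of its two localisation errors
#' (radial or tangential) exceeds `max_error`. There is no upper range cut:
#' distant positions of loud calls are kept. Positions flagged invalid by
#' the solver, or with missing error estimates, are also removed.
#'
#' @param positions a `bat_positions` data frame (array frame: ranges are
#'   measured from the origin).
#' @param min_range exclusion radius around the array centre in metres
#'   (default 2).
#' @param max_error cap on each of the radial and tangential errors in
#'   metres (default 0.5).
#' @return The surviving rows, same class and frame. Idempotent.
#' @export
filter_positions <- function(positions, min_range = 2.0, max_error = 0.5) {
  rng <- sqrt(positions$x^2 + positions$y^2 + positions$z^2)
  keep <- rng >= min_range &
    !is.na(positions$radial_error) & !is.na(positions$tangential_error) &
    positions$radial_error <= max_error &
    positions$tangential_error <= max_error
  if ("valid" %in% names(positions))
    keep <- keep & (positions$valid %in% TRUE)
  out <- positions[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain positions into flight tracks
#'
#' Greedy spatio-temporal chaining: positions are visited in time order and
#' each joins the open track whose last point is nearest, provided the time
#' gap is at most `max_gap` and the implied straight-line speed at most
#' `max_speed`; otherwise it opens a new track. Tracks shorter than
#' `min_positions` are discarded. Tracks are anonymous path segments: bats
#' leave and re-enter the monitored hemisphere, so no identity is claimed
#' across tracks.
#'
#' @param positions a `bat_positions` data frame.
#' @param max_gap maximum time gap within a track in seconds (default 1).
#' @param max_speed maximum plausible flight speed in m/s (default 20).
#' @param min_positions minimum track length in positions (default 3).
#' @return The input rows that belong to a retained track, with `track_id`
#'   filled (integer, 1-based, in order of first appearance), sorted by
#'   time.
#' @export
build_tracks <- function(positions, max_gap = 1.0, max_speed = 20,
                         min_positions = 3L) {
  if (nrow(positions) == 0L) {
    positions$track_id <- integer(0)
    return(positions)
  }
  ord <- order(positions$time)
  pos <- positions[ord, , drop = FALSE]
  n <- nrow(pos)
  track <- integer(n)
  last_idx <- integer(0)              # row index of each open track's tail
  for (i in seq_len(n)) {
    best <- 0L; best_d <- Inf
    for (k in seq_along(last_idx)) {
      j <- last_idx[k]
      dt <- pos$time[i] - pos$time[j]
      if (dt <= 0 || dt > max_gap) next
      d <- sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2 +
                  (pos$z[i] - pos$z[j])^2)
      if (d / dt > max_speed) next
      if (d < best_d) { best_d <- d; best <- k }
    }
    if (best == 0L) {
      last_idx <- c(last_idx, i)
      track[i] <- length(last_idx)
    } else {
      track[i] <- track[last_idx[best]]
      last_idx[best] <- i
    }
  }
  sizes <- table(track)
  keep_ids <- as.integer(names(sizes)[sizes >= min_positions])
  keep <- track %in% keep_ids
  pos <- pos[keep, , drop = FALSE]
  pos$track_id <- as.integer(factor(track[keep], levels = keep_ids))
  rownames(pos) <- NULL
  pos
}

#' Count bat passes
#'
#' A bat pass is a 10 s recording window (aligned to the recording start)
#' containing at least one localised position.
#'
#' @param positions a `bat_positions` data frame (or numeric vector of
#'   times in seconds).
#' @param window window length in seconds (default 10).
#' @return Integer number of windows containing at least one position.
#' @export
count_bat_passes <- function(positions, window = 10) {
  t <- if (is.data.frame(positions)) positions$time else as.numeric(positions)
  t <- t[is.finite(t)]
  if (length(t) == 0L) return(0L)
  length(unique(floor(t / window)))
}

#' Read / write positions CSV
#'
#' Columns: time, x, y, z, radial_error, tangential_error, max_toad_error,
#' residual_rms, n_mics, valid, guild, track_id; coordinates in metres. The
#' coordinate frame is recorded as a `# frame: <name>` comment on the first
#' line.
#'
#' @param positions a `bat_positions` data frame.
#' @param path file path.
#' @return For `read_positions`, a `bat_positions` data frame.
#' @export
write_positions <- function(positions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame: ", attr(positions, "frame") %||% "array"), con)
  utils::write.csv(as.data.frame(positions), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  frame <- if (startsWith(first, "# frame:"))
    trimws(sub("# frame:", "", first)) else "array"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bat_positions(df, frame = frame)
}
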