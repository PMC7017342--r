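#' Tracked flagellar coordinates of one cell
#'
#' Per-frame lab-frame flagellar point sets (ordered base to tip) plus head
#' position and orientation, sampled at a fixed frame rate, as produced by
#' dark-field video tracking (or by the package's synthetic generator). The
#' head orientation angle is unwrapped on ingest.
#'
#' @param frame_rate frames per second.
#' @param flagella list of `n_points x 2` matrices (x, y in micron), one per
#'   frame, each with at least 10 points ordered base to tip.
#' @param head `n_frames x 3` matrix or data frame: head x, y (micron) and
#'   orientation angle (rad).
#' @param cell_id identifier string.
#' @return An object of class `tracked_cell`.
#' @export
tracked_cell <- function(frame_rate, flagella, head, cell_id = "cell") {
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop_domain("`frame_rate` must be positive")
  if (!is.list(flagella) || length(flagella) < 2)
    stop_domain("`flagella` must be a list with >= 2 frames")
  npts <- vapply(flagella, nrow, 0L)
  if (any(npts < 10))
    stop_domain("each frame needs at least 10 flagellar points")
  head <- as.matrix(head)
  if (nrow(head) != length(flagella) || ncol(head) != 3)
    stop_domain("`head` must be n_frames x 3 (x, y, angle)")
  head[, 3] <- signal::unwrap(head[, 3])
  colnames(head) <- c("x", "y", "angle")
  structure(list(frame_rate = frame_rate,
                 flagella = lapply(flagella, function(m) {
                   m <- as.matrix(m)[, 1:2, drop = FALSE]
                   colnames(m) <- c("x", "y")
                   m
                 }),
                 head = head, cell_id = as.character(cell_id)),
            class = "tracked_cell")
}

#' @export
print.tracked_cell <- function(x, ...) {
  cat(sprintf(
    "Tracked cell '%s': %d frames at %g fps (%.3g s), %d-%d points/frame\n",
    x$cell_id, length(x$flagella), x$frame_rate,
    length(x$flagella) / x$frame_rate,
    min(vapply(x$flagella, nrow, 0L)), max(vapply(x$flagella, nrow, 0L))))
  invisible(x)
}

#' Write a tracked cell to tabular text
#'
#' Plain-text format: comment header (`# frame_rate_fps=`, `# units=um`,
#' `# cell_id=`, `# digits=`), a flagellar table
#' `frame point_index x y` (tab-separated, base to tip), and a head table
#' `frame head_x head_y head_angle_rad`. Numbers carry 6 significant digits
#' by default (declared in the header).
#'
#' @param cell a [tracked_cell()].
#' @param path output file path.
#' @param digits significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_tracked_cell <- function(cell, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# frame_rate_fps=%g", cell$frame_rate),
    "# units=um",
    sprintf("# cell_id=%s", cell$cell_id),
    sprintf("# digits=%d", digits),
    "frame\tpoint_index\tx\ty"), con)
  for (i in seq_along(cell$flagella)) {
    m <- cell$flagella[[i]]
    writeLines(sprintf("%d\t%d\t%s\t%s", i, seq_len(nrow(m)),
                       signif(m[, 1], digits), signif(m[, 2], digits)), con)
  }
  writeLines(c("# head", "frame\thead_x\thead_y\thead_angle_rad"), con)
  writeLines(sprintf("%d\t%s\t%s\t%s", seq_len(nrow(cell$head)),
                     signif(cell$head[, 1], digits),
                     signif(cell$head[, 2], digits),
                     signif(cell$head[, 3], digits)), con)
  invisible(path)
}

#' Read a tracked cell written by [write_tracked_cell()]
#'
#' @param path input file path.
#' @return a [tracked_cell()].
#' @export
read_tracked_cell <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# *[A-Za-z_]+=", lines, value = TRUE)
  get_key <- function(key, default = NULL) {
    hit <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# *", key, "="), "", hit[1])
  }
  fps <- as.numeric(get_key("frame_rate_fps"))
  cell_id <- get_key("cell_id", "cell")
  head_at <- grep("^# head", lines)
  if (!length(head_at)) stop_domain("missing '# head' section")
  is_data <- function(x) grepl("^[0-9]", x)
  flag_lines <- lines[seq_len(head_at - 1)]
  flag_lines <- flag_lines[is_data(flag_lines)]
  fl <- utils::read.table(text = flag_lines, sep = "\t",
                          col.names = c("frame", "point_index", "x", "y"))
  head_lines <- lines[seq(head_at + 1, length(lines))]
  head_lines <- head_lines[is_data(head_lines)]
  hd <- utils::read.table(text = head_lines, sep = "\t",
                          col.names = c("frame", "x", "y", "angle"))
  frames <- sort(unique(fl$frame))
  flagella <- lapply(frames, function(fr) {
    sub <- fl[fl$frame == fr, ]
    sub <- sub[order(sub$point_index), ]
    cbind(x = sub$x, y = sub$y)
  })
  hd <- hd[order(hd$frame), ]
  tracked_cell(fps, flagella, as.matrix(hd[, c("x", "y", "angle")]),
               cell_id = cell_id)
}
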