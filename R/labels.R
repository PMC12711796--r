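# YOLO-format label files: one text file per image, rows of
# "class cx cy w h [conf]" with 0-based class ids and center-format
# coordinates normalised to [0, 1]. Internally boxes are continuous xyxy
# pixel coordinates with the origin at the top-left corner.

#' Read a YOLO-format label file
#'
#' @param path label file path.
#' @param image_size `c(width, height)` in pixels.
#' @return data frame with `class`, `x1, y1, x2, y2` (pixels) and `conf`
#'   (`NA` when the file carries no confidence column).
#' @export
read_yolo_labels <- function(path, image_size) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) < 5L || length(f) > 6L || anyNA(f))
      stop(sprintf("%s: malformed label on line %d", path, i))
    if (f[4] <= 0 || f[5] <= 0)
      stop(sprintf("%s: non-positive box size on line %d", path, i))
    if (any(f[2:5] < 0) || any(f[2:5] > 1))
      stop(sprintf("%s: coordinates outside [0, 1] on line %d", path, i))
    data.frame(class = as.integer(f[1]),
               x1 = (f[2] - f[4] / 2) * image_size[1],
               y1 = (f[3] - f[5] / 2) * image_size[2],
               x2 = (f[2] + f[4] / 2) * image_size[1],
               y2 = (f[3] + f[5] / 2) * image_size[2],
               conf = if (length(f) == 6L) f[6] else NA_real_)
  })
  if (!length(out))
    return(data.frame(class = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), conf = numeric()))
  do.call(rbind, out)
}

#' Write YOLO-format labels
#'
#' @param records data frame with `class` and pixel `x1, y1, x2, y2`
#'   columns; an optional `conf` column is appended when present.
#' @param path output file path.
#' @param image_size `c(width, height)` in pixels.
#' @return the path, invisibly.
#' @export
write_yolo_labels <- function(records, path, image_size) {
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    cx <- (r$x1 + r$x2) / 2 / image_size[1]
    cy <- (r$y1 + r$y2) / 2 / image_size[2]
    w <- (r$x2 - r$x1) / image_size[1]
    h <- (r$y2 - r$y1) / image_size[2]
    if (w <= 0 || h <= 0) stop("box with non-positive size at row ", i)
    lines[i] <- if (!is.null(records$conf) && !is.na(r$conf))
      sprintf("%d %.6f %.6f %.6f %.6f %.6f", r$class, cx, cy, w, h, r$conf)
    else
      sprintf("%d %.6f %.6f %.6f %.6f", r$class, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}
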