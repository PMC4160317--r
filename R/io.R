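# Frame/CSV/config input-output.
#
# CSV dialect: comma-separated, header row, UTF-8, '.' decimal, no index
# column. Frames are PNG or TIFF image sequences in lexicographic order,
# converted to 8-bit grayscale on read.

#' Read a frame sequence
#'
#' Reads a directory of PNG/TIFF images in lexicographic name order and
#' converts each to an 8-bit grayscale matrix (multi-channel images are
#' averaged; 16-bit input is rescaled to 0-255). Video container files are
#' not supported; decode them to an image sequence first.
#'
#' @param source directory containing the frames.
#' @return list of numeric matrices (gray values 0-255).
#' @export
readFrames <- function(source) {
  if (!dir.exists(source)) {
    if (file.exists(source))
      stop("video container input is not supported; supply a directory of PNG/TIFF frames")
    stop("frame source not found: ", source)
  }
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no PNG/TIFF frames found in ", source)
  frames <- lapply(files, readFrameFile)
  dims <- vapply(frames, dim, numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed resolutions")
  frames
}

readFrameFile <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  round(img * 255)
}

#' Write a frame sequence as PNG files
#'
#' @param frames list of gray matrices (0-255).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the written file paths, invisibly.
#' @export
writeFrames <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s%05d.png", prefix, seq_along(frames)))
  for (k in seq_along(frames))
    png::writePNG(clamp(frames[[k]], 0, 255) / 255, paths[k])
  invisible(paths)
}

#' Write / read a detections table
#'
#' Columns `frame, x, y, length, width, angle, contrast, scale`, one row per
#' detection.
#'
#' @param detections list of per-frame detection tables, or one flat table
#'   with a `frame` column.
#' @param path CSV path.
#' @export
writeDetections <- function(detections, path) {
  if (is.data.frame(detections)) {
    flat <- detections
  } else {
    flat <- do.call(rbind, lapply(seq_along(detections), function(t) {
      d <- detections[[t]]
      if (is.null(d) || nrow(d) == 0) return(NULL)
      cbind(frame = t, d[, c("x", "y", "length", "width", "angle", "contrast", "scale")])
    }))
    if (is.null(flat))
      flat <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                         length = numeric(0), width = numeric(0),
                         angle = numeric(0), contrast = numeric(0),
                         scale = numeric(0))
  }
  write.csv(format(flat, digits = 10, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeDetections read the CSV back into a per-frame list.
#' @param nFrames total frame count (trailing empty frames included).
#' @export
readDetections <- function(path, nFrames = NULL) {
  flat <- read.csv(path)
  if (is.null(nFrames)) nFrames <- if (nrow(flat)) max(flat$frame) else 0
  lapply(seq_len(nFrames), function(t) {
    d <- flat[flat$frame == t, -1, drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Write / read a trajectory table
#'
#' Columns `frame, id, x, y[, angle[, interpolated]]` — the shared dialect of
#' ground truth and tracked trajectories.
#'
#' @param traj data.frame; an `id` or `traj_id` column is required.
#' @param path CSV path.
#' @export
writeTrajectories <- function(traj, path) {
  idcol <- if ("traj_id" %in% names(traj)) "traj_id" else "id"
  cols <- c("frame", idcol, "x", "y",
            intersect(c("angle", "interpolated"), names(traj)))
  out <- traj[, cols]
  names(out)[2] <- "id"
  write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeTrajectories read a trajectory CSV.
#' @export
readTrajectories <- function(path) read.csv(path)

configFields <- list(
  detection = c("scaleGrid", "wMin", "wMax", "k", "angleSep", "minArea"),
  tracking = c("dt", "q", "r", "p0", "tauW", "tauA", "tauG", "gateRadius",
               "acIters", "acSmooth"),
  linking = c("T1", "T2", "D", "minTrackLen"))

#' Read / write a pipeline configuration
#'
#' Flat `section.key = value` text (e.g. `detection.wMin = 16`,
#' `linking.T2 = 30`, `seed = 1`); blank lines and `#` comments are ignored;
#' unknown keys are errors. Keys not present keep their defaults.
#'
#' @param path config file path.
#' @return a [PipelineConfig-class].
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- pipelineConfig()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "seed") { cfg@seed <- as.numeric(val); next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(configFields) ||
        !parts[2] %in% configFields[[parts[1]]])
      stop("unknown config key: ", key)
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num) & toupper(vals) != "NA"))
      stop("non-numeric value for ", key, ": ", val)
    slot(slot(cfg, parts[1]), parts[2]) <- num
  }
  validObject(cfg@detection); validObject(cfg@tracking); validObject(cfg@linking)
  cfg
}

#' @describeIn readConfig write a configuration file.
#' @param config a [PipelineConfig-class].
#' @export
writeConfig <- function(config, path) {
  lines <- c(sprintf("seed = %g", config@seed))
  for (sec in names(configFields)) {
    obj <- slot(config, sec)
    for (f in configFields[[sec]]) {
      v <- slot(obj, f)
      lines <- c(lines, sprintf("%s.%s = %s", sec, f,
                                paste(format(v, digits = 10), collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
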