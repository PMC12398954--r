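#' Write a motion trace to CSV
#'
#' Canonical interchange format: UTF-8, comma-separated, header
#' `t_s,x_lat_mm,y_vert_mm,z_long_mm,status`, `.` decimal, timestamps in
#' seconds, status as a text enum. Numbers are written with 17 significant
#' digits so write/read round-trips are lossless.
#'
#' @param trace A `motion_trace` or data frame with the canonical columns
#'   (a ground-truth data frame from [render_sequence()] is accepted and
#'   written with status `TRACKED`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  tr <- as_motion_trace(trace)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c("t_s,x_lat_mm,y_vert_mm,z_long_mm,status",
             paste(num(tr$t_s), num(tr$x_lat_mm), num(tr$y_vert_mm),
                   num(tr$z_long_mm), tr$status, sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t_s = "numeric", x_lat_mm = "numeric",
                                       y_vert_mm = "numeric",
                                       z_long_mm = "numeric",
                                       status = "character"))
  need <- c("t_s", "x_lat_mm", "y_vert_mm", "z_long_mm", "status")
  if (!all(need %in% names(df))) {
    stop("malformed trace CSV (line 1): expected header ",
         paste(need, collapse = ","))
  }
  class(df) <- c("motion_trace", "data.frame")
  df
}

#' Coerce a data frame to the canonical motion-trace layout
#'
#' @param x A `motion_trace`, a ground-truth data frame (with or without a
#'   `status` column), or any data frame carrying the displacement columns.
#' @return A `motion_trace`.
#' @export
as_motion_trace <- function(x) {
  if (inherits(x, "motion_trace")) return(x)
  stopifnot(is.data.frame(x))
  need <- c("t_s", "x_lat_mm", "y_vert_mm", "z_long_mm")
  if (!all(need %in% names(x))) {
    stop("data frame lacks trace columns ", paste(need, collapse = ", "))
  }
  tr <- x[, need]
  tr$status <- if ("status" %in% names(x)) x$status else "TRACKED"
  class(tr) <- c("motion_trace", "data.frame")
  tr
}

# 16-bit depth (0.1 mm/unit) encoded losslessly into the R (high byte) and
# G (low byte) channels of an 8-bit PNG; B is zero.
encode_depth_png <- function(depth, path) {
  v <- round(pmin(pmax(depth * 10, 0), 65535))
  arr <- array(0, c(nrow(depth), ncol(depth), 3))
  arr[, , 1] <- (v %/% 256) / 255
  arr[, , 2] <- (v %% 256) / 255
  png::writePNG(arr, path)
  invisible(path)
}

decode_depth_png <- function(path) {
  arr <- png::readPNG(path)
  (round(arr[, , 1] * 255) * 256 + round(arr[, , 2] * 255)) / 10
}

#' Persist a frame sequence as a directory
#'
#' Layout: `color_NNNNN.png` (8-bit RGB), `depth_NNNNN.png` (16-bit depth
#' in 0.1 mm units packed into the red/green bytes of an 8-bit PNG),
#' `manifest.csv` (frame index, timestamp, file names, per-frame
#' ground-truth displacement) and `meta.json` (intrinsics, frame rate).
#'
#' @param seq A `frame_sequence`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence_dir <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(seq$frames)
  cfiles <- sprintf("color_%05d.png", seq_len(n))
  dfiles <- sprintf("depth_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    f <- seq$frames[[i]]
    png::writePNG(f$color / 255, file.path(dir, cfiles[i]))
    encode_depth_png(f$depth, file.path(dir, dfiles[i]))
  }
  gt <- seq$ground_truth
  man <- data.frame(frame_index = gt$frame_index,
                    timestamp_s = sprintf("%.17g", gt$t_s),
                    color = cfiles, depth = dfiles,
                    gt_x_lat = sprintf("%.17g", gt$x_lat_mm),
                    gt_y_vert = sprintf("%.17g", gt$y_vert_mm),
                    gt_z_long = sprintf("%.17g", gt$z_long_mm))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(intrinsics = unclass(seq$intrinsics), fps = seq$fps,
               depth_units_mm = 0.1, seed = seq$seed,
               surface = if (!is.null(seq$scene)) seq$scene$surface else NA)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_sequence_dir
#' @export
read_sequence_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ic <- meta$intrinsics
  intr <- camera_intrinsics(ic$fx, ic$fy, ic$cx, ic$cy, ic$width, ic$height)
  frames <- lapply(seq_len(nrow(man)), function(i) {
    col <- png::readPNG(file.path(dir, man$color[i])) * 255
    dep <- decode_depth_png(file.path(dir, man$depth[i]))
    list(timestamp_s = man$timestamp_s[i], color = col, depth = dep,
         frame_index = man$frame_index[i])
  })
  gt <- data.frame(frame_index = man$frame_index, t_s = man$timestamp_s,
                   x_lat_mm = man$gt_x_lat, y_vert_mm = man$gt_y_vert,
                   z_long_mm = man$gt_z_long)
  structure(list(frames = frames, ground_truth = gt, scene = NULL,
                 intrinsics = intr, fps = meta$fps),
            class = "frame_sequence")
}

#' Persist or load a detection dataset
#'
#' On disk the benchmark is a directory of PNG images plus an
#' `annotations.json` file mapping each image to its ground-truth triangle
#' vertices (zero-based pixel coordinates); masks are re-rasterized from
#' the vertices on load.
#'
#' @param dataset A [render_detection_dataset()] result.
#' @param dir Output directory.
#' @return `dir` (writer) or a `detection_dataset` (reader).
#' @export
write_detection_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- lapply(seq_along(dataset), function(i) {
    f <- sprintf("image_%04d.png", i)
    png::writePNG(dataset[[i]]$image / 255, file.path(dir, f))
    list(image = f, vertices_px = dataset[[i]]$vertices_px)
  })
  jsonlite::write_json(ann, file.path(dir, "annotations.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_detection_dataset
#' @export
read_detection_dataset <- function(dir) {
  af <- file.path(dir, "annotations.json")
  if (!file.exists(af)) stop("missing annotations: ", af)
  ann <- jsonlite::read_json(af, simplifyVector = TRUE)
  entries <- lapply(seq_len(nrow(ann)), function(i) {
    img <- png::readPNG(file.path(dir, ann$image[i])) * 255
    uv <- ann$vertices_px[[i]]
    cov <- triangle_coverage(uv, ncol(img), nrow(img))
    list(image = img, vertices_px = uv, mask = cov > 0.5)
  })
  structure(entries, class = "detection_dataset")
}

#' Serialize a validation report to JSON
#'
#' @param report An `eval_report`, optionally with a `bland_altman_result`
#'   attached, or any named list of results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "bland_altman_result")) {
      x <- x[c("bias_mm", "sd_mm", "loa_upper_mm", "loa_lower_mm", "n_pairs")]
    }
    if (is.list(x)) return(lapply(unclass(x), strip))
    # keep names of named vectors (e.g. TSR per threshold) as JSON keys
    if (!is.null(names(x)) && length(x) > 1) return(as.list(x))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
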