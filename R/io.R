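# File formats: NIfTI / multi-page TIFF mask stacks with a JSON sidecar
# for per-frame task labels and times; CSV for landmarks, measurements and
# metrics; JSON/markdown for reports.

#' Write a frame series
#'
#' Frames are stacked along the 3rd axis. NIfTI (`.nii` / `.nii.gz`)
#' stores pixel spacing in the header; TIFF gets it from the sidecar. A
#' JSON sidecar `<path>.json` always records `spacing`, `task` and `t`.
#'
#' @param frames list of [glottal_frame()] objects (same geometry).
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_series <- function(frames, path) {
  stopifnot(length(frames) >= 1)
  sp <- frames[[1]]$spacing
  arr <- vapply(frames, function(f) t(f$image),
                matrix(0, ncol(frames[[1]]$image), nrow(frames[[1]]$image)))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr, pixdim = c(sp, 1))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    tiff::writeTIFF(lapply(frames, function(f) f$image), path,
                    bits.per.sample = 32L)
  } else stop("unsupported series format: ", path)
  sidecar <- list(spacing = sp,
                  task = vapply(frames, function(f) f$task, ""),
                  t = vapply(frames, function(f) f$t, 1))
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a frame series
#'
#' Inverse of [write_series()]; landmarks are attached afterwards (see
#' [frames_with_landmarks()]).
#'
#' @param path series file written by [write_series()] (or compatible).
#' @return list with `images` (list of matrices), `spacing`, `task`, `t`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("cannot read series: ", path)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    arr <- as.array(img)
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    images <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
    spacing <- if (!is.null(sidecar$spacing)) as.numeric(sidecar$spacing) else pd[1:2]
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    images <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    if (is.null(sidecar$spacing))
      stop("TIFF series needs a JSON sidecar with pixel spacing: ", sidecar_path)
    spacing <- as.numeric(sidecar$spacing)
  } else stop("unsupported series format: ", path)
  list(images = images, spacing = spacing,
       task = if (!is.null(sidecar$task)) as.character(sidecar$task)
              else rep(NA_character_, length(images)),
       t = if (!is.null(sidecar$t)) as.numeric(sidecar$t)
           else rep(NA_real_, length(images)))
}

#' Write / read a landmark table
#'
#' CSV with columns `subject,study,frame,ac_x,ac_y,pc_x,pc_y` in pixel
#' units; a row with missing `frame` is static and applies to all frames.
#'
#' @param landmarks data.frame with the columns above.
#' @param path CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  check_columns(landmarks, c("subject", "study", "frame",
                             "ac_x", "ac_y", "pc_x", "pc_y"), "landmarks")
  write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- read.csv(path)
  check_columns(lm, c("subject", "study", "frame",
                      "ac_x", "ac_y", "pc_x", "pc_y"), "landmarks")
  lm
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(df)
}

#' Assemble frames from a series and a landmark table
#'
#' @param series output of [read_series()].
#' @param landmarks landmark data.frame (see [read_landmarks()]); static
#'   rows (missing `frame`) apply to every frame. Frames without a
#'   landmark row are skipped with a warning.
#' @param subject,study used to select landmark rows.
#' @return list of [glottal_frame()] objects, named by frame index.
#' @export
frames_with_landmarks <- function(series, landmarks, subject, study = 1) {
  lm <- landmarks[landmarks$subject == subject & landmarks$study == study, ]
  out <- list()
  for (k in seq_along(series$images)) {
    row <- lm[!is.na(lm$frame) & lm$frame == k, ]
    if (nrow(row) == 0) row <- lm[is.na(lm$frame), ]
    if (nrow(row) == 0) {
      warning(sprintf("no landmarks for subject %s study %s frame %d: frame skipped",
                      subject, study, k))
      next
    }
    row <- row[1, ]
    out[[as.character(k)]] <- glottal_frame(
      series$images[[k]], series$spacing,
      task = series$task[k], t = series$t[k],
      landmarks = landmark_set(c(row$ac_x, row$ac_y), c(row$pc_x, row$pc_y)))
  }
  out
}

#' Write / read a measurement or metrics table
#'
#' Plain CSV with `row.names = FALSE`; re-reading gives back an identical
#' table (up to numeric printing).
#'
#' @param df data.frame.
#' @param path CSV path.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_measurements <- function(path) {
  m <- read.csv(path)
  check_columns(m, c("subject", "study", "reader", "task", "frame",
                     "left_area", "right_area", "left_angle", "right_angle"),
                "measurements")
  m
}

# "mean (SD)" at 2 decimals, the table format used throughout the report.
fmt_mean_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return("NA")
  sprintf("%.2f (%.2f)", mean(x), if (length(x) > 1) sd(x) else 0)
}
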