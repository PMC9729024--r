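#' Canonical landmark names
#'
#' The package uses a fixed internal vocabulary for body landmarks:
#' `shoulder_l`, `shoulder_r`, `elbow_l`, `elbow_r`, `wrist_l`, `wrist_r`,
#' `hip_l`, `hip_r`, `knee_l`, `knee_r`, `ankle_l`, `ankle_r`.  Output of any
#' pose estimator (33-, 25- or 26-point conventions) can be ingested by
#' supplying a `landmark_map` to [read_keypoints()] that translates the
#' estimator's names to this vocabulary.
#'
#' @return Character vector of the twelve canonical landmark names.
#' @export
canonical_landmarks <- function() {
  as.vector(outer(c("shoulder", "elbow", "wrist", "hip", "knee", "ankle"),
                  c("l", "r"), paste, sep = "_"))
}

#' Construct a keypoint trajectory
#'
#' A `keypoint_trajectory` holds per-frame 2-D image coordinates (pixels,
#' origin top-left, y increasing downward) and a visibility value in
#' \[0, 1\] for a set of named landmarks, together with the video frame rate
#' and (optionally) the image size.
#'
#' @param x,y Numeric matrices, frames in rows and landmarks in columns.
#'   `NA` entries denote missing markers (e.g. after outlier removal).
#' @param visibility Numeric matrix of the same shape with values in
#'   \[0, 1\], or `NULL`, in which case all visibilities default to 1.
#' @param fps Frames per second (positive).
#' @param landmarks Character vector of landmark names; defaults to the
#'   column names of `x`.
#' @param image_size Optional `c(width, height)` in pixels.
#' @return An object of class `keypoint_trajectory`.
#' @export
keypoint_trajectory <- function(x, y, visibility = NULL, fps,
                                landmarks = colnames(x), image_size = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(landmarks)) stop("landmark names are required")
  if (!identical(dim(x), dim(y)))
    stop("'x' and 'y' must have identical dimensions")
  n <- nrow(x)
  if (n < 2) stop("a trajectory needs at least 2 frames, got ", n)
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  if (length(landmarks) != ncol(x))
    stop("length of 'landmarks' does not match the number of columns")
  if (is.null(visibility)) {
    visibility <- matrix(1, n, ncol(x))
  } else {
    visibility <- as.matrix(visibility)
    if (!identical(dim(visibility), dim(x)))
      stop("'visibility' must have the same dimensions as the coordinates")
  }
  v <- visibility[!is.na(visibility)]
  if (any(v < 0 | v > 1))
    stop("visibility values must lie in [0, 1]")
  if (any(is.infinite(x)) || any(is.infinite(y)))
    stop("coordinates must be finite or NA")
  dimnames(x) <- dimnames(y) <- dimnames(visibility) <- list(NULL, landmarks)
  structure(
    list(x = x, y = y, visibility = visibility, fps = fps,
         n_frames = n, landmarks = landmarks, image_size = image_size),
    class = "keypoint_trajectory")
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat("<keypoint_trajectory> ", x$n_frames, " frames @ ", x$fps, " fps, ",
      length(x$landmarks), " landmarks\n", sep = "")
  cat("  landmarks:", paste(x$landmarks, collapse = ", "), "\n")
  if (!is.null(x$image_size))
    cat("  image:", x$image_size[1], "x", x$image_size[2], "px\n")
  miss <- sum(is.na(x$x) | is.na(x$y))
  cat("  missing coordinate entries:", miss, "\n")
  invisible(x)
}

#' Trial duration in seconds
#'
#' The bird-dog task is administered for at most 60 seconds per side, so the
#' duration reported for a trial is `n_frames / fps` capped at 60.
#'
#' @param traj A [keypoint_trajectory()].
#' @return Duration in seconds, in (0, 60\].
#' @export
duration_seconds <- function(traj) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  min(traj$n_frames / traj$fps, 60)
}

parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*(fps|width|height)\\s*[:=]\\s*([0-9.eE+-]+)", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  meta
}

long_to_trajectory <- function(df, fps, image_size, landmark_map, path) {
  if (!is.null(landmark_map)) {
    hit <- df$landmark %in% names(landmark_map)
    df$landmark[hit] <- unname(landmark_map[df$landmark[hit]])
  }
  key <- paste(df$frame, df$landmark, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate record for frame ", d$frame, ", landmark '", d$landmark,
         "' in ", path)
  }
  frames <- sort(unique(df$frame))
  lms <- unique(df$landmark)
  n <- length(frames)
  x <- y <- matrix(NA_real_, n, length(lms), dimnames = list(NULL, lms))
  vis <- matrix(0, n, length(lms), dimnames = list(NULL, lms))
  ri <- match(df$frame, frames)
  ci <- match(df$landmark, lms)
  idx <- cbind(ri, ci)
  x[idx] <- df$x
  y[idx] <- df$y
  vis[idx] <- df$visibility
  keypoint_trajectory(x, y, vis, fps = fps, landmarks = lms,
                      image_size = image_size)
}

#' Read keypoint trajectories from CSV or JSON
#'
#' The CSV dialect has the header `frame,landmark,x,y,visibility` (the
#' visibility column is optional and defaults to 1), 0-based frame indices
#' and pixel coordinates with origin at the top-left of the image.  Metadata
#' may be carried in leading comment lines of the form `# fps: 30`,
#' `# width: 1920`, `# height: 1080`, or supplied by the caller (caller
#' arguments win).  The JSON dialect is
#' `{"fps": ..., "width": ..., "height": ...,
#'   "frames": [{"idx": ..., "points": {"<landmark>": [x, y, visibility]}}]}`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param fps Frames per second; overrides file metadata.
#' @param image_size Optional `c(width, height)`; overrides file metadata.
#' @param landmark_map Optional named character vector mapping the file's
#'   landmark names to the canonical vocabulary, e.g.
#'   `c(LEFT_SHOULDER = "shoulder_l")`.
#' @return A [keypoint_trajectory()].
#' @export
read_keypoints <- function(path, format = c("auto", "csv", "json"),
                           fps = NULL, image_size = NULL,
                           landmark_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(fps)) fps <- doc$fps
    if (is.null(fps)) stop("fps missing from JSON and not supplied")
    if (is.null(image_size) && !is.null(doc$width))
      image_size <- c(doc$width, doc$height)
    recs <- list()
    for (fr in doc$frames) {
      for (lm in names(fr$points)) {
        p <- fr$points[[lm]]
        recs[[length(recs) + 1L]] <- data.frame(
          frame = fr$idx, landmark = lm, x = p[[1]], y = p[[2]],
          visibility = if (length(p) >= 3) p[[3]] else 1.0)
      }
    }
    if (!length(recs)) stop("no frames in JSON file ", path)
    df <- do.call(rbind, recs)
  } else {
    lines <- readLines(path, n = 10L)
    meta <- parse_meta_comments(lines[startsWith(lines, "#")])
    if (is.null(fps)) fps <- meta$fps
    if (is.null(fps)) stop("fps missing from CSV header and not supplied")
    if (is.null(image_size) && !is.null(meta$width))
      image_size <- c(meta$width, meta$height)
    df <- utils::read.csv(path, comment.char = "#",
                          colClasses = c(landmark = "character"),
                          stringsAsFactors = FALSE)
    need <- c("frame", "landmark", "x", "y")
    if (!all(need %in% names(df)))
      stop("CSV ", path, " must have columns ", paste(need, collapse = ", "))
    if (!"visibility" %in% names(df)) df$visibility <- 1.0
    bad <- which(!is.finite(df$frame) | !is.finite(df$x) | !is.finite(df$y) |
                   !is.finite(df$visibility) | df$landmark == "")
    if (length(bad))
      stop("malformed row(s) in ", path, " at data line ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  long_to_trajectory(df, fps = fps, image_size = image_size,
                     landmark_map = landmark_map, path = path)
}

#' Write a keypoint trajectory to CSV or JSON
#'
#' Inverse of [read_keypoints()]; entries with missing coordinates are
#' omitted from the file.
#'
#' @param traj A [keypoint_trajectory()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(traj, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  n <- traj$n_frames
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    cat("# fps: ", format(traj$fps, digits = 15), "\n", sep = "", file = con)
    if (!is.null(traj$image_size)) {
      cat("# width: ", traj$image_size[1], "\n", sep = "", file = con)
      cat("# height: ", traj$image_size[2], "\n", sep = "", file = con)
    }
    df <- data.frame(
      frame = rep(seq_len(n) - 1L, times = length(traj$landmarks)),
      landmark = rep(traj$landmarks, each = n),
      x = as.vector(traj$x), y = as.vector(traj$y),
      visibility = as.vector(traj$visibility))
    df <- df[!is.na(df$x) & !is.na(df$y), , drop = FALSE]
    df <- df[order(df$frame, match(df$landmark, traj$landmarks)), , drop = FALSE]
    num <- function(v) sub("e([+-])0?(\\d\\d+)", "e\\1\\2",
                           sprintf("%.17g", v))  # round-trip exact
    cat("frame,landmark,x,y,visibility\n", file = con)
    cat(sprintf("%d,%s,%s,%s,%s\n", df$frame, df$landmark, num(df$x),
                num(df$y), num(df$visibility)), sep = "", file = con)
  } else {
    frames <- lapply(seq_len(n), function(i) {
      pts <- list()
      for (j in seq_along(traj$landmarks)) {
        if (is.na(traj$x[i, j]) || is.na(traj$y[i, j])) next
        pts[[traj$landmarks[j]]] <-
          c(traj$x[i, j], traj$y[i, j], traj$visibility[i, j])
      }
      list(idx = i - 1L, points = pts)
    })
    doc <- list(fps = traj$fps,
                width = if (is.null(traj$image_size)) NULL else traj$image_size[1],
                height = if (is.null(traj$image_size)) NULL else traj$image_size[2],
                frames = frames)
    doc <- doc[!vapply(doc, is.null, logical(1))]
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

side_landmarks <- function(side) {
  arm <- if (side == "left_arm_right_leg") "l" else "r"
  leg <- if (side == "left_arm_right_leg") "r" else "l"
  c(shoulder = paste0("shoulder_", arm), hip = paste0("hip_", arm),
    elbow = paste0("elbow_", arm), wrist = paste0("wrist_", arm),
    knee = paste0("knee_", leg), ankle = paste0("ankle_", leg))
}

#' Resolve the six task landmarks for a bird-dog trial
#'
#' Selects the shoulder, hip, elbow and wrist of the lifted arm and the knee
#' and ankle of the lifted (contralateral) leg, and computes the trunk
#' length `t` as the mean over frames of the Euclidean shoulder-hip
#' distance.  By default `t` uses the shoulder of the lifted arm and the
#' hip on the same body side (the camera-facing pair in a lateral view,
#' which is the most reliably tracked); `t_mode = "mean_both"` averages the
#' left and right shoulder-hip pairs when both are present.  Frames where
#' the shoulder or hip is missing are excluded from the average.
#'
#' @param traj A [keypoint_trajectory()].
#' @param side `"left_arm_right_leg"` or `"right_arm_left_leg"` (which arm
#'   is lifted; the lifted leg is contralateral).
#' @param t_mode Trunk-length convention, `"ipsilateral"` (default) or
#'   `"mean_both"`.
#' @return An object of class `task_keypoints`: per-frame `n x 2` coordinate
#'   matrices `shoulder`, `hip`, `elbow`, `wrist`, `knee`, `ankle`, the
#'   trunk length `t`, `side`, `fps` and `n_frames`.  The limb keypoints are
#'   indexed `k = 1` (elbow), `2` (wrist), `3` (knee), `4` (ankle).
#' @export
resolve_task_keypoints <- function(traj,
                                   side = c("left_arm_right_leg",
                                            "right_arm_left_leg"),
                                   t_mode = c("ipsilateral", "mean_both")) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  side <- match.arg(side)
  t_mode <- match.arg(t_mode)
  lm <- side_landmarks(side)
  absent <- setdiff(unname(lm), traj$landmarks)
  if (length(absent))
    stop("required landmark(s) missing for side '", side, "': ",
         paste(absent, collapse = ", "))
  get <- function(name) cbind(x = traj$x[, name], y = traj$y[, name])
  series <- lapply(lm, get)
  for (nm in names(series)) {
    frac_missing <- mean(is.na(series[[nm]][, 1]) | is.na(series[[nm]][, 2]))
    if (frac_missing > 0.5)
      stop("landmark '", lm[[nm]], "' is missing in ",
           round(100 * frac_missing), "% of frames: insufficient data")
  }
  pair_t <- function(sh, hp) {
    d <- sqrt(rowSums((sh - hp)^2))
    mean(d, na.rm = TRUE)
  }
  t_len <- pair_t(series$shoulder, series$hip)
  if (t_mode == "mean_both") {
    arm <- if (side == "left_arm_right_leg") "l" else "r"
    other <- if (arm == "l") "r" else "l"
    sh2 <- paste0("shoulder_", other); hp2 <- paste0("hip_", other)
    if (all(c(sh2, hp2) %in% traj$landmarks))
      t_len <- mean(c(t_len, pair_t(get(sh2), get(hp2))))
  }
  if (!is.finite(t_len) || t_len <= 0)
    stop("trunk length is not positive; shoulder/hip data degenerate")
  structure(
    c(series,
      list(trunk_length = t_len, side = side, fps = traj$fps,
           n_frames = traj$n_frames,
           k_index = c("1" = "elbow", "2" = "wrist",
                       "3" = "knee", "4" = "ankle"))),
    class = "task_keypoints")
}

#' @export
print.task_keypoints <- function(x, ...) {
  cat("<task_keypoints> side =", x$side, "\n")
  cat("  frames:", x$n_frames, "@", x$fps, "fps;  trunk length t =",
      format(x$trunk_length, digits = 6), "px\n")
  invisible(x)
}
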