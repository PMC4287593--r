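# Keyframe animation.  Each object carries a sorted list of keyframes
# (pose, color, group membership, visibility at a time point).  Sampling
# interpolates positions with a Catmull-Rom spline in time, orientations
# with piecewise shortest-arc slerp, colors linearly; group membership and
# visibility switch stepwise at keyframe times.

# ---- quaternions (unit, scalar-first), internal ---------------------------

quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# spherical linear interpolation with shortest-arc sign correction
quat_slerp <- function(q1, q2, s) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  if (d > 1 - 1e-12) {
    q <- (1 - s) * q1 + s * q2
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(max(-1, min(1, d)))
  (sin((1 - s) * th) * q1 + sin(s * th) * q2) / sin(th)
}

# ---- keyframes and timelines ----------------------------------------------

#' Create a keyframe
#'
#' @param time time in seconds, >= 0.
#' @param pose a `rigid_transform`.
#' @param color RGB triple in `[0, 1]` or a character data-coloring label.
#' @param group group id the object belongs to at this time, or `NA`.
#' @param visible logical.
#' @return A list of class `keyframe`.
#' @export
keyframe <- function(time, pose, color = c(1, 1, 1), group = NA_character_,
                     visible = TRUE) {
  if (time < 0) stop("keyframe time must be >= 0", call. = FALSE)
  rt_validate(pose)
  structure(list(time = time, pose = pose, color = color, group = group,
                 visible = visible), class = "keyframe")
}

#' Create an empty timeline
#' @param duration total duration in seconds (informational).
#' @return A list of class `timeline`.
#' @export
timeline_new <- function(duration = 0) {
  structure(list(tracks = list(), duration = duration), class = "timeline")
}

#' @export
print.timeline <- function(x, ...) {
  nk <- sum(vapply(x$tracks, length, integer(1)))
  cat(sprintf("<timeline> %d object track(s), %d keyframe(s)\n",
              length(x$tracks), nk))
  invisible(x)
}

#' Set a keyframe on an object's track
#'
#' Keeps the track sorted by time; a keyframe at a time already keyed
#' replaces the old one (at most one keyframe per object per time).
#'
#' @param timeline a `timeline`.
#' @param object_id object id the keyframe applies to.
#' @param kf a [keyframe()].
#' @return The updated timeline.
#' @export
set_keyframe <- function(timeline, object_id, kf) {
  stopifnot(inherits(timeline, "timeline"), inherits(kf, "keyframe"))
  track <- timeline$tracks[[object_id]]
  if (is.null(track)) track <- list()
  times <- vapply(track, function(k) k$time, numeric(1))
  hit <- which(times == kf$time)
  if (length(hit)) {
    track[[hit]] <- kf
  } else {
    track[[length(track) + 1L]] <- kf
    times <- c(times, kf$time)
    track <- track[order(times)]
  }
  timeline$tracks[[object_id]] <- track
  timeline$duration <- max(timeline$duration, kf$time)
  timeline
}

# Catmull-Rom tangent interpolation in the time domain: cubic Hermite
# between consecutive keyframes with finite-difference tangents, one-sided
# at the ends.  Two keyframes degenerate to exact linear interpolation.
interp_positions <- function(times, pos, t) {
  n <- length(times)
  if (t <= times[1]) return(pos[1, ])
  if (t >= times[n]) return(pos[n, ])
  i <- findInterval(t, times)    # times[i] <= t < times[i+1]
  t0 <- times[i]; t1 <- times[i + 1]
  h <- t1 - t0
  s <- (t - t0) / h
  p0 <- pos[i, ]; p1 <- pos[i + 1, ]
  m0 <- if (i == 1) (p1 - p0) / h else (p1 - pos[i - 1, ]) / (t1 - times[i - 1])
  m1 <- if (i + 1 == n) (p1 - p0) / h else (pos[i + 2, ] - p0) / (times[i + 2] - t0)
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * p0 + h10 * h * m0 + h01 * p1 + h11 * h * m1
}

#' Sample an object's animated state at a time
#'
#' Exactly reproduces keyframe states at keyframe times. Between keyframes,
#' positions follow a Catmull-Rom spline (in time, clamped at the ends;
#' linear when only two keyframes exist), orientations follow piecewise
#' shortest-arc quaternion slerp, colors interpolate linearly. Group
#' membership and visibility hold the value of the latest keyframe at or
#' before `t`. Before the first / after the last keyframe the boundary
#' state holds.
#'
#' @param timeline a `timeline`.
#' @param object_id object id with at least one keyframe.
#' @param t sample time in seconds.
#' @return A list with `pose`, `color`, `group`, `visible`.
#' @export
sample_timeline <- function(timeline, object_id, t) {
  track <- timeline$tracks[[object_id]]
  if (is.null(track) || length(track) == 0)
    stop("object ", object_id, " has no keyframes", call. = FALSE)
  times <- vapply(track, function(k) k$time, numeric(1))
  n <- length(track)

  hit <- which(times == t)
  if (length(hit)) {
    k <- track[[hit]]
    return(list(pose = k$pose, color = k$color, group = k$group,
                visible = k$visible))
  }
  if (t <= times[1]) k <- track[[1]]
  else if (t >= times[n]) k <- track[[n]]
  else k <- NULL
  if (!is.null(k))
    return(list(pose = k$pose, color = k$color, group = k$group,
                visible = k$visible))

  i <- findInterval(t, times)
  k0 <- track[[i]]; k1 <- track[[i + 1]]
  s <- (t - times[i]) / (times[i + 1] - times[i])

  pos <- do.call(rbind, lapply(track, function(k) k$pose$t))
  p <- interp_positions(times, pos, t)
  q <- quat_slerp(quat_from_matrix(k0$pose$R), quat_from_matrix(k1$pose$R), s)
  pose <- rt_new(quat_to_matrix(q), p)

  color <- if (is.numeric(k0$color) && is.numeric(k1$color)) {
    (1 - s) * k0$color + s * k1$color
  } else k0$color  # symbolic data-coloring labels switch stepwise

  # stepwise channels: latest keyframe at or before t
  list(pose = pose, color = color, group = k0$group, visible = k0$visible)
}

#' Sample the whole timeline into per-frame records
#'
#' @param timeline a `timeline`.
#' @param object_ids objects to sample (default: every track).
#' @param fps frames per second, > 0.
#' @param t0,t1 start and end times (seconds), `t1 >= t0`. Produces
#'   `floor((t1 - t0) * fps) + 1` frames, frame k sampled at `t0 + k/fps`.
#' @return A list of frames; each frame is a list with `frame`, `time`, and
#'   `objects` (per id: `pose` as a 4x4 matrix, `color`, `group`,
#'   `visible`).
#' @export
export_frames <- function(timeline, object_ids = names(timeline$tracks),
                          fps = 24, t0 = 0, t1 = timeline$duration) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  nframes <- floor((t1 - t0) * fps + 1e-9) + 1L
  lapply(seq_len(nframes) - 1L, function(k) {
    t <- t0 + k / fps
    states <- lapply(object_ids, function(id) {
      st <- sample_timeline(timeline, id, t)
      list(pose = rt_to_matrix(st$pose), color = st$color,
           group = st$group, visible = st$visible)
    })
    names(states) <- object_ids
    list(frame = k, time = t, objects = states)
  })
}

#' Write exported frames as JSON lines
#'
#' One JSON object per line: frame index, time, and per-object 4x4 pose
#' matrix (row-major), color, group and visibility. A neutral hand-off
#' format for downstream renderers.
#'
#' @param frames result of [export_frames()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_jsonl <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    rec <- list(frame = fr$frame, time = fr$time,
                objects = lapply(fr$objects, function(o) {
                  list(matrix = as.numeric(t(o$pose)), color = o$color,
                       group = o$group, visible = o$visible)
                }))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
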