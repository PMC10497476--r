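#' Build a frame schedule from (count, duration) blocks
#'
#' A framing protocol partitions a dynamic scan into contiguous temporal
#' frames. Schedules are specified the way protocols are printed in the
#' dynamic-PET literature: a list of blocks, each "n frames of d seconds".
#'
#' @param spec A list of length-2 numeric vectors `c(count, duration_s)`,
#'   or a 2-column matrix/data.frame with columns count and duration (s).
#' @param name Optional protocol label carried through downstream objects.
#' @return A `frame_schedule`: list with `starts` and `durations` in seconds
#'   (frames contiguous, first start 0) and `name`.
#' @examples
#' s <- make_schedule(list(c(30, 1), c(30, 5), c(10, 12), c(5, 60), c(25, 120)))
#' n_frames(s)        # 100
#' schedule_end(s)    # 3600
#' @seealso [preset_protocol()] for the six built-in protocols.
#' @export
make_schedule <- function(spec, name = NULL) {
  if (is.matrix(spec) || is.data.frame(spec))
    spec <- lapply(seq_len(nrow(spec)), function(i) as.numeric(spec[i, 1:2]))
  if (length(spec) == 0L)
    stop("empty schedule specification")
  counts <- vapply(spec, function(b) as.numeric(b[[1]]), numeric(1))
  durs   <- vapply(spec, function(b) as.numeric(b[[2]]), numeric(1))
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("frame durations must be positive")
  durations <- rep(durs, times = counts)
  starts <- cumsum(c(0, durations[-length(durations)]))
  new_frame_schedule(starts, durations, name)
}

new_frame_schedule <- function(starts, durations, name = NULL) {
  sched <- structure(
    list(starts = as.numeric(starts), durations = as.numeric(durations),
         name = name),
    class = "frame_schedule")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  starts <- sched$starts; durations <- sched$durations
  if (length(starts) != length(durations))
    stop("starts and durations differ in length")
  if (length(starts) < 1L) stop("schedule has no frames")
  if (any(durations <= 0)) stop("frame durations must be strictly positive")
  if (starts[1] != 0) stop("first frame must start at 0 s")
  if (length(starts) > 1L) {
    gap <- starts[-1] - (starts[-length(starts)] + durations[-length(durations)])
    bad <- which(abs(gap) > 1e-9)
    if (length(bad))
      stop("frames not contiguous at index ", bad[1] + 1L,
           " (gap ", signif(gap[bad[1]], 3), " s)")
  }
  invisible(sched)
}

#' The six printed framing protocols
#'
#' Returns one of the six 60-min framing protocols compared in total-body
#' FDG protocol-optimization work, exactly as printed:
#' \describe{
#'   \item{P-100f}{30 x 1 s, 30 x 5 s, 10 x 12 s, 5 x 60 s, 25 x 120 s}
#'   \item{P-61f}{30 x 2 s, 6 x 10 s, 8 x 30 s, 4 x 60 s, 5 x 120 s, 8 x 300 s}
#'   \item{P-48f}{12 x 5 s, 6 x 10 s, 8 x 30 s, 8 x 60 s, 8 x 120 s, 6 x 300 s}
#'   \item{P-29f}{6 x 10 s, 2 x 30 s, 6 x 60 s, 5 x 120 s, 4 x 180 s, 6 x 300 s}
#'   \item{P-19f}{6 x 10 s, 3 x 180 s, 10 x 300 s}
#'   \item{P-12f}{6 x 10 s, 1 x 540 s, 5 x 600 s}
#' }
#' All cover exactly 3600 s.
#'
#' @param name Protocol name, one of `protocol_names()`.
#' @return A [make_schedule()] `frame_schedule`.
#' @export
preset_protocol <- function(name) {
  blocks <- .protocol_blocks[[name]]
  if (is.null(blocks))
    stop("unknown protocol '", name, "'; valid presets: ",
         paste(protocol_names(), collapse = ", "))
  make_schedule(blocks, name = name)
}

.protocol_blocks <- list(
  "P-100f" = list(c(30, 1), c(30, 5), c(10, 12), c(5, 60), c(25, 120)),
  "P-61f"  = list(c(30, 2), c(6, 10), c(8, 30), c(4, 60), c(5, 120), c(8, 300)),
  "P-48f"  = list(c(12, 5), c(6, 10), c(8, 30), c(8, 60), c(8, 120), c(6, 300)),
  "P-29f"  = list(c(6, 10), c(2, 30), c(6, 60), c(5, 120), c(4, 180), c(6, 300)),
  "P-19f"  = list(c(6, 10), c(3, 180), c(10, 300)),
  "P-12f"  = list(c(6, 10), c(1, 540), c(5, 600))
)

#' @rdname preset_protocol
#' @export
protocol_names <- function() names(.protocol_blocks)

#' Frame mid-times in minutes
#'
#' Frame values are time-averages of the activity over the frame and are
#' attributed to the frame mid-time for all regression and integration.
#'
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of mid-times in minutes, strictly increasing.
#' @export
frame_midtimes <- function(schedule) {
  validate_schedule(schedule)
  (schedule$starts + schedule$durations / 2) / 60
}

#' @export
#' @rdname frame_midtimes
n_frames <- function(schedule) length(schedule$starts)

#' @export
#' @rdname frame_midtimes
schedule_end <- function(schedule) {
  n <- length(schedule$starts)
  schedule$starts[n] + schedule$durations[n]
}

#' @export
as.data.frame.frame_schedule <- function(x, ...) {
  data.frame(frame_start_s = x$starts, frame_duration_s = x$durations)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("Frame schedule", if (!is.null(x$name)) paste0("'", x$name, "'") else "",
      "\n  ", n_frames(x), " frames, 0-", schedule_end(x), " s\n", sep = "")
  rle_d <- rle(x$durations)
  cat("  blocks:", paste(rle_d$lengths, "x", rle_d$values, "s", collapse = ", "),
      "\n")
  invisible(x)
}

schedules_identical <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    all(abs(a$starts - b$starts) <= tol) &&
    all(abs(a$durations - b$durations) <= tol)
}

#' Time-activity curve
#'
#' Per-frame mean decay-corrected activity concentration (kBq/mL) tied to a
#' frame schedule. Negative values are permitted (noise) but flagged with a
#' warning.
#'
#' @param schedule A `frame_schedule`.
#' @param values Numeric vector, one value per frame (kBq/mL).
#' @param label Role tag, e.g. `"tissue"` or `"blood"`.
#' @return A `tac` object.
#' @export
tac <- function(schedule, values, label = "tissue") {
  validate_schedule(schedule)
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule))
    stop("values length (", length(values), ") != frame count (",
         n_frames(schedule), ")")
  if (any(!is.finite(values)))
    stop("TAC values must be finite")
  if (any(values < 0))
    warning("TAC contains ", sum(values < 0), " negative value(s)")
  structure(list(schedule = schedule, values = values, label = label),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat("Time-activity curve [", x$label, "], ", n_frames(x$schedule),
      " frames, 0-", schedule_end(x$schedule), " s\n", sep = "")
  cat("  range ", signif(min(x$values), 4), " to ", signif(max(x$values), 4),
      " kBq/mL\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  cbind(as.data.frame(x$schedule),
        data.frame(value_kBq_per_mL = x$values))
}

#' @export
plot.tac <- function(x, ..., xlab = "Time (min)",
                     ylab = "Activity (kBq/mL)", type = "b", pch = 16) {
  graphics::plot(frame_midtimes(x$schedule), x$values, xlab = xlab,
                 ylab = ylab, type = type, pch = pch, ...)
  invisible(x)
}

#' Arterial/blood input function
#'
#' A [tac()] with blood role plus a plasma-to-blood scaling. For FDG the
#' plasma-to-blood ratio is close to 1, so whole-blood values are used as
#' plasma by default.
#'
#' @param schedule,values As in [tac()].
#' @param plasma_to_blood_ratio Positive scale applied to blood values to
#'   obtain plasma concentration (default 1).
#' @return An `input_function` (also a `tac`).
#' @export
input_function <- function(schedule, values, plasma_to_blood_ratio = 1.0) {
  if (!is.numeric(plasma_to_blood_ratio) || plasma_to_blood_ratio <= 0)
    stop("plasma_to_blood_ratio must be > 0")
  obj <- tac(schedule, values, label = "blood")
  obj$plasma_to_blood_ratio <- plasma_to_blood_ratio
  class(obj) <- c("input_function", "tac")
  obj
}

#' @export
#' @rdname input_function
#' @param x An object to coerce.
as_input_function <- function(x, plasma_to_blood_ratio = 1.0) {
  if (inherits(x, "input_function")) return(x)
  if (inherits(x, "tac"))
    return(input_function(x$schedule, x$values, plasma_to_blood_ratio))
  stop("cannot coerce ", class(x)[1], " to input_function")
}

# plasma values used in kinetic math
plasma_values <- function(cp) {
  ratio <- if (!is.null(cp$plasma_to_blood_ratio)) cp$plasma_to_blood_ratio else 1
  cp$values * ratio
}
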