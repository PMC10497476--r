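#' Rebin dynamic data onto another framing protocol
#'
#' Each target frame value is the overlap-duration-weighted mean of the
#' source frame values. When every target frame is a union of source frames
#' (the six presets are all unions of a 1-s grid) the operation is exact:
#' the time integral `sum(value_i * dt_i)` over any aligned interval is
#' conserved to floating tolerance. Misaligned boundaries are allowed with
#' fractional-overlap weights and raise a warning. Weighting is by overlap
#' duration only (the data are decay-corrected).
#'
#' @param data A [tac()] / [input_function()] or a [dynamic_image()].
#' @param target Target `frame_schedule`; must be covered by the source span.
#' @param ... Unused.
#' @return The same kind of object on the target schedule.
#' @export
rebin <- function(data, target, ...) UseMethod("rebin")

#' @export
rebin.tac <- function(data, target, ...) {
  W <- overlap_weights(data$schedule, target)
  vals <- as.numeric(W %*% data$values)
  if (inherits(data, "input_function"))
    input_function(target, vals, data$plasma_to_blood_ratio)
  else
    tac(target, vals, label = data$label)
}

#' @export
rebin.dynamic_image <- function(data, target, ...) {
  W <- overlap_weights(data$schedule, target)
  m <- as_voxel_matrix(data) %*% t(W)
  dynamic_image(array(m, dim = c(dim(data$data)[1:3], n_frames(target))),
                target, spacing = data$spacing, affine = data$affine)
}

# n_target x n_source row-stochastic matrix of fractional overlap weights
overlap_weights <- function(source, target) {
  validate_schedule(source); validate_schedule(target)
  if (schedule_end(target) > schedule_end(source) + 1e-9)
    stop("target schedule (", schedule_end(target),
         " s) extends past source (", schedule_end(source), " s)")
  s0 <- source$starts; s1 <- s0 + source$durations
  t0 <- target$starts; t1 <- t0 + target$durations
  ov <- outer(t1, s1, pmin) - outer(t0, s0, pmax)
  ov[ov < 0] <- 0
  tot <- rowSums(ov)
  zero <- which(tot <= 0)
  if (length(zero))
    stop("target frame ", zero[1], " has zero overlap with the source")
  # a target frame strictly inside one source frame carries no sub-frame
  # information: temporal upsampling is not supported
  inside <- vapply(seq_along(t0), function(i) {
    j <- which(s0 <= t0[i] + 1e-9 & s1 >= t1[i] - 1e-9)
    length(j) == 1L && target$durations[i] < source$durations[j] - 1e-9
  }, logical(1))
  if (any(inside))
    stop("target frame ", which(inside)[1], " is finer than the source ",
         "frames covering it; temporal upsampling is not supported")
  bounds <- sort(unique(c(s0, s1)))
  aligned <- all(vapply(c(t0, t1),
                        function(b) min(abs(bounds - b)) < 1e-9, logical(1)))
  if (!aligned)
    warning("target frame boundaries not aligned with source; ",
            "using fractional-overlap weights")
  ov / tot
}

#' Rebin onto several preset protocols at once
#'
#' @param data As in [rebin()]; a fine source grid (<= 1 s frames) is
#'   recommended so all presets are exact unions of source frames.
#' @param names Subset of [protocol_names()] (default all six).
#' @param verbose Log the frame counts per preset.
#' @return Named list of rebinned objects, one per requested preset.
#' @export
rebin_all_presets <- function(data, names = protocol_names(), verbose = FALSE) {
  bad <- setdiff(names, protocol_names())
  if (length(bad))
    stop("unknown preset(s): ", paste(bad, collapse = ", "))
  out <- lapply(names, function(nm) rebin(data, preset_protocol(nm)))
  names(out) <- names
  if (verbose)
    for (nm in names)
      message(nm, ": ", n_frames(preset_protocol(nm)), " frames")
  out
}
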