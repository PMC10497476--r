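#' Read / write a dynamic image as NIfTI + timing sidecar
#'
#' The 4D volume is stored as NIfTI (.nii or .nii.gz); frame timing travels
#' in a JSON sidecar with keys `FrameTimesStart` and `FrameDuration`
#' (seconds, BIDS-PET style). The schedule is validated on read: frames must
#' be contiguous, start at 0, and match the 4th dimension.
#'
#' @param image_path Path to the 4D NIfTI file.
#' @param timing_path Path to the timing JSON sidecar.
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(image_path, timing_path) {
  nii <- RNifti::readNifti(image_path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI, got ", length(dim(arr)), "D")
  sched <- read_timing(timing_path)
  if (n_frames(sched) != dim(arr)[4])
    stop("timing has ", n_frames(sched), " frames but image has ",
         dim(arr)[4])
  spacing <- RNifti::pixdim(nii)[1:3]
  affine <- unclass(RNifti::xform(nii))
  dynamic_image(arr, sched, spacing = spacing, affine = affine)
}

#' @rdname read_dynamic
#' @param image A [dynamic_image()].
#' @export
write_dynamic <- function(image, image_path, timing_path) {
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(image$spacing, schedule_end(image$schedule))
  RNifti::sform(nii) <- structure(image$affine, code = 2L)
  RNifti::writeNifti(nii, image_path)
  write_timing(image$schedule, timing_path)
  invisible(c(image_path, timing_path))
}

#' @rdname read_dynamic
#' @param path File path.
#' @export
read_timing <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$FrameTimesStart) || is.null(j$FrameDuration))
    stop("timing JSON needs FrameTimesStart and FrameDuration")
  new_frame_schedule(j$FrameTimesStart, j$FrameDuration, name = j$ProtocolName)
}

#' @rdname read_dynamic
#' @param schedule A `frame_schedule`.
#' @export
write_timing <- function(schedule, path) {
  validate_schedule(schedule)
  obj <- list(FrameTimesStart = schedule$starts,
              FrameDuration = schedule$durations)
  if (!is.null(schedule$name)) obj$ProtocolName <- schedule$name
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read / write time-activity curves as CSV
#'
#' Columns: `frame_start_s`, `frame_duration_s`, `value_kBq_per_mL`.
#' Round trips are lossless at double precision.
#'
#' @param path CSV file path.
#' @param label Role tag for the returned [tac()].
#' @return A [tac()].
#' @export
read_tac <- function(path, label = "tissue") {
  df <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_duration_s", "value_kBq_per_mL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TAC file missing column(s): ", paste(miss, collapse = ", "))
  if (!all(vapply(df[need], is.numeric, logical(1))))
    stop("TAC columns must be numeric")
  sched <- new_frame_schedule(df$frame_start_s, df$frame_duration_s)
  suppressWarnings(tac(sched, df$value_kBq_per_mL, label = label))
}

#' @rdname read_tac
#' @param x A [tac()].
#' @export
write_tac <- function(x, path) {
  utils::write.csv(format(as.data.frame(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a centerline CSV (columns x_mm, y_mm, z_mm)
#'
#' @param path CSV file path.
#' @return A [centerline()].
#' @export
read_centerline <- function(path) {
  centerline(utils::read.csv(path))
}

#' @rdname read_centerline
#' @param cl A [centerline()].
#' @export
write_centerline <- function(cl, path) {
  utils::write.csv(as.data.frame(cl), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a 3D parametric map as NIfTI with a units sidecar
#'
#' @param map 3D numeric array.
#' @param path Output NIfTI path.
#' @param spacing Voxel spacing mm.
#' @param units Unit string recorded in the JSON sidecar.
#' @export
write_map <- function(map, path, spacing = c(4, 4, 2.886),
                      units = "mL/min/cm^3") {
  nii <- RNifti::asNifti(map)
  RNifti::pixdim(nii) <- spacing
  RNifti::sform(nii) <- structure(diag(c(spacing, 1)), code = 2L)
  RNifti::writeNifti(nii, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(Units = units), side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a 3D label/mask NIfTI
#'
#' @param path NIfTI path.
#' @return Integer 3D array.
#' @export
read_labels <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected a 3D label NIfTI")
  array(as.integer(round(arr)), dim = dim(arr))
}
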