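# Acquisition containers and TIFF-backed I/O.
#
# Channel identity is always supplied explicitly by the caller (channel_order);
# it is never guessed from TIFF metadata, because microscope TIFF dialects are
# inconsistent. Pixel grids are (row, column) matrices; intensities are kept
# as read, never rescaled or clipped.

.channel_roles <- c("donor", "acceptor", "autofluo")

.default_channel_meta <- list(
  donor    = list(emission_center_nm = 490, emission_halfwidth_nm = 5),
  acceptor = list(emission_center_nm = 530, emission_halfwidth_nm = 5),
  autofluo = list(emission_center_nm = 600, emission_halfwidth_nm = 5)
)

#' Single-channel image
#'
#' A 2-D grid of non-negative photon counts from one emission window, with
#' the acquisition wavelengths attached. The three windows used throughout
#' are the donor (CFP, 490 +/- 5 nm), acceptor (YFP, 530 +/- 5 nm) and
#' autofluorescence (600 +/- 5 nm) channels.
#'
#' @param pixels numeric matrix of non-negative counts (row, column).
#' @param channel_role one of `"donor"`, `"acceptor"`, `"autofluo"`.
#' @param emission_center_nm,emission_halfwidth_nm emission window (nm).
#' @param excitation_nm excitation wavelength (nm), default 458.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_role,
                          emission_center_nm = NULL,
                          emission_halfwidth_nm = NULL,
                          excitation_nm = 458) {
  channel_role <- match.arg(channel_role, .channel_roles)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixel grid must be at least 1x1")
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel values must be finite and >= 0")
  meta <- .default_channel_meta[[channel_role]]
  if (is.null(emission_center_nm)) emission_center_nm <- meta$emission_center_nm
  if (is.null(emission_halfwidth_nm))
    emission_halfwidth_nm <- meta$emission_halfwidth_nm
  if (emission_center_nm <= excitation_nm)
    stop("emission_center_nm must exceed excitation_nm")
  structure(list(pixels = pixels, channel_role = channel_role,
                 emission_center_nm = emission_center_nm,
                 emission_halfwidth_nm = emission_halfwidth_nm,
                 excitation_nm = excitation_nm),
            class = "channel_image")
}

#' Three-channel acquisition
#'
#' Bundles the three co-registered emission-window images of one confocal
#' acquisition. All three planes must share dimensions and excitation
#' wavelength; a logical saturation mask (pixels at the detector dtype
#' maximum in any channel) can be attached and is excluded downstream.
#'
#' @param donor,acceptor,autofluo [channel_image] objects with matching roles.
#' @param time_index optional non-negative integer frame number.
#' @param sample_id free-text sample identifier.
#' @param saturation optional logical matrix flagging saturated pixels.
#' @param background_corrected logical; set by
#'   [constant_background_subtract()] so [compute_fret_map()] treats the
#'   donor/acceptor channels directly as abundances.
#' @return an object of class `acquisition_set`.
#' @export
acquisition_set <- function(donor, acceptor, autofluo, time_index = NA_integer_,
                            sample_id = "", saturation = NULL,
                            background_corrected = FALSE) {
  chans <- list(donor = donor, acceptor = acceptor, autofluo = autofluo)
  for (role in names(chans)) {
    ch <- chans[[role]]
    if (!inherits(ch, "channel_image")) stop(role, " must be a channel_image")
    if (ch$channel_role != role)
      stop("channel in slot '", role, "' has role '", ch$channel_role, "'")
  }
  dims <- vapply(chans, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all three channels must share identical dimensions")
  exc <- vapply(chans, function(ch) ch$excitation_nm, numeric(1))
  if (length(unique(exc)) != 1L)
    stop("excitation_nm must be identical across channels")
  if (!is.na(time_index) && time_index < 0)
    stop("time_index must be a non-negative integer")
  if (is.null(saturation))
    saturation <- matrix(FALSE, dims[1, 1], dims[2, 1])
  stopifnot(is.logical(saturation), all(dim(saturation) == dims[, 1]))
  structure(list(donor = donor, acceptor = acceptor, autofluo = autofluo,
                 time_index = time_index, sample_id = sample_id,
                 saturation = saturation,
                 background_corrected = isTRUE(background_corrected)),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  d <- dim(x$donor$pixels)
  cat(sprintf("<acquisition_set> %dx%d px, sample '%s'%s\n", d[1], d[2],
              x$sample_id,
              if (!is.na(x$time_index)) sprintf(", t=%d", x$time_index) else ""))
  cat(sprintf("  saturated px: %d; background_corrected: %s\n",
              sum(x$saturation), x$background_corrected))
  invisible(x)
}

#' Integer ROI/cell label mask
#'
#' @param labels matrix of non-negative integers; 0 is background, k > 0
#'   identifies ROI/cell k.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels))
    stop("labels must be a numeric matrix")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "label_mask")
}

#' Per-pixel FRET ratio map
#'
#' @param ratio numeric matrix of acceptor/donor abundance ratios.
#' @param valid logical matrix; ratio is only meaningful where TRUE.
#' @param min_intensity_used intensity threshold (counts) applied when the
#'   map was built.
#' @return an object of class `fret_map`.
#' @export
fret_map <- function(ratio, valid, min_intensity_used) {
  stopifnot(is.matrix(ratio), is.matrix(valid), is.logical(valid),
            all(dim(ratio) == dim(valid)))
  if (any(!is.finite(ratio[valid])))
    stop("ratio must be finite wherever valid")
  structure(list(ratio = ratio, valid = valid,
                 min_intensity_used = min_intensity_used),
            class = "fret_map")
}

.saturation_from_planes <- function(planes) {
  sat <- NULL
  for (m in planes) {
    s <- if (identical(attr(m, "sample_format"), "uint")) {
      m == (2^attr(m, "bits") - 1)
    } else matrix(FALSE, nrow(m), ncol(m))
    sat <- if (is.null(sat)) s else sat | s
  }
  sat
}

#' Read a three-channel acquisition from a multi-page TIFF
#'
#' Pixel data are taken from the file's planes verbatim (cast to double,
#' never rescaled). Saturated pixels of integer inputs (values at the dtype
#' maximum) are flagged in the acquisition's saturation mask.
#'
#' @param path multi-page TIFF with at least three planes.
#' @param channel_order character vector mapping page order to roles, e.g.
#'   `c("donor", "acceptor", "autofluo")`; must cover each role exactly once.
#' @param metadata optional named list of per-role wavelength settings
#'   (each a list with `emission_center_nm`, `emission_halfwidth_nm`).
#' @param excitation_nm excitation wavelength shared by all channels.
#' @param time_index,sample_id acquisition metadata.
#' @return an [acquisition_set()].
#' @export
read_acquisition <- function(path, channel_order, metadata = NULL,
                             excitation_nm = 458, time_index = NA_integer_,
                             sample_id = basename(path)) {
  if (!setequal(channel_order, .channel_roles) ||
      length(channel_order) != 3L)
    stop("channel_order must name donor, acceptor and autofluo exactly once")
  planes <- read_tiff(path)
  if (length(planes) < 3L)
    stop("acquisition TIFF must have at least 3 planes, found ",
         length(planes))
  planes <- planes[1:3]
  dims <- vapply(planes, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("acquisition planes have mismatched dimensions")
  by_role <- list()
  for (i in 1:3) by_role[[channel_order[i]]] <- planes[[i]]
  chans <- lapply(.channel_roles, function(role) {
    meta <- if (!is.null(metadata) && !is.null(metadata[[role]]))
      metadata[[role]] else list()
    channel_image(`attributes<-`(by_role[[role]],
                                 list(dim = dim(by_role[[role]]))),
                  channel_role = role,
                  emission_center_nm = meta$emission_center_nm,
                  emission_halfwidth_nm = meta$emission_halfwidth_nm,
                  excitation_nm = excitation_nm)
  })
  acquisition_set(chans[[1]], chans[[2]], chans[[3]],
                  time_index = time_index, sample_id = sample_id,
                  saturation = .saturation_from_planes(planes))
}

#' Write an acquisition as a 3-page TIFF (donor, acceptor, autofluo order)
#'
#' @param acq an [acquisition_set()].
#' @param path output path.
#' @param dtype TIFF sample type; `"float32"` (default) round-trips counts
#'   exactly for values below 2^24.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path, dtype = "float32") {
  stopifnot(inherits(acq, "acquisition_set"))
  write_tiff(list(acq$donor$pixels, acq$acceptor$pixels, acq$autofluo$pixels),
             path, dtype = dtype)
}

.mask_sidecar_path <- function(path) {
  sub("(\\.[^.]+)?$", "_mask.tif", path)
}

#' Write a FRET map as float32 TIFF plus a sidecar validity mask
#'
#' Invalid pixels are encoded as NaN in the ratio plane; the sidecar
#' `<path>_mask.tif` holds the validity mask as uint8 (1 = valid).
#'
#' @param map a [fret_map()].
#' @param path output path for the ratio TIFF.
#' @return `path`, invisibly.
#' @export
write_fret_map <- function(map, path) {
  stopifnot(inherits(map, "fret_map"))
  ratio <- map$ratio
  ratio[!map$valid] <- NaN
  write_tiff(ratio, path, dtype = "float32")
  write_tiff(matrix(as.numeric(map$valid), nrow(ratio), ncol(ratio)),
             .mask_sidecar_path(path), dtype = "uint8")
  invisible(path)
}

#' Read a FRET map written by [write_fret_map()]
#'
#' @param path ratio TIFF path; the sidecar mask is looked up next to it.
#' @param min_intensity_used threshold to record on the reloaded map.
#' @return a [fret_map()].
#' @export
read_fret_map <- function(path, min_intensity_used = NA_real_) {
  ratio <- read_tiff(path)[[1]]
  mask_path <- .mask_sidecar_path(path)
  valid <- if (file.exists(mask_path)) {
    read_tiff(mask_path)[[1]] > 0
  } else is.finite(ratio)
  ratio[!valid] <- NA_real_
  attributes(ratio) <- list(dim = dim(ratio))
  fret_map(ratio, valid, min_intensity_used)
}

#' Read an integer label mask from a single-plane TIFF
#'
#' @param path TIFF path; pixel values must be integral.
#' @param reference_shape optional `c(rows, cols)` the mask must match.
#' @return a [label_mask()].
#' @export
read_label_mask <- function(path, reference_shape = NULL) {
  m <- read_tiff(path)[[1]]
  if (any(!is.finite(m)) || any(m != round(m)))
    stop("label mask TIFF contains non-integer pixel values")
  if (!is.null(reference_shape) && !all(dim(m) == reference_shape))
    stop(sprintf("label mask is %dx%d but reference shape is %dx%d",
                 nrow(m), ncol(m), reference_shape[1], reference_shape[2]))
  attributes(m) <- list(dim = dim(m))
  label_mask(m)
}

#' Write a label mask as uint16 TIFF
#'
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("labels exceed uint16 range")
  write_tiff(matrix(as.numeric(mask$labels), nrow(mask$labels),
                    ncol(mask$labels)), path, dtype = "uint16")
}

#' Labels present in a mask (background excluded)
#' @param mask a [label_mask()].
#' @return sorted integer vector of ROI ids.
#' @export
roi_ids <- function(mask) {
  ids <- sort(unique(as.vector(mask$labels)))
  ids[ids > 0]
}
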