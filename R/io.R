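# Cube container format: multi-page TIFF (one 16-bit page per time bin, page
# order = increasing time) plus a JSON sidecar carrying {n_bins,
# time_window_ns, image_shape, seed, config echo}. Vendor TCSPC formats are
# out of scope; a reader for another container only needs to produce a
# TCSPCCube to join the pipeline.

sidecarPath <- function(path) sub("\\.tiff?$", ".json", path)

#' Write a TCSPCCube as multi-page TIFF with JSON sidecar
#'
#' Counts are stored as unsigned 16-bit (maximum 65535 per pixel per bin);
#' the round trip through [readTCSPCCube()] is bit-exact.
#'
#' @param cube a [TCSPCCube-class].
#' @param path output TIFF path (the sidecar gets the same basename,
#'   extension `.json`).
#' @return `path`, invisibly.
#' @export
writeTCSPCCube <- function(cube, path) {
  stopifnot(is(cube, "TCSPCCube"))
  cnt <- counts(cube)
  if (max(cnt) > 65535L)
    stop("counts exceed 16-bit range; cannot store as uint16 TIFF")
  pages <- lapply(seq_len(dim(cnt)[3]),
                  function(k) cnt[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(n_bins = dim(cnt)[3], time_window_ns = timeWindow(cube),
                 image_shape = dim(cnt)[1:2]),
            cube@metadata)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a TCSPCCube from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path written by [writeTCSPCCube()].
#' @return a [TCSPCCube-class].
#' @export
readTCSPCCube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  side <- sidecarPath(path)
  if (!file.exists(side)) stop("missing JSON sidecar for cube: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("failed to read TIFF ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    stop("format error in ", path, ": ", length(pages),
         " pages but sidecar declares n_bins = ", meta$n_bins)
  sh <- dim(pages[[1]])
  if (!is.null(meta$image_shape) &&
      !all(sh == unlist(meta$image_shape)))
    stop("format error in ", path, ": page shape ", paste(sh, collapse = "x"),
         " does not match sidecar image_shape")
  arr <- array(0L, dim = c(sh[1], sh[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(pages[[k]])
  extra <- meta[setdiff(names(meta),
                        c("n_bins", "time_window_ns", "image_shape"))]
  TCSPCCube(arr, timeWindow = meta$time_window_ns, metadata = extra)
}

#' Write / read a LifetimeMap as float TIFF plus mask TIFF
#'
#' `path` receives the lifetime image (32-bit float; pixel value =
#' lifetime in ns divided by 64, so the donor band sits well inside the
#' unit range the container requires; invalid pixels are written as 0) and
#' `<path base>_mask.tif` the validity mask (1 = valid). A JSON sidecar
#' records the scale, bin width and photon counts. The round trip preserves
#' lifetimes to 32-bit float precision (about 1e-7 relative).
#'
#' @param map a [LifetimeMap-class].
#' @param path output TIFF path.
#' @return `writeLifetimeMap` returns `path` invisibly; `readLifetimeMap`
#'   a [LifetimeMap-class].
#' @export
writeLifetimeMap <- function(map, path) {
  stopifnot(is(map, "LifetimeMap"))
  scale <- 64
  tau <- tauMap(map) / scale
  tau[!validMask(map)] <- 0
  if (any(tau >= 1))
    stop("lifetime exceeds the storable range (", scale, " ns)")
  tiff::writeTIFF(tau, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  maskPath <- sub("(\\.tiff?)$", "_mask\\1", path)
  tiff::writeTIFF(validMask(map) * 1, maskPath, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(tau_scale_ns = scale, bin_width_ns = map@binWidth,
                            photons = as.vector(photonMap(map)),
                            shape = dim(tauMap(map))),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLifetimeMap
#' @export
readLifetimeMap <- function(path) {
  if (!file.exists(path)) stop("lifetime map not found: ", path)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  tau <- tiff::readTIFF(path) * meta$tau_scale_ns
  maskPath <- sub("(\\.tiff?)$", "_mask\\1", path)
  valid <- tiff::readTIFF(maskPath) > 0.5
  tau[!valid] <- NA_real_
  new("LifetimeMap", tau = tau, valid = valid,
      photons = matrix(meta$photons, meta$shape[1], meta$shape[2]),
      binWidth = meta$bin_width_ns, metadata = list())
}
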