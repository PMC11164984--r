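#' Parse a channel file name
#'
#' File names follow the convention `[image name]_c[channel ID].[ext]` with
#' extension tiff/tif/jpg/jpeg/png. The name is split at the LAST underscore,
#' so the sample name may itself contain underscores
#' (`20231212_HEK293_HAP40_c1.tiff` names sample `20231212_HEK293_HAP40`,
#' channel 1).
#'
#' @param filename file name (with or without directory part).
#' @return list with `sampleName` (character) and `channelId` (integer >= 1).
#' @examples
#' parseImageName("20231212_HEK293_HAP40_c1.tiff")
#' @export
parseImageName <- function(filename) {
  base <- basename(filename)
  ext <- tolower(sub(".*\\.", "", base))
  if (!ext %in% c("tiff", "tif", "jpg", "jpeg", "png"))
    stop("unsupported image format '.", ext, "' in file '", base,
         "' (expected tiff/tif/jpg/jpeg/png)")
  stem <- sub("\\.[^.]*$", "", base)
  m <- regmatches(stem, regexec("^(.*)_c([0-9]+)$", stem))[[1]]
  if (length(m) != 3L || m[2] == "")
    stop("file '", base, "' does not follow the naming convention ",
         "'[image name]_c[channel ID].", ext, "'")
  id <- as.integer(m[3])
  if (id < 1L)
    stop("channel ID in '", base, "' must be >= 1")
  list(sampleName = m[2], channelId = id)
}

# Read one channel file into a [0,1] matrix. EBImage scales integer
# containers by their bit-depth maximum, preserving cross-image
# comparability for images captured with identical settings. RGB planes are
# collapsed to one grayscale plane by Rec. 709 luminance, with a warning.
readChannelRaster <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    warning("file '", basename(path), "' stores ", dim(a)[3],
            " colour planes; collapsing to one grayscale plane by luminance",
            call. = FALSE)
    if (dim(a)[3] >= 3L) {
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  # EBImage stores images x-by-y; transpose to row = image row
  m <- t(as.matrix(a))
  clip01(m)
}

#' Load all images of one biological condition
#'
#' Reads every parsable image file in `folder`, groups files by sample name,
#' orders channels by channel ID, and rescales intensities to \[0, 1\] by the
#' container bit depth. Channel IDs must be contiguous from 1; gaps, channel
#' count mismatches between samples, and dimension mismatches within a
#' sample are errors.
#'
#' @param folder directory holding the condition's channel files.
#' @param label condition name attached to the group.
#' @return an [ImageGroup-class].
#' @export
loadImageGroup <- function(folder, label = basename(folder)) {
  if (!dir.exists(folder)) stop("folder '", folder, "' does not exist")
  files <- list.files(folder, pattern = "\\.(tiff|tif|jpg|jpeg|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("folder '", folder, "' contains no image files")
  parsed <- lapply(files, parseImageName)
  samples <- vapply(parsed, `[[`, character(1), "sampleName")
  ids <- vapply(parsed, `[[`, integer(1), "channelId")
  images <- lapply(sort(unique(samples)), function(s) {
    sel <- which(samples == s)
    sid <- ids[sel]
    if (anyDuplicated(sid))
      stop("sample '", s, "' has duplicate channel files")
    if (!identical(sort(sid), seq_len(max(sid))))
      stop("sample '", s, "' has non-contiguous channel IDs (found c",
           paste(sort(sid), collapse = ", c"), "); channels must be 1..k")
    ord <- sel[order(sid)]
    rasters <- lapply(files[ord], readChannelRaster)
    d <- vapply(rasters, dim, integer(2))
    if (any(d != d[, 1]))
      stop("sample '", s, "' has channels with mismatched dimensions")
    MultiChannelImage(s, rasters)
  })
  k <- vapply(images, nChannels, integer(1))
  if (length(unique(k)) > 1L)
    stop("folder '", folder, "' mixes images with different channel counts (",
         paste(sort(unique(k)), collapse = ", "), ")")
  ImageGroup(label, images)
}

#' Write a multichannel image to disk under the naming convention
#'
#' One 16-bit grayscale TIFF per channel, named `<name>_c<id>.tiff`.
#'
#' @param image a [MultiChannelImage-class].
#' @param folder destination directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeImageChannels <- function(image, folder) {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nChannels(image))
  for (i in seq_len(nChannels(image))) {
    paths[i] <- file.path(folder,
                          sprintf("%s_c%d.tiff", imageName(image), i))
    # EBImage expects x-by-y orientation
    EBImage::writeImage(EBImage::Image(t(channelData(image, i))),
                        paths[i], bits.per.sample = 16L)
  }
  invisible(paths)
}
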