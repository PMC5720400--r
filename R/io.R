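# MetaImage (MHD + raw) and TIFF export.  MetaImage is the de-facto plain
# exchange format for projection stacks and volumes in CT tooling: a short
# ASCII header next to a raw little-endian data file.

#' Write a 3D array as a MetaImage (.mhd + .raw) pair
#'
#' @param values 2D or 3D numeric array.
#' @param path Output path ending in `.mhd`.
#' @param spacing Element spacing (mm), recycled to 3.
#' @param metadata Named character vector of extra header fields.
#' @return The header path, invisibly.
#' @export
write_mhd <- function(values, path, spacing = c(1, 1, 1), metadata = NULL) {
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3, grepl("\\.mhd$", path))
  spacing <- rep_len(spacing, 3)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("ElementSpacing = %g %g %g", spacing[1], spacing[2], spacing[3]),
    sprintf("DimSize = %d %d %d", dim(values)[1], dim(values)[2], dim(values)[3]),
    "ElementType = MET_DOUBLE",
    if (!is.null(metadata)) sprintf("%s = %s", names(metadata), metadata),
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.double(values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) pair
#'
#' Supports the subset written by [write_mhd()] (3D, uncompressed,
#' little-endian `MET_DOUBLE`/`MET_FLOAT`).
#'
#' @param path Path to the `.mhd` header.
#' @return A list with `values` (3D array), `spacing`, and `metadata`
#'   (all non-standard header fields).
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), character(1))
  get <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(get("DimSize"), " ")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " ")[[1]])
  type <- get("ElementType")
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported ElementType: ", type))
  if (identical(get("CompressedData"), "True")) stop("compressed MetaImage not supported")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  values <- readBin(con, "double", n = n, size = size, endian = "little")
  std <- c("ObjectType", "NDims", "BinaryData", "BinaryDataByteOrderMSB",
           "ElementSpacing", "DimSize", "ElementType", "ElementDataFile",
           "CompressedData")
  extra <- !(keys %in% std)
  list(values = array(values, dims), spacing = spacing,
       metadata = stats::setNames(vals[extra], keys[extra]))
}

#' Write a projection stack as MetaImage
#'
#' The stack's pixel pitch becomes the element spacing (third axis: view
#' index); plane type, angles and `i0` are stored as header metadata.
#'
#' @param stack A [projection_stack()].
#' @param path Output `.mhd` path.
#' @param geometry A [cone_beam_geometry()] (for the pixel pitch).
#' @return The header path, invisibly.
#' @export
write_stack_mhd <- function(stack, path, geometry) {
  write_mhd(stack$values, path,
            spacing = c(geometry$pitch_u, geometry$pitch_v, 1),
            metadata = c(Plane = stack$plane,
                         I0 = format(stack$i0),
                         Angles = paste(format(stack$angles, trim = TRUE),
                                        collapse = " ")))
}

#' Write a reconstructed volume as MetaImage
#'
#' @param volume A [fdk_reconstruct()] result.
#' @param path Output `.mhd` path.
#' @return The header path, invisibly.
#' @export
write_volume_mhd <- function(volume, path) {
  write_mhd(volume$values, path, spacing = rep(volume$grid$voxel_size, 3))
}

#' Export a detector image or mask as 8-bit TIFF
#'
#' Values are rescaled to `[0, 1]` over `range` (defaults to the data range)
#' for visual inspection.
#'
#' @param image Matrix (e.g. one view, or a mask's `values`).
#' @param path Output `.tif` path.
#' @param range Length-2 display range.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(image, path, range = NULL) {
  if (inherits(image, "detector_mask")) image <- image$values
  if (is.null(range)) range <- range(image)
  span <- diff(range)
  scaled <- if (span > 0) (image - range[1]) / span else image * 0
  # transpose so v runs down the page
  tiff::writeTIFF(t(pmin(pmax(scaled, 0), 1)), path, bits.per.sample = 8L)
  invisible(path)
}
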