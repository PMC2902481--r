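## Volume readers/writers.
##
## MetaImage (.mha/.mhd) support is written here directly: the format is a
## plain key = value header followed (for .mha) by a raw data block, or (for
## .mhd) by a sidecar .raw file.  Only uncompressed, axis-aligned 3D images
## with 1 or 3 channels are supported, which covers scalar volumes, label
## masks and dense displacement fields.  NIfTI goes through RNifti.

.met_types <- c(MET_UCHAR = "uint8", MET_CHAR = "int8",
                MET_USHORT = "uint16", MET_SHORT = "int16",
                MET_UINT = "uint32", MET_INT = "int32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_mha_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  offset <- 0L
  repeat {
    line <- character()
    repeat {
      ch <- readBin(con, "raw", 1L)
      offset <- offset + 1L
      if (length(ch) == 0L) stop("unexpected end of MetaImage header in ", path)
      if (ch == as.raw(10L)) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line in ", path, ": ", line)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  list(header = hdr, data_offset = offset)
}

#' Read a 3D volume (MetaImage or NIfTI)
#'
#' Format is chosen from the file extension: `.mha`/`.mhd` (MetaImage,
#' uncompressed) or `.nii`/`.nii.gz` (NIfTI).  Values are converted to
#' doubles; geometry (dims, spacing, origin) comes from the header.
#'
#' @param path path to the volume file.
#' @return A [volume_image()].  For 3-channel MetaImage files (displacement
#'   fields) a list of three `volume_image`s, one per component.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".mha", ".mhd")) {
    read_volume_mha(path)
  } else if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("not a 3D volume (", length(d), "D): ", path)
    sp <- RNifti::pixdim(img)[seq_len(3)]
    # sform/qform origin; axis-aligned volumes only, so take the translation
    xf <- RNifti::xform(img)
    orig <- xf[seq_len(3), 4]
    # NIfTI is RAS with possible axis flips; we keep axis-aligned positive
    # spacing and the translation column as origin
    volume_image(array(as.numeric(img), dim = d),
                 volume_geometry(d, abs(sp), orig))
  } else {
    stop("unsupported volume format: ", path)
  }
}

read_volume_mha <- function(path) {
  h <- read_mha_header(path)
  hdr <- h$header
  ndims <- as.integer(hdr[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop("not a 3D MetaImage volume (NDims=", hdr[["NDims"]], "): ", path)
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE")
    stop("compressed MetaImage data not supported: ", path)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  nchan <- if (!is.null(hdr[["ElementNumberOfChannels"]]))
    as.integer(hdr[["ElementNumberOfChannels"]]) else 1L
  met <- hdr[["ElementType"]]
  if (!met %in% names(.met_types)) stop("unsupported ElementType ", met)
  rtype <- .met_types[[met]]
  size <- c(uint8 = 1L, int8 = 1L, uint16 = 2L, int16 = 2L,
            uint32 = 4L, int32 = 4L, float32 = 4L, float64 = 8L)[[rtype]]
  n <- prod(dims) * nchan
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    readBin(con, "raw", h$data_offset)
  } else {
    con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(con), add = TRUE)
  }
  what <- if (rtype %in% c("float32", "float64")) "double" else "integer"
  vals <- readBin(con, what, n = n,
                  size = size,
                  signed = !(rtype %in% c("uint8", "uint16")),
                  endian = "little")
  if (length(vals) != n) stop("truncated MetaImage data block: ", path)
  geom <- volume_geometry(dims, spacing, origin)
  if (nchan == 1L) {
    volume_image(array(as.numeric(vals), dim = dims), geom)
  } else {
    # channels interleaved fastest
    arr <- array(as.numeric(vals), dim = c(nchan, dims))
    lapply(seq_len(nchan), function(k)
      volume_image(array(arr[k, , , ], dim = dims), geom))
  }
}

#' Write a 3D volume
#'
#' @param vol a [volume_image()], or a list of three of them sharing one
#'   geometry (written as a 3-channel MetaImage displacement field).
#' @param path output path; extension selects MetaImage (`.mha`) or NIfTI
#'   (`.nii`/`.nii.gz`).
#' @param element_type MetaImage scalar type (default `MET_DOUBLE`; use
#'   `MET_SHORT` or `MET_FLOAT` for compactness).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, element_type = "MET_DOUBLE") {
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  multi <- !inherits(vol, "volume_image")
  if (multi) {
    stopifnot(is.list(vol), length(vol) == 3L,
              all(vapply(vol, inherits, logical(1), "volume_image")))
  }
  if (ext == ".mha") {
    geom <- if (multi) vol[[1]]$geometry else vol$geometry
    rtype <- .met_types[[element_type]]
    if (is.null(rtype)) stop("unsupported element_type ", element_type)
    size <- c(uint8 = 1L, int8 = 1L, uint16 = 2L, int16 = 2L,
              uint32 = 4L, int32 = 4L, float32 = 4L, float64 = 8L)[[rtype]]
    nchan <- if (multi) 3L else 1L
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    hdr <- c("ObjectType = Image",
             "NDims = 3",
             "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             "CompressedData = False",
             paste("DimSize =", paste(geom$dims, collapse = " ")),
             paste("ElementSpacing =", paste(format(geom$spacing, digits = 17), collapse = " ")),
             paste("Offset =", paste(format(geom$origin, digits = 17), collapse = " ")),
             if (nchan > 1L) paste("ElementNumberOfChannels =", nchan),
             paste("ElementType =", element_type),
             "ElementDataFile = LOCAL")
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    vals <- if (multi) {
      as.vector(aperm(array(c(vol[[1]]$values, vol[[2]]$values, vol[[3]]$values),
                            dim = c(geom$dims, 3L)), c(4, 1, 2, 3)))
    } else as.vector(vol$values)
    if (rtype %in% c("float32", "float64")) {
      writeBin(as.numeric(vals), con, size = size, endian = "little")
    } else {
      writeBin(as.integer(round(vals)), con, size = size, endian = "little")
    }
  } else if (ext %in% c(".nii", ".nii.gz")) {
    if (multi) stop("multi-channel NIfTI output not supported; use .mha")
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$geometry$spacing
    xf <- diag(4)
    diag(xf)[seq_len(3)] <- vol$geometry$spacing
    xf[seq_len(3), 4] <- vol$geometry$origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname read_volume
#' @param mask a [region_mask()] to write; label names go to a `<path>.labels.json`
#'   sidecar so masks round-trip with their region names.
#' @export
write_mask <- function(mask, path) {
  write_volume(volume_image(mask$labels + 0, mask$geometry), path,
               element_type = "MET_SHORT")
  jsonlite::write_json(as.list(mask$label_names),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  side <- paste0(path, ".labels.json")
  nm <- if (file.exists(side)) {
    l <- jsonlite::read_json(side)
    stats::setNames(as.integer(unlist(l)), names(l))
  } else {
    labs <- sort(unique(as.integer(vol$values)))
    labs <- labs[labs > 0]
    stats::setNames(labs, paste0("label_", labs))
  }
  region_mask(array(as.integer(round(vol$values)), dim = vol$geometry$dims),
              vol$geometry, nm)
}

#' Read/write a dense displacement field (3-channel MetaImage)
#'
#' @param field list of three [volume_image()]s (x, y, z displacement in mm).
#' @param path `.mha` path.
#' @export
write_displacement_field <- function(field, path) {
  write_volume(field, path, element_type = "MET_FLOAT")
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  f <- read_volume(path)
  if (inherits(f, "volume_image") || length(f) != 3L)
    stop("not a 3-component displacement field: ", path)
  f
}
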