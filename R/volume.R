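#' 3D scalar volume with world-space metadata
#'
#' A thin container for a 3D intensity grid plus the geometry needed to place
#' it in world (scanner) space: per-axis voxel spacing in mm and the world
#' coordinate of voxel `(1, 1, 1)`. Voxel `(i, j, k)` sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data A numeric 3D array.
#' @param spacing Length-3 positive voxel size in mm.
#' @param origin Length-3 world coordinate of the first voxel, in mm.
#' @param mask Optional logical array of the same dimensions flagging valid
#'   voxels (used to exclude out-of-field voxels from similarity metrics).
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), spacing = c(2.59, 2.59, 8))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     mask = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array.", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values.", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values.", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("Volume data must be finite.", call. = FALSE)
  if (!is.null(mask) && !identical(dim(mask), dim(data))) {
    stop("`mask` must match the data dimensions.", call. = FALSE)
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume3d> ", d[1], "x", d[2], "x", d[3],
      " | spacing ", paste(x$spacing, collapse = " x "), " mm",
      " | origin (", paste(signif(x$origin, 6), collapse = ", "), ")\n",
      sep = "")
  cat("  intensity range: [", paste(signif(range(x$data), 6), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' World-space center of a volume
#'
#' The world coordinate of the geometric center of the field of view; the
#' conventional rotation center for rigid registration in this package.
#'
#' @param volume A [volume3d()].
#' @return Length-3 numeric world point in mm.
#' @export
volume_center <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  volume$origin + (dim(volume$data) - 1) / 2 * volume$spacing
}

# World coordinates of every voxel center, as an n x 3 matrix in array order.
voxel_world_coordinates <- function(volume) {
  d <- dim(volume$data)
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  zs <- volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Read and write volumes
#'
#' `read_volume()` / `write_volume()` handle NIfTI (`.nii`, `.nii.gz`,
#' via RNifti) and MetaImage (`.mha`, or `.mhd` + raw file) formats,
#' preserving voxel spacing and origin.
#'
#' @param path File path; the extension selects the format.
#' @param volume A [volume3d()].
#' @return `read_volume()` returns a [volume3d()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    xf <- RNifti::xform(img)
    # we write axis-aligned affines; spacing = column norms, origin = offset
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    volume3d(arr, spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_metaimage(path)
  } else {
    stop("Unsupported volume format: ", path, call. = FALSE)
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    affine <- diag(4)
    diag(affine)[1:3] <- volume$spacing
    affine[1:3, 4] <- volume$origin
    img <- RNifti::asNifti(volume$data)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_metaimage(volume, path)
  } else {
    stop("Unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

# --- Minimal MetaImage support (uncompressed, local or .raw data) ----------
# No installed R package reads MetaImage, so a small reader/writer for the
# common uncompressed cases lives here.

meta_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
                MET_USHORT = "integer", MET_INT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
meta_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("Malformed MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) {
    stop("Only 3D MetaImage volumes are supported.", call. = FALSE)
  }
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE") {
    stop("Compressed MetaImage data is not supported.", call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]])) {
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  } else c(1, 1, 1)
  origin <- if (!is.null(hdr[["Offset"]])) {
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  } else c(0, 0, 0)
  etype <- hdr[["ElementType"]]
  if (!etype %in% names(meta_types)) {
    stop("Unsupported MetaImage element type: ", etype, call. = FALSE)
  }
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  read_payload <- function(cn) {
    readBin(cn, what = meta_types[[etype]], n = n,
            size = meta_sizes[[etype]], endian = "little",
            signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  }
  vals <- if (toupper(datafile) == "LOCAL") {
    read_payload(con)
  } else {
    raw_path <- file.path(dirname(path), datafile)
    cn2 <- file(raw_path, "rb")
    on.exit(close(cn2), add = TRUE)
    read_payload(cn2)
  }
  if (length(vals) != n) stop("Truncated MetaImage data: ", path, call. = FALSE)
  volume3d(array(as.numeric(vals), dim = dims), spacing = spacing,
           origin = origin)
}

write_metaimage <- function(volume, path) {
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else {
    sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  }
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(volume$data), collapse = " ")),
    paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
    paste("Offset =", paste(volume$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (local) {
    writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.numeric(volume$data), con2, size = 8L, endian = "little")
    close(con2)
  }
  invisible(path)
}
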