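#' Read a 3D volume from disk
#'
#' Supported containers: MHD header + raw (`.mhd`, lossless doubles or
#' floats, voxel size from the `ElementSpacing` header in nm) and multipage
#' TIFF stacks (`.tif`/`.tiff`, one page per z-slice, values in [0, 1]; TIFF
#' carries no physical voxel size here, so `voxel_size_nm` must be given).
#' Arrays are `[x, y, z]` with index origin 1 (see [scalar_volume()]).
#'
#' @param path file path.
#' @param voxel_size_nm voxel size override (required for TIFF without one).
#' @return an [scalar_volume()].
#' @export
read_volume <- function(path, voxel_size_nm = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") {
    hdr <- read_mhd_header(path)
    dims <- hdr$DimSize
    spacing <- hdr$ElementSpacing
    if (is.null(voxel_size_nm)) {
      if (is.null(spacing)) stop("no ElementSpacing in header: pass voxel_size_nm explicitly")
      if (diff(range(spacing)) > 1e-9 * max(spacing))
        stop("anisotropic spacing unsupported")
      voxel_size_nm <- spacing[1]
    }
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    type <- switch(hdr$ElementType, MET_DOUBLE = "double", MET_FLOAT = "float",
                   stop("unsupported ElementType: ", hdr$ElementType))
    n <- prod(dims)
    con <- file(raw_path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n,
                    size = if (type == "float") 4L else 8L, endian = "little")
    if (length(vals) != n)
      stop(sprintf("raw data truncated: header declares %d voxels, file holds %d",
                   n, length(vals)))
    origin <- if (!is.null(hdr$Offset)) hdr$Offset / 1000 else c(0, 0, 0)
    scalar_volume(array(vals, dim = dims), voxel_size_nm, origin)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(voxel_size_nm))
      stop("TIFF carries no voxel size: pass voxel_size_nm explicitly")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d1 <- dim(pages[[1]])
    vals <- array(0, dim = c(d1[1], d1[2], length(pages)))
    for (k in seq_along(pages)) {
      if (!identical(dim(pages[[k]])[1:2], d1[1:2]))
        stop(sprintf("page %d has dimensions %s, expected %s", k,
                     paste(dim(pages[[k]]), collapse = "x"),
                     paste(d1[1:2], collapse = "x")))
      vals[, , k] <- pages[[k]]
    }
    scalar_volume(vals, voxel_size_nm)
  } else {
    stop("unsupported volume container: .", ext)
  }
}

read_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  hdr <- list()
  for (p in kv) {
    if (length(p) != 2) next
    key <- trimws(p[1])
    val <- trimws(p[2])
    hdr[[key]] <- val
  }
  for (num in c("DimSize", "ElementSpacing", "Offset", "NDims"))
    if (!is.null(hdr[[num]]))
      hdr[[num]] <- as.numeric(strsplit(hdr[[num]], "\\s+")[[1]])
  hdr
}

#' Write a 3D volume to disk
#'
#' `.mhd` writes an MHD text header plus a little-endian raw file of doubles
#' (lossless; `ElementSpacing` and `Offset` stored in nm). `.tif`/`.tiff`
#' writes a multipage 32-bit float TIFF, which requires gray values in
#' [0, 1].
#'
#' @param vol an [scalar_volume()].
#' @param path output path; the container is chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lcn_volume"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(vol$values)
  if (ext == "mhd") {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c("ObjectType = Image",
             "NDims = 3",
             paste("DimSize =", paste(d, collapse = " ")),
             "ElementType = MET_DOUBLE",
             paste("ElementSpacing =", paste(rep(vol$voxel_size_nm, 3), collapse = " ")),
             paste("Offset =", paste(vol$origin_um * 1000, collapse = " ")),
             "ElementByteOrderMSB = False",
             paste("ElementDataFile =", raw_name))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    if (min(vol$values) < 0 || max(vol$values) > 1)
      stop("TIFF output requires gray values in [0, 1]; rescale or use .mhd")
    pages <- lapply(seq_len(d[3]), function(k) vol$values[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  } else {
    stop("unsupported volume container: .", ext)
  }
  invisible(path)
}
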