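# TrackVis .trk binary codec (version 2, 1000-byte header). Coordinates are
# stored in the format's voxel-mm convention, which is how this package
# represents streamlines internally, so writing is a direct dump.

trk_header_template <- function(dims, voxel_mm, n_count) {
  list(dims = as.integer(dims), voxel_mm = as.numeric(voxel_mm),
       n_count = as.integer(n_count))
}

#' Write a tractogram in TrackVis .trk format
#'
#' @param tract A `tractogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, nbytes) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(nbytes - length(raw))), con)
  }
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  dims <- if (all(tract$dims > 0)) tract$dims else c(1L, 1L, 1L)
  wchar("TRACK", 6)                          # id_string
  wi16(dims)                                 # dim[3]
  wf32(tract$voxel_mm)                       # voxel_size[3]
  wf32(c(0, 0, 0))                           # origin[3]
  wi16(0)                                    # n_scalars
  wchar("", 200)                             # scalar_name[10][20]
  wi16(0)                                    # n_properties
  wchar("", 200)                             # property_name[10][20]
  vox2ras <- diag(c(tract$voxel_mm, 1))      # voxmm -> RAS
  wf32(as.numeric(t(vox2ras)))               # vox_to_ras[4][4], row-major
  wchar("", 444)                             # reserved
  wchar("RAS", 4)                            # voxel_order
  wchar("", 4)                               # pad2
  wf32(c(1, 0, 0, 0, 1, 0))                  # image_orientation_patient
  wchar("", 2)                               # pad1
  writeBin(as.raw(rep(0, 6)), con)           # invert/swap flags
  wi32(length(tract$streamlines))            # n_count
  wi32(2)                                    # version
  wi32(1000)                                 # hdr_size
  for (m in tract$streamlines) {
    wi32(nrow(m))
    wf32(as.numeric(t(m)))
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' @param path Input path.
#' @return A `tractogram` (params set to defaults; streamline step length is
#'   whatever the file contains).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic_raw <- readBin(con, "raw", 6)
  magic <- rawToChar(magic_raw[magic_raw != 0])
  if (!identical(magic, "TRACK")) {
    abort(sprintf("not a TrackVis file (magic '%s')", magic),
          class = "microdki_format_error")
  }
  dims <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_mm <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  invisible(readBin(con, "numeric", 16, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 444))
  invisible(readBin(con, "raw", 4)) # voxel_order
  invisible(readBin(con, "raw", 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 2))
  invisible(readBin(con, "raw", 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # version
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 1000L)) {
    abort(sprintf("unexpected .trk header size %d", hdr_size),
          class = "microdki_format_error")
  }
  streamlines <- vector("list", max(n_count, 0))
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    i <- i + 1L
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) {
      invisible(readBin(con, "numeric", n_props, size = 4, endian = "little"))
    }
    if (i <= length(streamlines)) streamlines[[i]] <- m else
      streamlines <- c(streamlines, list(m))
  }
  if (i != n_count) {
    abort(sprintf(".trk header promises %d streamlines, found %d", n_count, i),
          class = "microdki_format_error")
  }
  lens <- vapply(streamlines, function(m) {
    if (nrow(m) < 2) return(0)
    sum(sqrt(rowSums(diff(m)^2)))
  }, numeric(1))
  structure(list(streamlines = streamlines, lengths = lens,
                 seed_index = rep(NA_integer_, n_count),
                 params = tracking_params(), voxel_mm = voxel_mm,
                 dims = dims),
            class = "tractogram")
}
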