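#' @useDynLib lobulae, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif dgamma pt qnorm pchisq pf var sd convolve
#' @importFrom stats approx setNames cov contr.helmert
#' @importFrom utils write.table read.table
NULL

# 26-neighbourhood offsets (3x3x3 cube minus the centre), one row per offset.
neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Shift a 3D array by an integer voxel offset
#'
#' Voxels shifted in from outside the grid take the value `fill`.
#'
#' @param a 3D array.
#' @param d integer offset `c(dx, dy, dz)`; positive shifts move content
#'   towards higher indices.
#' @param fill value used for voxels with no source (default 0 / FALSE).
#' @return array of the same dimension and type as `a`.
#' @keywords internal
shift3d <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  idx_dst <- idx_src <- vector("list", 3L)
  for (i in 1:3) {
    if (abs(d[i]) >= dm[i]) return(out)
    if (d[i] >= 0) {
      idx_dst[[i]] <- (1L + d[i]):dm[i]
      idx_src[[i]] <- 1L:(dm[i] - d[i])
    } else {
      idx_dst[[i]] <- 1L:(dm[i] + d[i])
      idx_src[[i]] <- (1L - d[i]):dm[i]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' One-voxel 26-connected dilation
#'
#' Expands a binary mask by one voxel in every direction in 3D, i.e. with the
#' 3x3x3 (26-neighbour) structuring element.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
dilate26 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- mask > 0
  out <- mask
  offs <- neighbour_offsets_26()
  for (k in seq_len(nrow(offs))) out <- out | shift3d(mask, offs[k, ])
  out
}

#' One-voxel 26-connected erosion
#'
#' Voxels outside the grid count as background, so mask voxels on the grid
#' border always erode away.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
erode26 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- mask > 0
  out <- mask
  offs <- neighbour_offsets_26()
  for (k in seq_len(nrow(offs))) out <- out & shift3d(mask, offs[k, ])
  out
}

#' 26-connected component labelling of a binary mask
#'
#' @param mask logical 3D array.
#' @return integer array: 0 background, components numbered 1, 2, ... in
#'   order of first (column-major) occurrence.
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  mask <- mask > 0
  lab <- array(0L, dm)
  offs <- neighbour_offsets_26()
  seeds <- which(mask)
  nxt <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      co <- arrayInd(frontier, dm)
      nb <- NULL
      for (k in seq_len(nrow(offs))) {
        cand <- sweep(co, 2L, offs[k, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
          cand[, 2] >= 1 & cand[, 2] <= dm[2] &
          cand[, 3] >= 1 & cand[, 3] <= dm[3]
        if (!any(ok)) next
        lin <- cand[ok, 1] + dm[1] * (cand[ok, 2] - 1L) +
          dm[1] * dm[2] * (cand[ok, 3] - 1L)
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- nxt
          nb <- c(nb, lin)
        }
      }
      frontier <- unique(nb)
    }
  }
  lab
}

nifti_datatype_table <- function() {
  data.frame(
    name = c("uint8", "int16", "int32", "float32", "float64"),
    code = c(2L, 4L, 8L, 16L, 64L),
    bitpix = c(8L, 16L, 32L, 32L, 64L),
    stringsAsFactors = FALSE
  )
}

#' Write a 3D/4D volume as NIfTI-1
#'
#' Minimal NIfTI-1 writer (little-endian, single file, `n+1` magic).  The
#' sform is a diagonal scaling by the voxel size with the origin at voxel
#' (1,1,1); for 4D data the repetition time is stored in `pixdim[4]`
#' (seconds).  The default `float64` datatype round-trips R doubles
#' bit-identically.
#'
#' @param data numeric/logical 3D or 4D array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size_mm positive length-3 voxel size in mm.
#' @param tr_s repetition time in seconds (4D only; NA to omit).
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = c(1, 1, 1),
                         tr_s = NA_real_,
                         datatype = c("float64", "float32", "int16",
                                      "int32", "uint8")) {
  datatype <- match.arg(datatype)
  dm <- dim(data)
  if (is.null(dm) || !(length(dm) %in% c(3L, 4L)))
    stop("write_volume: data must be a 3D or 4D array")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  dt <- nifti_datatype_table()
  dt <- dt[dt$name == datatype, ]
  ndim <- length(dm)
  dim8 <- rep(1L, 8L); dim8[1] <- ndim; dim8[1 + seq_len(ndim)] <- dm
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- voxel_size_mm
  if (ndim == 4L && !is.na(tr_s)) pixdim[5] <- tr_s

  pad <- function(n) raw(n)
  chr <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    r
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer")
    writeBin(as.vector(x), con, size = size, endian = "little")
  writeBin(348L, con, size = 4L, endian = "little")
  writeBin(pad(35L), con)                       # data_type, db_name, extents, ...
  writeBin(pad(1L), con)                        # dim_info
  w(as.integer(dim8), 2L)                       # dim[8]
  w(numeric(3), 4L)                             # intent_p1..p3
  w(0L, 2L)                                     # intent_code
  w(dt$code, 2L)                                # datatype
  w(dt$bitpix, 2L)                              # bitpix
  w(0L, 2L)                                     # slice_start
  w(pixdim, 4L)                                 # pixdim[8]
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(0L, 2L)                                     # slice_end
  writeBin(pad(1L), con)                        # slice_code
  writeBin(as.raw(10L), con)                    # xyzt_units: mm | sec
  w(numeric(4), 4L)                             # cal_max, cal_min, slice_duration, toffset
  w(integer(2), 4L)                             # glmax, glmin
  writeBin(chr("lobulae", 80L), con)            # descrip
  writeBin(pad(24L), con)                       # aux_file
  w(0L, 2L)                                     # qform_code
  w(1L, 2L)                                     # sform_code
  w(numeric(6), 4L)                             # quatern b,c,d + qoffset x,y,z
  w(c(voxel_size_mm[1], 0, 0, 0), 4L)           # srow_x
  w(c(0, voxel_size_mm[2], 0, 0), 4L)           # srow_y
  w(c(0, 0, voxel_size_mm[3], 0), 4L)           # srow_z
  writeBin(pad(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                        # extender
  vals <- as.vector(data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    storage.mode(vals) <- "integer"
    writeBin(vals, con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads plain or gzipped single-file NIfTI-1, either endianness, datatypes
#' uint8/int16/int32/float32/float64, applying `scl_slope`/`scl_inter` when
#' set.
#'
#' @param path file path.
#' @return list with `data` (array), `voxel_size_mm`, `tr_s` (NA for 3D),
#'   and `datatype`.
#' @export
read_volume <- function(path) {
  con <- gzfile(path, "rb")   # transparently handles uncompressed files
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("read_volume: truncated NIfTI header")
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L)
      stop("read_volume: not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  dim8 <- rd(40L, "integer", 8L, 2L, endian)
  code <- rd(70L, "integer", 1L, 2L, endian)
  pixdim <- rd(76L, "numeric", 8L, 4L, endian)
  vox_offset <- rd(108L, "numeric", 1L, 4L, endian)
  scl_slope <- rd(112L, "numeric", 1L, 4L, endian)
  scl_inter <- rd(116L, "numeric", 1L, 4L, endian)
  dt <- nifti_datatype_table()
  dt <- dt[dt$code == code, ]
  if (nrow(dt) != 1L)
    stop("read_volume: unsupported NIfTI datatype code ", code)
  ndim <- dim8[1]
  if (!(ndim %in% c(3L, 4L))) stop("read_volume: only 3D/4D supported")
  dm <- dim8[1 + seq_len(ndim)]
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dm)
  vals <- if (dt$name %in% c("float32", "float64")) {
    readBin(con, "numeric", n = n, size = dt$bitpix / 8L, endian = endian)
  } else if (dt$name == "uint8") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = dt$bitpix / 8L, endian = endian,
            signed = TRUE)
  }
  if (length(vals) != n) stop("read_volume: truncated data section")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(
    data = array(vals, dm),
    voxel_size_mm = pixdim[2:4],
    tr_s = if (ndim == 4L && pixdim[5] > 0) pixdim[5] else NA_real_,
    datatype = dt$name
  )
}

#' Voxel indices to mm coordinates
#'
#' The frame used throughout the package: origin at the centre of voxel
#' (1,1,1), axis 1 left-to-right, axis 2 posterior-to-anterior, axis 3
#' inferior-to-superior.
#'
#' @param ind integer matrix of voxel indices (rows = voxels, 3 columns).
#' @param voxel_size_mm length-3 voxel size.
#' @return numeric matrix of mm coordinates.
#' @keywords internal
voxel_to_mm <- function(ind, voxel_size_mm) {
  sweep(ind - 1, 2L, voxel_size_mm, "*")
}
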