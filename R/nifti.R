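# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only what this package needs: 2-D/3-D arrays, float32 storage on write,
# common datatypes + scl slope/intercept on read, little- or big-endian.
# No NIfTI package exists in the supported R stack, hence this module.

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 2-D or 3-D array as NIfTI-1
#'
#' Data are stored as float32, little-endian, single-file NIfTI-1
#' (`vox_offset` 352, identity orientation, `pixdim` 1 mm). Paths ending in
#' `.gz` are gzip-compressed.
#'
#' @param img numeric matrix or 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes, recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = 1) {
  stopifnot(is.numeric(img), length(dim(img)) %in% c(2L, 3L))
  d <- dim(img)
  nd <- length(d)
  pixdim <- rep_len(pixdim, nd)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_i4(348)                                   # sizeof_hdr
  writeBin(raw(36), con)                      # data_type..dim_info
  w_i2(c(nd, d, rep(1L, 7 - nd)))             # dim[8]
  w_f4(c(0, 0, 0))                            # intent_p1..p3
  w_i2(c(0, 16, 32, 0))                       # intent_code, FLOAT32, bitpix
  w_f4(c(1, pixdim, rep(0, 7 - nd)))          # pixdim[8] (qfac = 1)
  w_f4(c(352, 1, 0))                          # vox_offset, scl_slope, inter
  w_i2(0)                                     # slice_end
  writeBin(as.raw(c(0, 2)), con)              # slice_code, xyzt_units (mm)
  w_f4(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i4(c(0, 0))                               # glmax, glmin
  desc <- charToRaw("quickdwi")
  writeBin(c(desc, raw(80 - length(desc))), con)
  writeBin(raw(24), con)                      # aux_file
  w_i2(c(0, 0))                               # qform_code, sform_code
  w_f4(rep(0, 6))                             # quatern/qoffset
  w_f4(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0))  # srow
  writeBin(raw(16), con)                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                       # extension flag
  w_f4(as.vector(img))
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Supports single-file NIfTI-1 (optionally gzipped), datatypes uint8,
#' int16, int32, float32, float64, either endianness, and applies the
#' scaling slope/intercept. Images of dimension > 3 are rejected.
#'
#' @param path file path.
#' @return numeric array with attributes `pixdim` and `descrip`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_con(path, "rb")
  chunks <- list()
  repeat {
    ch <- readBin(con, "raw", n = 1048576L)
    if (length(ch) == 0) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  close(con)
  buf <- do.call(c, chunks)
  if (length(buf) < 352) stop("malformed NIfTI file (too short): ", path)
  rd <- function(off, what, n, size, endian) {
    readBin(buf[(off + 1):length(buf)], what, n = n, size = size,
            endian = endian, signed = size > 1)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian) != 348) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian) != 348)
      stop("malformed NIfTI header (sizeof_hdr != 348): ", path)
  }
  dim8 <- rd(40, "integer", 8, 2, endian)
  nd <- dim8[1]
  if (nd > 3) {
    d <- dim8[2:(nd + 1)]
    if (sum(d > 1) > 3 || nd > 7)
      stop("NIfTI images of dimension > 3 are unsupported: ", path)
    nd <- max(which(d > 1))
  }
  d <- dim8[2:(nd + 1)]
  datatype <- rd(70, "integer", 1, 2, endian)
  pixdim <- rd(76, "numeric", 8, 4, endian)[2:(nd + 1)]
  vox_offset <- rd(108, "numeric", 1, 4, endian)
  scl_slope <- rd(112, "numeric", 1, 4, endian)
  scl_inter <- rd(116, "numeric", 1, 4, endian)
  descrip <- rawToChar(buf[149:228][buf[149:228] != as.raw(0)])
  n <- prod(d)
  off <- as.integer(vox_offset)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(rd(off, "integer", n, 1, endian)),
    "4"  = as.numeric(rd(off, "integer", n, 2, endian)),
    "8"  = as.numeric(rd(off, "integer", n, 4, endian)),
    "16" = rd(off, "numeric", n, 4, endian),
    "64" = rd(off, "numeric", n, 8, endian),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, dim = d)
  attr(out, "pixdim") <- pixdim
  attr(out, "descrip") <- descrip
  out
}

#' Write / read a full acquisition stack as NIfTI files
#'
#' Each (b-value, direction, acquisition) image becomes one file named
#' `b%04d_d%d_a%d.nii` inside `dir`; the protocol is stored alongside as
#' `protocol.json`. `read_dwi_stack` reassembles the 5-axis tensor.
#'
#' @param stack a `dwi_stack`.
#' @param dir output directory (created if needed).
#' @return `write_dwi_stack`: `dir` invisibly; `read_dwi_stack`: the stack.
#' @export
write_dwi_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "dwi_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- stack$protocol
  for (ib in seq_along(pr$b_values))
    for (id in seq_len(pr$n_directions))
      for (ia in seq_len(pr$n_acquisitions))
        write_nifti(stack$data[ib, id, ia, , ],
                    file.path(dir, sprintf("b%04d_d%d_a%d.nii",
                                           round(pr$b_values[ib]), id, ia)))
  jsonlite::write_json(unclass(pr), file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dwi_stack
#' @export
read_dwi_stack <- function(dir) {
  pj <- file.path(dir, "protocol.json")
  if (!file.exists(pj)) stop("missing protocol sidecar: ", pj)
  pr <- jsonlite::read_json(pj, simplifyVector = TRUE)
  pr <- acquisition_protocol(pr$b_values, pr$n_directions, pr$n_acquisitions,
                             pr$noise_sigma, pr$intensity_ceiling, pr$seed)
  first <- read_nifti(file.path(dir, sprintf("b%04d_d1_a1.nii",
                                             round(pr$b_values[1]))))
  gs <- dim(first)
  dat <- array(0, dim = c(length(pr$b_values), pr$n_directions,
                          pr$n_acquisitions, gs[1], gs[2]))
  for (ib in seq_along(pr$b_values))
    for (id in seq_len(pr$n_directions))
      for (ia in seq_len(pr$n_acquisitions))
        dat[ib, id, ia, , ] <- read_nifti(
          file.path(dir, sprintf("b%04d_d%d_a%d.nii",
                                 round(pr$b_values[ib]), id, ia)))
  structure(list(data = dat, protocol = pr), class = "dwi_stack")
}

#' Export phantom ground truth as NIfTI files
#'
#' Writes `s0.nii`, `adc.nii`, optional `adc_d{1..3}.nii`, and one
#' `roi_<label>.nii` (0/1) per lesion compartment into `dir`.
#'
#' @param gt a `dwi_ground_truth`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "dwi_ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(gt$s0_map, file.path(dir, "s0.nii"))
  write_nifti(gt$adc_map, file.path(dir, "adc.nii"))
  if (!is.null(gt$adc_dir_maps))
    for (d in 1:3)
      write_nifti(gt$adc_dir_maps[[d]], file.path(dir, sprintf("adc_d%d.nii", d)))
  for (lb in names(gt$roi_masks))
    write_nifti(gt$roi_masks[[lb]] + 0, file.path(dir, paste0("roi_", lb, ".nii")))
  invisible(dir)
}
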