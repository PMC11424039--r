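#' Read and write TCK streamline files
#'
#' Minimal reader/writer for the MRtrix TCK track format: a text header
#' terminated by `END`, then little-endian float32 point triplets with
#' `(NaN, NaN, NaN)` separating streamlines and `(Inf, Inf, Inf)`
#' terminating the file. Only `Float32LE` data are supported.
#'
#' @param tck a [tractogram()] (coordinates written as stored, in mm).
#' @param path file path.
#' @export
write_tck <- function(tck, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  body <- unlist(lapply(tck$streamlines, function(s) {
    c(as.numeric(t(s)), NaN, NaN, NaN)
  }))
  body <- c(body, Inf, Inf, Inf)
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              paste0("count: ", length(tck$streamlines)))
  # compute the data offset: header text + "file: . <offset>\nEND\n"
  base_len <- sum(nchar(header)) + length(header)  # incl newlines
  offset <- base_len
  repeat {
    line <- paste0("file: . ", offset)
    total <- base_len + nchar(line) + 1 + nchar("END") + 1
    if (total <= offset) break
    offset <- total
  }
  txt <- paste0(paste(header, collapse = "\n"), "\n",
                "file: . ", offset, "\nEND\n")
  writeChar(txt, con, eos = NULL)
  pad <- offset - nchar(txt)
  if (pad > 0) writeBin(raw(pad), con)
  writeBin(body, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop_invalid("not a TCK file")
  offset <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "END") break
    if (grepl("^datatype:", line) &&
        !grepl("Float32LE", line)) {
      stop_invalid("only Float32LE TCK data are supported")
    }
    if (grepl("^file:", line)) {
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", line))
    }
  }
  if (is.null(offset)) stop_invalid("TCK header lacks a file offset")
  seek(con, offset)
  vals <- readBin(con, "numeric", n = file.size(path), size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  ends <- which(!is.finite(pts[, 1]) & !is.finite(pts[, 2]))
  streamlines <- list()
  start <- 1
  for (e in ends) {
    if (is.nan(pts[e, 1])) {
      if (e > start) {
        streamlines[[length(streamlines) + 1L]] <-
          pts[start:(e - 1), , drop = FALSE]
      }
      start <- e + 1
    } else break  # Inf terminator
  }
  tractogram(streamlines)
}

#' Read and write label/signal volumes as NIfTI
#'
#' Thin wrappers around RNifti with the package's voxel-grid convention
#' (isotropic voxels, axis-aligned, origin at the corner of voxel 1).
#'
#' @param arr 3D or 4D numeric array.
#' @param grid a [voxel_grid()].
#' @param path `.nii` or `.nii.gz` path.
#' @export
write_nifti_volume <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size, 3),
                           rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @param voxel_size voxel size for the returned grid (taken from the
#'   header if omitted).
#' @return `read_nifti_volume()` returns a list `arr`, `grid`.
#' @export
read_nifti_volume <- function(path, voxel_size = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  vs <- voxel_size %||% RNifti::pixdim(img)[1]
  list(arr = arr, grid = voxel_grid(dim(arr)[1:3], vs))
}

#' Write streamline weights as CSV
#'
#' Columns: streamline_id, x, kept.
#'
#' @param weights a `streamline_weights` object.
#' @param path CSV path.
#' @export
write_weights <- function(weights, path) {
  write.csv(data.frame(streamline_id = seq_along(weights$x),
                       x = weights$x, kept = weights$kept_mask),
            path, row.names = FALSE)
  invisible(path)
}
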