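# TRK (TrackVis) and TCK (MRtrix) tractogram readers/writers.
#
# TRK stores points in "voxmm" coordinates with the voxel origin at the
# corner: world = vox_to_ras %*% (voxmm / voxel_size - 0.5). The package
# keeps streamlines in world mm, so conversion happens on the fly using the
# vox_to_ras header field (populated from a reference volume when writing).
# TCK stores points directly in world (scanner) mm as little-endian float32
# triplets, streamlines separated by NaN triplets and terminated by Inf.

trk_axis_code <- function(affine) {
  letters_pos <- c("R", "A", "S")
  letters_neg <- c("L", "P", "I")
  code <- character(3)
  R <- affine[1:3, 1:3]
  for (j in 1:3) {
    i <- which.max(abs(R[, j]))
    code[j] <- if (R[i, j] >= 0) letters_pos[i] else letters_neg[i]
  }
  paste(code, collapse = "")
}

#' Write a tractogram
#'
#' @param tract a `vmf_tractogram` or list of streamline matrices (world
#'   mm). All streamlines are written regardless of status.
#' @param path output file; format from extension unless given.
#' @param reference a `vmf_volume` supplying grid/affine for the TRK header
#'   (required for TRK, ignored for TCK).
#' @param format `"trk"` or `"tck"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(tract, path, reference = NULL,
                              format = c("auto", "trk", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      stop("cannot infer streamline format from extension: ", path)
    }
  }
  sl <- if (inherits(tract, "vmf_tractogram")) tract$streamlines else tract
  if (format == "trk") {
    if (is.null(reference)) stop("TRK output needs a reference volume")
    write_trk(sl, path, reference)
  } else {
    write_tck(sl, path)
  }
  invisible(path)
}

#' Read a tractogram
#'
#' @param path TRK or TCK file.
#' @param format `"trk"` or `"tck"` (default: from the extension).
#' @return a `vmf_tractogram` (all streamlines `accepted`; world mm).
#' @export
read_streamlines <- function(path, format = c("auto", "trk", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      stop("cannot infer streamline format from extension: ", path)
    }
  }
  if (!file.exists(path)) stop("file not found: ", path)
  sl <- if (format == "trk") read_trk(path) else read_tck(path)
  vmf_tractogram(sl)
}

write_trk <- function(sl, path, reference) {
  con <- file(path, "wb")
  on.exit(close(con))
  vs <- vol_voxel_size(reference)
  dims <- vol_dim(reference)
  zero_raw <- function(n) raw(n)
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(as.numeric(vs), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")   # origin (unused)
  writeBin(0L, con, size = 2, endian = "little")           # n_scalars
  writeBin(zero_raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")           # n_properties
  writeBin(zero_raw(200), con)
  # vox_to_ras, row-major float32[4][4]
  writeBin(as.numeric(t(reference$affine)), con, size = 4, endian = "little")
  writeBin(zero_raw(444), con)
  vo <- charToRaw(trk_axis_code(reference$affine))
  writeBin(c(vo, raw(4 - length(vo))), con)
  writeBin(zero_raw(4), con)                               # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")   # img orientation
  writeBin(zero_raw(2), con)                               # pad1
  writeBin(zero_raw(6), con)                               # invert/swap flags
  writeBin(length(sl), con, size = 4, endian = "little")   # n_count
  writeBin(2L, con, size = 4, endian = "little")           # version
  writeBin(1000L, con, size = 4, endian = "little")        # hdr_size
  for (S in sl) {
    S <- rbind3(S)
    vox <- world_to_vox(reference, S)
    voxmm <- sweep(vox + 0.5, 2, vs, "*")
    writeBin(nrow(S), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) {
    stop("not a TRK file (bad magic): ", path)
  }
  invisible(readBin(con, "integer", 3, size = 2, endian = "little")) # dim
  vs <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  M <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L) stop("malformed TRK header (hdr_size ", hdr_size, ")")
  if (all(M == 0)) stop("TRK v", version, " file without vox_to_ras affine")
  out <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!length(np)) break
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0) {
      invisible(readBin(con, "numeric", n_props, size = 4,
                        endian = "little"))
    }
    P <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3,
                                                          drop = FALSE]
    vox <- sweep(P, 2, vs, "/") - 0.5
    world <- sweep(vox %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
    out[[length(out) + 1L]] <- world
  }
  if (n_count > 0 && length(out) != n_count) {
    warning("TRK header announced ", n_count, " streamlines, read ",
            length(out))
  }
  out
}

write_tck <- function(sl, path) {
  body_lines <- c("mrtrix tracks",
                  "datatype: Float32LE",
                  sprintf("count: %d", length(sl)))
  # the 'file: . <offset>' line includes the offset of the binary section,
  # which depends on the header length; iterate until stable
  offset <- 0
  for (i in 1:5) {
    hdr <- paste0(paste(c(body_lines, sprintf("file: . %d", offset), "END"),
                        collapse = "\n"), "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (S in sl) {
    writeBin(as.numeric(t(rbind3(S))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header is ASCII up to the END line
  end_pat <- as.integer(charToRaw("\nEND\n"))
  hdr_end <- NA
  for (i in seq_len(min(length(raw), 4096) - 4L)) {
    if (all(as.integer(raw[i + 0:4]) == end_pat)) { hdr_end <- i + 4L; break }
  }
  if (is.na(hdr_end)) stop("malformed TCK header (no END): ", path)
  hdr <- strsplit(rawToChar(raw[1:hdr_end]), "\n")[[1]]
  if (!identical(hdr[1], "mrtrix tracks")) {
    stop("not a TCK file (bad magic): ", path)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  dt <- get_field("datatype")
  if (!identical(dt, "Float32LE")) {
    stop("unsupported TCK datatype: ", dt)
  }
  off <- as.integer(strsplit(get_field("file"), " ")[[1]][2])
  vals <- readBin(raw[(off + 1):length(raw)], "numeric",
                  (length(raw) - off) / 4, size = 4, endian = "little")
  P <- matrix(vals, ncol = 3, byrow = TRUE)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(P))) {
    if (any(is.infinite(P[i, ]))) break
    if (any(is.nan(P[i, ]))) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- do.call(rbind, cur)
      cur <- NULL
    } else {
      cur <- c(cur, list(P[i, ]))
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- do.call(rbind, cur)
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles all weights, the encoder configuration and the
#' input standardization, so a loaded model tracks identically.
#'
#' @param model a `vmf_tract_model`.
#' @param path checkpoint path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vmf_tract_model"))
  saveRDS(list(format = "vmftract-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "vmftract-checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  x$model
}
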