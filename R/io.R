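# TIFF / CSV plumbing. Stacks are written one 16-bit TIFF per
# channel-frame plus a JSON sidecar holding pixel size, channel names,
# origin and the intensity scale; label masks round-trip exactly because
# 16-bit quantization is exact at label/65535.

#' Write an ImageStack to TIFF files
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param scale intensity divisor mapping pixel values into `[0, 1]` for
#'   16-bit storage; recorded in the sidecar and undone on reading.
#' @return Invisibly, the sidecar path.
#' @export
writeImageStack <- function(stack, dir, prefix = "stack", scale = 65535) {
  stopIfNot(is(stack, "ImageStack"), "stack must be an ImageStack")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- imgData(stack)
  for (ci in seq_len(dim(d)[3L])) for (t in seq_len(dim(d)[4L])) {
    fn <- file.path(dir, sprintf("%s_c%02d_t%04d.tif", prefix, ci, t))
    tiff::writeTIFF(pmin(pmax(d[, , ci, t] / scale, 0), 1), fn,
                    bits.per.sample = 16L)
  }
  meta <- list(pixelSize = pixelSize(stack),
               channelNames = channelNames(stack),
               origin = stackOrigin(stack),
               dim = dim(d), scale = scale,
               metadata = stack@metadata[
                 vapply(stack@metadata, function(x)
                   is.atomic(x) && length(x) < 100, logical(1))])
  side <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read an ImageStack written by [writeImageStack()]
#'
#' @param dir directory holding the files.
#' @param prefix file name prefix used at write time.
#' @return The reconstructed [ImageStack-class].
#' @export
readImageStack <- function(dir, prefix = "stack") {
  side <- file.path(dir, paste0(prefix, "_meta.json"))
  stopIfNot(file.exists(side), paste("missing sidecar", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dm <- as.integer(meta$dim)
  d <- array(0, dm)
  for (ci in seq_len(dm[3L])) for (t in seq_len(dm[4L])) {
    fn <- file.path(dir, sprintf("%s_c%02d_t%04d.tif", prefix, ci, t))
    stopIfNot(file.exists(fn), paste("missing frame file", fn))
    d[, , ci, t] <- tiff::readTIFF(fn) * meta$scale
  }
  imageStack(d, pixelSize = meta$pixelSize,
             channelNames = meta$channelNames,
             origin = meta$origin,
             metadata = if (is.null(meta$metadata)) list()
                        else as.list(meta$metadata))
}

#' Write a LabelMask as a 16-bit label TIFF
#' @param mask a [LabelMask-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopIfNot(is(mask, "LabelMask"), "mask must be a LabelMask")
  stopIfNot(max(maskData(mask)) <= 65535, "too many labels for 16-bit storage")
  tiff::writeTIFF(maskData(mask) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label TIFF written by [writeMask()]
#' @param path file path.
#' @param pixelSize µm per pixel to attach.
#' @return A [LabelMask-class].
#' @export
readMask <- function(path, pixelSize = 1) {
  m <- round(tiff::readTIFF(path) * 65535)
  labelMask(m, pixelSize = pixelSize, provenance = path)
}

#' Validate a set of input files
#'
#' Checks that each path exists, that TIFF files are readable, and that CSV
#' files carry any required columns.
#'
#' @param paths character vector of file paths.
#' @param requiredColumns optional named list: `path -> character vector`
#'   of columns the CSV must contain.
#' @return A data.frame report with one row per file: `path`, `status`
#'   (`ok`/`fail`/`warn`) and `detail`; attribute `pass` is TRUE when no
#'   file failed.
#' @export
validateInputs <- function(paths, requiredColumns = list()) {
  rows <- lapply(paths, function(p) {
    if (!file.exists(p))
      return(data.frame(path = p, status = "fail", detail = "missing file"))
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("tif", "tiff")) {
      ok <- tryCatch({ tiff::readTIFF(p, info = TRUE); TRUE },
                     error = function(e) e)
      if (isTRUE(ok))
        data.frame(path = p, status = "ok", detail = "readable TIFF")
      else
        data.frame(path = p, status = "fail",
                   detail = paste("unreadable TIFF:", conditionMessage(ok)))
    } else if (ext == "csv") {
      tab <- tryCatch(read.csv(p, nrows = 5), error = function(e) e)
      if (inherits(tab, "error"))
        return(data.frame(path = p, status = "fail",
                          detail = paste("unreadable CSV:",
                                         conditionMessage(tab))))
      need <- requiredColumns[[p]]
      miss <- setdiff(need, names(tab))
      if (length(miss))
        data.frame(path = p, status = "fail",
                   detail = paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
      else data.frame(path = p, status = "ok", detail = "readable CSV")
    } else {
      data.frame(path = p, status = "warn", detail = "unrecognized format")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- !any(out$status == "fail")
  out
}
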