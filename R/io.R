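# External formats: frame stacks as zero-padded PNG sequences or multi-page
# TIFF, ground truth and manifests as JSON, records and annotations as CSV.

#' Write a frame stack to disk
#'
#' @param frames List of intensity matrices (0-255), or a
#'   `feeding_sequence`.
#' @param path Directory (PNG sequence `frame_000001.png`, ...) or a
#'   `.tif`/`.tiff` file (multi-page TIFF).
#' @return Invisibly, the files written.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "feeding_sequence")) frames <- frames$frames
  norm <- lapply(frames, function(m) pmin(pmax(m / 255, 0), 1))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- file.path(path, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(norm[[i]], files[i])
  invisible(files)
}

#' Read a frame stack from disk
#'
#' @param path Directory of PNG/TIFF frames (sorted by file name) or a
#'   multi-page TIFF file.
#' @return List of intensity matrices (0-255).
#' @export
read_frames <- function(path) {
  to255 <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]   # collapse grayscale-as-RGB
    m * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    return(lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) to255(png::readPNG(f))
      else to255(tiff::readTIFF(f))
    }))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    return(lapply(tiff::readTIFF(path, all = TRUE), to255))
  stop("path is neither a frame directory nor a TIFF stack: ", path)
}

#' Write ground truth (or any list structure) as JSON
#' @param truth List (e.g. `feeding_sequence$truth`).
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write mandibulation records as tidy CSV
#' @param records data.frame of records.
#' @param path Output file.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read catch-and-throw / boundary annotations (CSV or JSON)
#' @param path File path; format chosen by extension.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path)
}
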