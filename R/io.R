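#' Read TIMIT-style word/phone annotations
#'
#' Parses the sample-indexed annotation dialect (three whitespace-
#' separated columns per line: `start_sample end_sample token`) and
#' converts to seconds.  Rows must be sorted and non-overlapping
#' (abutting is allowed).
#'
#' @param path annotation file path.
#' @param sample_rate sample rate of the indices, default 16000 Hz.
#' @return data.frame: `word`, `onset_s`, `offset_s` (empty for an
#'   empty file).
#' @export
read_annotations <- function(path, sample_rate = 16000) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(word = character(0), onset_s = numeric(0),
                      offset_s = numeric(0)))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 3) stopf("malformed annotation at line %d: '%s'", i, lines[i])
    s <- suppressWarnings(as.numeric(f[1]))
    e <- suppressWarnings(as.numeric(f[2]))
    if (is.na(s) || is.na(e) || e <= s) {
      stopf("malformed annotation span at line %d: '%s'", i, lines[i])
    }
    data.frame(word = f[3], onset_s = s / sample_rate, offset_s = e / sample_rate)
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(out$onset_s)) stopf("annotations not sorted by onset")
  if (nrow(out) > 1) {
    ov <- which(out$onset_s[-1] < out$offset_s[-nrow(out)] - 1e-12)
    if (length(ov)) stopf("overlapping annotations at line %d", ov[1] + 1)
  }
  out
}

#' Write a dataset of named arrays plus metadata to a container file
#'
#' The container is a single hierarchical file (R serialization)
#' holding named numeric arrays and JSON-serializable metadata;
#' [container_read()] returns arrays bit-identical to what was
#' written.
#'
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param path output file path.
#' @param meta metadata list (must be JSON-serializable).
#' @return `path`, invisibly.
#' @export
container_write <- function(arrays, path, meta = list()) {
  if (length(arrays) && (is.null(names(arrays)) || any(!nzchar(names(arrays))))) {
    stopf("all arrays must be named")
  }
  for (nm in names(arrays)) {
    if (!is.numeric(arrays[[nm]]) && !is.logical(arrays[[nm]])) {
      stopf("unsupported value type for array '%s' (%s)", nm, class(arrays[[nm]])[1])
    }
  }
  ok <- tryCatch({jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA); TRUE},
                 error = function(e) FALSE)
  if (!ok) stopf("metadata is not JSON-serializable")
  obj <- structure(list(arrays = arrays, meta = meta,
                        format = "speechenc_container", version = 1L),
                   class = "speechenc_container")
  saveRDS(obj, path)
  invisible(path)
}

#' Read a container file written by [container_write()]
#'
#' @param path container file path.
#' @return List with `arrays` and `meta`.
#' @export
container_read <- function(path) {
  if (!file.exists(path)) stopf("container file not found: %s", path)
  obj <- readRDS(path)
  if (!inherits(obj, "speechenc_container")) {
    stopf("not a speechenc container: %s", path)
  }
  obj
}
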