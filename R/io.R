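#' @title Peak-list input/output
#'
#' @description Peak lists travel as CSV/TSV tables with columns
#'   `mz, intensity[, charge, snr]`, or as minimal mzXML (centroided
#'   scans, uncompressed network-order base64 peak arrays).  A matching
#'   writer exists for each reader so fixtures round-trip in code.
#' @name peak_io
NULL

.validate_peaks <- function(df, where = "peak list") {
  if (!all(c("mz", "intensity") %in% names(df)))
    stop(where, " must have columns mz, intensity")
  bad <- which(!is.finite(df$mz) | df$mz <= 0)
  if (length(bad))
    stop(where, ": non-positive or unparseable m/z at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad))
    stop(where, ": negative or unparseable intensity at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df[order(df$mz), , drop = FALSE]
}

#' Read a peak list
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mzxml"`.
#' @return data frame of peaks sorted by m/z, with at least `mz` and
#'   `intensity`; malformed rows are reported with their row numbers.
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "tsv", "mzxml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv",
                     mzxml = "mzxml",
                     stop("cannot infer peak-list format of ", path))
  if (format == "mzxml") return(.read_mzxml(path))
  df <- utils::read.table(path, header = TRUE,
                          sep = if (format == "csv") "," else "\t",
                          stringsAsFactors = FALSE)
  df <- .validate_peaks(df, path)
  rownames(df) <- NULL
  df
}

#' Write a peak list
#'
#' @param peaks peak data frame.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  utils::write.table(peaks, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_mzxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, ".//scan")
  if (length(scans) == 0) stop("no scans in mzXML file ", path)
  out <- list()
  for (sc in scans) {
    centroided <- xml2::xml_attr(sc, "centroided")
    if (!is.na(centroided) && centroided == "0")
      stop("profile-mode mzXML scan without centroiding in ", path)
    pk <- xml2::xml_find_first(sc, ".//peaks")
    comp <- xml2::xml_attr(pk, "compressionType")
    if (!is.na(comp) && !comp %in% c("none", ""))
      stop("compressed mzXML peak data not supported (", comp, ")")
    prec <- xml2::xml_attr(pk, "precision")
    size <- if (!is.na(prec) && prec == "32") 4L else 8L
    raw <- jsonlite::base64_dec(gsub("\\s", "", xml2::xml_text(pk)))
    vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                    endian = "big")
    if (length(vals) %% 2 != 0) stop("odd-length peak array in ", path)
    m <- matrix(vals, ncol = 2, byrow = TRUE)
    out[[length(out) + 1L]] <- data.frame(mz = m[, 1], intensity = m[, 2])
  }
  .validate_peaks(do.call(rbind, out), path)
}

#' Write a minimal centroided mzXML file
#'
#' One MS2 scan, uncompressed network-order m/z-int pairs; intended for
#' generating text fixtures and for round-trip testing of the reader.
#'
#' @param peaks peak data frame.
#' @param path output file.
#' @param precision 64 (doubles) or 32 (floats).
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(peaks, path, precision = 64L) {
  size <- if (precision == 32) 4L else 8L
  vals <- as.vector(rbind(peaks$mz, peaks$intensity))
  raw <- writeBin(vals, raw(), size = size, endian = "big")
  b64 <- jsonlite::base64_enc(raw)
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    ' <msRun scanCount="1">\n',
    '  <scan num="1" msLevel="2" centroided="1" peaksCount="', nrow(peaks),
    '">\n',
    '   <peaks precision="', precision,
    '" byteOrder="network" contentType="m/z-int" compressionType="none">',
    gsub("\n", "", b64), '</peaks>\n',
    '  </scan>\n </msRun>\n</mzXML>\n')
  writeLines(xml, path)
  invisible(path)
}
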