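## Reading and writing photon streams.
##
## Two on-disk forms:
##  * tabular CSV: columns timestamp_us, channel (D/A), excitation (D/A),
##    and optional truth columns true_state, donor_alive, acceptor_alive;
##  * a photon-HDF5-compatible layout: a directory holding the same fields
##    as plain-text arrays (timestamps, detectors, alternation flags) plus a
##    metadata.yaml echoing acquisition parameters, mirroring the photon-HDF5
##    field grouping in a text-only form.

#' Write a photon stream
#'
#' @param stream a \code{PhotonStream}
#' @param path output file (csv) or directory (photon-HDF5-compatible layout)
#' @param format "csv" or "phdf5"
#' @param metadata named list echoed into the layout's metadata.yaml
#'   (e.g. alternation period, seed, config echo); ignored for csv
#' @return \code{path}, invisibly
#' @export
writePhotons <- function(stream, path, format = c("csv", "phdf5"),
    metadata = list()) {
  format <- match.arg(format)
  df <- data.frame(
    timestamp_us = format(stream@timestamps, scientific = FALSE, trim = TRUE),
    channel = c("D", "A")[stream@channel],
    excitation = c("D", "A")[stream@excitation],
    stringsAsFactors = FALSE)
  if (nrow(stream@truth)) df <- cbind(df, stream@truth)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeLines(yaml::as.yaml(c(list(format = "photon-hdf5-compatible-text",
      n_photons = length(stream), timestamp_unit_us = 1), metadata)),
      file.path(path, "metadata.yaml"))
    writeLines(df$timestamp_us, file.path(path, "timestamps.txt"))
    writeLines(df$channel, file.path(path, "detectors.txt"))
    writeLines(df$excitation, file.path(path, "excitation.txt"))
    if (nrow(stream@truth))
      write.csv(stream@truth, file.path(path, "truth.csv"), row.names = FALSE,
        quote = FALSE)
  }
  invisible(path)
}

#' Read a photon stream written by \code{\link{writePhotons}}
#'
#' @param path csv file or layout directory
#' @return a \code{PhotonStream}
#' @export
readPhotons <- function(path) {
  if (dir.exists(path)) {
    ts <- as.numeric(readLines(file.path(path, "timestamps.txt")))
    ch <- readLines(file.path(path, "detectors.txt"))
    ex <- readLines(file.path(path, "excitation.txt"))
    tf <- file.path(path, "truth.csv")
    tr <- if (file.exists(tf)) read.csv(tf) else data.frame()
    return(photonStream(ts, ch, ex, tr))
  }
  if (!file.exists(path)) stop("no such photon file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_us", "channel", "excitation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed photon file '", path, "': missing column(s) ",
      paste(miss, collapse = ", "))
  ts <- suppressWarnings(as.numeric(df$timestamp_us))
  if (anyNA(ts) && nrow(df) > 0) {
    bad <- which(is.na(ts))[1]
    stop("malformed photon file '", path, "': non-numeric timestamp_us at data line ",
      bad, " (value '", df$timestamp_us[bad], "')")
  }
  badc <- which(!df$channel %in% c("D", "A"))
  if (length(badc))
    stop("malformed photon file '", path, "': bad channel at data line ",
      badc[1], " (value '", df$channel[badc[1]], "')")
  bade <- which(!df$excitation %in% c("D", "A"))
  if (length(bade))
    stop("malformed photon file '", path, "': bad excitation at data line ",
      bade[1], " (value '", df$excitation[bade[1]], "')")
  tr <- df[setdiff(names(df), need)]
  if (!ncol(tr)) tr <- data.frame()
  if ("true_state" %in% names(tr)) tr$true_state <- as.integer(tr$true_state)
  for (cc in c("donor_alive", "acceptor_alive"))
    if (cc %in% names(tr)) tr[[cc]] <- as.logical(tr[[cc]])
  photonStream(ts, df$channel, df$excitation, tr)
}
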