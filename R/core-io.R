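#' Construct a StimulusEnsemble
#'
#' @param sequences data.frame with columns \code{sequence_id},
#'   \code{base_class}, \code{variant_id}, \code{direction} (degrees on a
#'   regular grid).
#' @param nDirections number of points on the direction grid.
#' @param classNames base-class labels in canonical order; defaults to the
#'   order of first appearance in \code{sequences}.
#' @return a validated \linkS4class{StimulusEnsemble}.
#' @export
StimulusEnsemble <- function(sequences, nDirections,
                             classNames = unique(sequences$base_class)) {
  sequences <- as.data.frame(sequences, stringsAsFactors = FALSE)
  for (col in c("sequence_id", "base_class", "variant_id"))
    if (col %in% names(sequences))
      sequences[[col]] <- as.character(sequences[[col]])
  rownames(sequences) <- NULL
  new("StimulusEnsemble", sequences = sequences,
      nDirections = as.integer(nDirections),
      classNames = as.character(classNames))
}

#' Construct a ResponseTensor
#'
#' @param activity 3-axis nonnegative array, neurons x sequences x time.
#' @param binWidth time bin width in seconds.
#' @param ensemble a \linkS4class{StimulusEnsemble} aligned with axis 2.
#' @param neuronIds character ids for axis 1; defaults to \code{n1..nN}.
#' @return a validated \linkS4class{ResponseTensor}.
#' @export
ResponseTensor <- function(activity, binWidth, ensemble,
                           neuronIds = paste0("n", seq_len(dim(activity)[1]))) {
  new("ResponseTensor", activity = activity, binWidth = as.numeric(binWidth),
      ensemble = ensemble, neuronIds = as.character(neuronIds))
}

# Required columns of the sequences metadata table.
.SEQ_COLS <- c("sequence_id", "base_class", "variant_id", "direction")

#' Write a ResponseTensor as a CSV bundle
#'
#' Serializes the tensor into a directory of plain-text files: a
#' long-format activity table (\code{activity.csv}: neuron_id,
#' sequence_id, time_bin, activity), the sequence metadata
#' (\code{sequences.csv}), the neuron list (\code{neurons.csv}) and a JSON
#' header with bin width and shape. Activity values are written with 17
#' significant digits so the read/write round trip is value-exact for
#' doubles.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param path directory to create (or overwrite files in).
#' @param format currently \code{"csv-bundle"}.
#' @return \code{path}, invisibly.
#' @export
writeResponseTensor <- function(tensor, path, format = c("csv-bundle", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 output is not supported by this build; use format = 'csv-bundle'",
         call. = FALSE)
  stopifnot(is(tensor, "ResponseTensor"))
  validObject(tensor)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  a <- tensor@activity
  d <- dim(a)
  sq <- tensor@ensemble@sequences
  long <- data.frame(
    neuron_id   = rep(tensor@neuronIds, times = d[2] * d[3]),
    sequence_id = rep(rep(sq$sequence_id, each = d[1]), times = d[3]),
    time_bin    = rep(seq_len(d[3]), each = d[1] * d[2]),
    activity    = formatC(as.vector(a), digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  write.csv(long, file.path(path, "activity.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(sq, file.path(path, "sequences.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(neuron_id = tensor@neuronIds),
            file.path(path, "neurons.csv"), row.names = FALSE, quote = FALSE)
  header <- list(
    format = "neurogeom-csv-bundle-v1",
    bin_width = tensor@binWidth,
    n_neurons = d[1], n_sequences = d[2], n_time_bins = d[3],
    n_directions = tensor@ensemble@nDirections,
    class_names = as.list(tensor@ensemble@classNames)
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ResponseTensor from a CSV bundle
#'
#' Counterpart of \code{\link{writeResponseTensor}}. Fails with a schema
#' error naming the offending column or id when the metadata table does
#' not cover the activity table, and with a validation error citing the
#' (neuron, sequence, bin) index when activity values are negative or
#' non-finite.
#'
#' @param path bundle directory.
#' @param format currently \code{"csv-bundle"}.
#' @return a validated \linkS4class{ResponseTensor}.
#' @export
readResponseTensor <- function(path, format = c("csv-bundle", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 input is not supported by this build; use format = 'csv-bundle'",
         call. = FALSE)
  stopIfNot(dir.exists(path), "bundle directory '%s' does not exist", path)
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  sqPeek <- read.csv(file.path(path, "sequences.csv"), nrows = 1L)
  sqClasses <- c(sequence_id = "character", base_class = "character",
                 variant_id = "character", direction = "numeric")
  sq <- read.csv(file.path(path, "sequences.csv"),
                 colClasses = sqClasses[intersect(names(sqClasses),
                                                  names(sqPeek))])
  miss <- setdiff(.SEQ_COLS, names(sq))
  if (length(miss) > 0L)
    stop(sprintf("schema error: sequences.csv is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  nrn <- read.csv(file.path(path, "neurons.csv"),
                  colClasses = c(neuron_id = "character"))
  long <- read.csv(file.path(path, "activity.csv"),
                   colClasses = c(neuron_id = "character",
                                  sequence_id = "character",
                                  time_bin = "integer",
                                  activity = "numeric"))
  for (col in c("neuron_id", "sequence_id", "time_bin", "activity"))
    if (!col %in% names(long))
      stop(sprintf("schema error: activity.csv is missing column(s): %s", col),
           call. = FALSE)
  orphan <- setdiff(unique(long$sequence_id), sq$sequence_id)
  if (length(orphan) > 0L)
    stop(sprintf(
      "schema error: sequence id(s) %s in activity.csv absent from sequences.csv",
      paste(orphan, collapse = ", ")), call. = FALSE)
  orphanN <- setdiff(unique(long$neuron_id), nrn$neuron_id)
  if (length(orphanN) > 0L)
    stop(sprintf(
      "schema error: neuron id(s) %s in activity.csv absent from neurons.csv",
      paste(orphanN, collapse = ", ")), call. = FALSE)
  N <- nrow(nrn); S <- nrow(sq); T <- max(long$time_bin)
  a <- array(NA_real_, dim = c(N, S, T))
  ni <- match(long$neuron_id, nrn$neuron_id)
  si <- match(long$sequence_id, sq$sequence_id)
  a[cbind(ni, si, long$time_bin)] <- long$activity
  if (anyNA(a)) {
    idx <- arrayInd(which(is.na(a))[1L], dim(a))
    stop(sprintf(
      "schema error: activity.csv has no entry for (neuron %s, sequence %s, bin %d)",
      nrn$neuron_id[idx[1]], sq$sequence_id[idx[2]], idx[3]), call. = FALSE)
  }
  ens <- StimulusEnsemble(sq, nDirections = header$n_directions,
                          classNames = unlist(header$class_names))
  ResponseTensor(a, binWidth = header$bin_width, ensemble = ens,
                 neuronIds = nrn$neuron_id)
}

#' Extract a direction-by-time PSTH grid for one neuron
#'
#' Collects the neuron's time courses for one (base class, variant)
#' pattern across every drift direction and stacks them with direction
#' rows ascending, the image form used to visualize joint temporal
#' response patterns.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param neuron neuron id.
#' @param baseClass base-stimulus class label.
#' @param variant variant id within the class.
#' @return a \linkS4class{PSTHGrid}.
#' @export
psthGrid <- function(tensor, neuron, baseClass, variant) {
  stopifnot(is(tensor, "ResponseTensor"))
  ni <- match(neuron, tensor@neuronIds)
  if (is.na(ni))
    stop(sprintf("lookup error: unknown neuron '%s'", neuron), call. = FALSE)
  sq <- tensor@ensemble@sequences
  sel <- sq$base_class == baseClass & sq$variant_id == variant
  if (!any(sel))
    stop(sprintf("lookup error: no sequences for class '%s', variant '%s'",
                 baseClass, variant), call. = FALSE)
  sub <- sq[sel, , drop = FALSE]
  nd <- tensor@ensemble@nDirections
  if (nrow(sub) != nd || anyDuplicated(sub$direction))
    stop(sprintf(
      "lookup error: class '%s' variant '%s' does not cover all %d directions",
      baseClass, variant, nd), call. = FALSE)
  ord <- order(sub$direction)
  rows <- which(sel)[ord]
  m <- tensor@activity[ni, rows, , drop = FALSE]
  m <- matrix(m, nrow = nd, dimnames = NULL)
  new("PSTHGrid", matrix = m, directions = sub$direction[ord],
      neuron = as.character(neuron), baseClass = as.character(baseClass),
      variant = as.character(variant), timeAxis = timeAxis(tensor))
}
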