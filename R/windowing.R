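#' Construct a Recording from a numeric matrix
#'
#' @param channels numeric matrix or data frame, one row per sample and one
#'   column per accelerometer axis (g units).
#' @param samplingRate sampling rate in Hz.
#' @param annotations optional character vector of per-sample labels.
#' @param subjectId subject identifier.
#' @return A [Recording-class] object.
#' @examples
#' rec <- recording(matrix(rnorm(300), ncol = 3), samplingRate = 50)
#' rec
#' @export
recording <- function(channels, samplingRate, annotations = NULL,
                      subjectId = "s1") {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  new("Recording", channels = channels, samplingRate = samplingRate,
    annotations = if (is.null(annotations)) character(0)
      else as.character(annotations),
    subjectId = as.character(subjectId))
}

#' Read a multichannel accelerometer recording from CSV
#'
#' The file holds one row per sample and one numeric column per axis, in
#' acquisition order. An optional annotation file gives activity labels as
#' half-open, 0-based sample intervals (`start_sample,end_sample,label`);
#' samples not covered by any interval are labeled `"unknown"`.
#'
#' @param path path to the signal CSV.
#' @param samplingRate sampling rate in Hz.
#' @param annotationPath optional path to the interval annotation CSV.
#' @param subjectId subject identifier.
#' @param header logical; does the signal CSV carry a header row?
#' @return A [Recording-class] object with channels in file column order.
#' @seealso [writeRecording()], [segmentFrames()]
#' @export
readRecording <- function(path, samplingRate, annotationPath = NULL,
                          subjectId = "s1", header = TRUE) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.csv(path, header = header)
  if (nrow(df) == 0) stop("recording file is empty: ", path)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all signal columns must be numeric in ", path)
  x <- as.matrix(df)
  ann <- NULL
  if (!is.null(annotationPath)) {
    iv <- readAnnotations(annotationPath)
    if (max(iv$end_sample) > nrow(x))
      stop("annotation intervals extend past the recording (",
        max(iv$end_sample), " > ", nrow(x), " samples)")
    ann <- rep("unknown", nrow(x))
    for (r in seq_len(nrow(iv)))
      ann[(iv$start_sample[r] + 1):iv$end_sample[r]] <- iv$label[r]
  }
  recording(x, samplingRate, annotations = ann, subjectId = subjectId)
}

#' Read an interval annotation file
#'
#' @param path CSV with columns `start_sample`, `end_sample`, `label`;
#'   intervals are half-open and 0-based.
#' @return A data frame of validated intervals.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  iv <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("start_sample", "end_sample", "label")
  if (!all(need %in% names(iv)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  if (any(iv$end_sample <= iv$start_sample) || any(iv$start_sample < 0))
    stop("annotation intervals must be half-open, 0-based and non-empty")
  iv$label <- as.character(iv$label)
  iv
}

#' Write a recording (and optionally its annotations) to CSV
#'
#' @param rec a [Recording-class] object.
#' @param path output CSV path for the signal.
#' @param annotationPath optional output path for run-length encoded
#'   per-sample annotations as half-open 0-based intervals.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, annotationPath = NULL) {
  x <- channels(rec)
  colnames(x) <- if (is.null(colnames(x)))
    paste0("ch", seq_len(ncol(x))) else colnames(x)
  # %.17g guarantees doubles survive the text round trip bit-exactly
  txt <- apply(x, 2, function(col) sprintf("%.17g", col))
  utils::write.table(rbind(colnames(x), txt), path, sep = ",",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  ann <- annotations(rec)
  if (!is.null(annotationPath) && !is.null(ann)) {
    r <- rle(ann)
    end <- cumsum(r$lengths)
    iv <- data.frame(start_sample = c(0L, end[-length(end)]),
      end_sample = end, label = r$values)
    utils::write.csv(iv, annotationPath, row.names = FALSE)
  }
  invisible(path)
}

#' Segment a recording into overlapping data frames
#'
#' Cuts fixed-width sliding windows from the recording at hop
#' `step = round(width * (1 - overlap))`. Frames start at samples 0, step,
#' 2*step, ...; trailing samples that do not fill a frame are dropped. With
#' annotations present, each frame receives the majority label of its
#' samples; frames that overlap an annotated `"transition"` zone, or whose
#' majority vote ties, are labeled `"transition"`.
#'
#' @param rec a [Recording-class] object.
#' @param width frame width in samples.
#' @param overlap fractional overlap between consecutive frames in
#'   `[0, 1)`; 0.5 gives the conventional 50% overlapping frames.
#' @return A [FrameSet-class] object.
#' @examples
#' rec <- recording(matrix(seq_len(100), ncol = 1), samplingRate = 10)
#' segmentFrames(rec, width = 50, overlap = 0.5)   # 3 frames at 0, 25, 50
#' @export
segmentFrames <- function(rec, width, overlap = 0.5) {
  width <- as.integer(width)
  L <- nrow(channels(rec))
  if (width < 1) stop("width must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (width > L)
    stop("width (", width, ") exceeds recording length (", L, ")")
  step <- as.integer(round(width * (1 - overlap)))
  if (step < 1L) step <- 1L
  starts <- seq.int(0L, L - width, by = step)
  x <- channels(rec)
  frms <- lapply(starts, function(s) x[(s + 1):(s + width), , drop = FALSE])
  ann <- annotations(rec)
  labs <- character(0)
  if (!is.null(ann)) {
    labs <- vapply(starts, function(s) {
      a <- ann[(s + 1):(s + width)]
      if (any(a == "transition")) return("transition")
      m <- majorityLabel(a)
      if (is.na(m)) "transition" else m
    }, character(1))
  }
  new("FrameSet", frames = frms, width = width, step = step,
    samplingRate = samplingRate(rec), frameLabels = labs,
    spurious = logical(0))
}
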