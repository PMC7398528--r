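# ChIP-seq coverage summaries over promoter windows.
#
# The module consumes pre-computed per-interval coverage (bedGraph) together
# with a declared total mapped-read count; it never aligns reads or calls
# peaks. Tracks are rescaled to a read depth of 10 million so occupancy is
# comparable across libraries, and promoter occupancy is expressed relative
# to a positive-control locus (a constitutive p53 target such as CDKN1A).

#' Construct a coverage track
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and non-negative `depth`.
#' @param total_reads Total mapped reads in the library (positive integer).
#' @param normalized Whether depths are already on the 10-million-read scale.
#' @return A data frame of class `coverage_track` (sorted, non-overlapping
#'   within each chromosome) with attributes `total_reads` and `normalized`.
#' @export
coverage_track <- function(intervals, total_reads, normalized = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(intervals)))
  total_reads <- as.numeric(total_reads)
  if (is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be a positive count")
  df <- data.frame(chrom = as.character(intervals$chrom),
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end),
                   depth = as.numeric(intervals$depth),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$start >= df$end))
    stop("coverage intervals need integer 0 <= start < end")
  if (any(df$depth < 0)) stop("negative depth in coverage track")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ov <- df$chrom[-1L] == df$chrom[-nrow(df)] & df$start[-1L] < df$end[-nrow(df)]
  if (nrow(df) > 1L && any(ov))
    stop("overlapping coverage intervals within a chromosome (first at row ",
         which(ov)[1L] + 1L, ")")
  rownames(df) <- NULL
  structure(df, total_reads = total_reads, normalized = isTRUE(normalized),
            class = c("coverage_track", "data.frame"))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "Coverage track: %d intervals on %d chromosome(s); %s reads; %s\n",
    nrow(x), length(unique(x$chrom)),
    format(attr(x, "total_reads"), big.mark = ","),
    if (attr(x, "normalized")) "normalized to 10M reads" else "raw depth"))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, depth).
#' @param total_reads Declared total mapped reads of the library.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, total_reads) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines))
    return(coverage_track(data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), depth = numeric(0)),
                          total_reads))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad))
    stop(sprintf("%s line %d: expected 4 tab-separated fields", path, bad[1L]))
  m <- matrix(unlist(lapply(f, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  coverage_track(data.frame(chrom = m[, 1L],
                            start = suppressWarnings(as.integer(m[, 2L])),
                            end = suppressWarnings(as.integer(m[, 3L])),
                            depth = suppressWarnings(as.numeric(m[, 4L])),
                            stringsAsFactors = FALSE),
                 total_reads)
}

#' Normalise a coverage track to a read depth of 10 million
#'
#' Multiplies every depth by `1e7 / total_reads`. Normalisation is linear
#' and guarded: applying it twice is an error, and a library of exactly
#' 10 million reads is a fixed point.
#'
#' @param track A [coverage_track()].
#' @return The normalised track.
#' @export
normalize_to_10M <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (attr(track, "normalized"))
    stop("track is already normalized to 10M reads")
  total <- attr(track, "total_reads")
  if (total <= 0) stop("total_reads must be positive")
  track$depth <- track$depth * (1e7 / total)
  attr(track, "normalized") <- TRUE
  track
}

#' Max and mean coverage over a window
#'
#' Uncovered bases count as depth 0; the mean is length-weighted over the
#' whole window.
#'
#' @param track A normalised [coverage_track()].
#' @param window One-row interval (list or data frame with `chrom`, `start`,
#'   `end`).
#' @return Named numeric vector `c(max = ..., mean = ...)`.
#' @export
window_signal <- function(track, window) {
  stopifnot(inherits(track, "coverage_track"))
  if (!attr(track, "normalized"))
    stop("window_signal requires a track normalized to 10M reads")
  chrom <- as.character(window$chrom)
  ws <- as.integer(window$start); we <- as.integer(window$end)
  if (ws < 0L || ws >= we) stop("invalid window")
  if (!chrom %in% track$chrom) {
    warning("chromosome ", chrom, " absent from coverage track")
    return(c(max = 0, mean = 0))
  }
  sub <- track[track$chrom == chrom & track$start < we & track$end > ws, ,
               drop = FALSE]
  if (!nrow(sub)) return(c(max = 0, mean = 0))
  clip_len <- pmin(sub$end, we) - pmax(sub$start, ws)
  covered <- sum(clip_len)
  mx <- max(sub$depth)
  if (covered < we - ws) mx <- max(mx, 0)
  c(max = mx, mean = sum(sub$depth * clip_len) / (we - ws))
}

#' Promoter occupancy relative to a control locus
#'
#' Summarises the target window's coverage and expresses its maximum as a
#' ratio to the control window's maximum (the p53-activation reference,
#' e.g. CDKN1A). The target is flagged `enriched` when the ratio reaches
#' `threshold`.
#'
#' @param track A normalised [coverage_track()].
#' @param target_window,control_window One-row intervals (`chrom`, `start`,
#'   `end`).
#' @param labels Character vector of two locus labels
#'   (default `c("target", "control")`).
#' @param threshold Enrichment ratio cut-off (default 0.1).
#' @return An object of class `occupancy_report`: list with `locus`,
#'   `window`, `max_signal`, `mean_signal`, `control_locus`, `control_max`,
#'   `ratio_to_control` (`NA` when the control is uncovered), and logical
#'   `enriched`.
#' @export
occupancy_report <- function(track, target_window, control_window,
                             labels = c("target", "control"),
                             threshold = 0.1) {
  tgt <- window_signal(track, target_window)
  ctl <- window_signal(track, control_window)
  ratio <- if (ctl[["max"]] > 0) tgt[["max"]] / ctl[["max"]] else NA_real_
  structure(
    list(locus = labels[1L], window = target_window,
         max_signal = tgt[["max"]], mean_signal = tgt[["mean"]],
         control_locus = labels[2L], control_max = ctl[["max"]],
         ratio_to_control = ratio, threshold = threshold,
         control_uncovered = ctl[["max"]] == 0,
         enriched = !is.na(ratio) && ratio >= threshold),
    class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("Occupancy of %s (vs %s)\n", x$locus, x$control_locus))
  cat(sprintf("  max %.3f  mean %.3f  control max %.3f\n",
              x$max_signal, x$mean_signal, x$control_max))
  if (is.na(x$ratio_to_control))
    cat("  ratio: undefined (control uncovered)\n")
  else
    cat(sprintf("  ratio to control: %.3f  -> %s (threshold %.2f)\n",
                x$ratio_to_control,
                if (x$enriched) "enriched" else "not enriched", x$threshold))
  invisible(x)
}

#' Annotate response elements with overlapping peaks
#'
#' Half-open overlap semantics: an element `[s, e)` overlaps a peak
#' `[ps, pe)` iff `s < pe` and `ps < e` (and chromosomes agree when both
#' sides carry a `chrom` column).
#'
#' @param elements Element data frame (see [scan_response_elements()]),
#'   optionally with a `chrom` column.
#' @param peaks Interval data frame of peaks.
#' @return `elements` with added columns `n_peaks` and `peaks`
#'   (semicolon-joined peak names or indices).
#' @export
overlap_elements_with_peaks <- function(elements, peaks) {
  peak_names <- if (!is.null(peaks$name) && !all(peaks$name == "."))
    peaks$name else as.character(seq_len(nrow(peaks)))
  n_peaks <- integer(nrow(elements))
  hits <- character(nrow(elements))
  for (k in seq_len(nrow(elements))) {
    ok <- elements$start[k] < peaks$end & peaks$start < elements$end[k]
    if (!is.null(elements$chrom) && !is.null(peaks$chrom))
      ok <- ok & peaks$chrom == elements$chrom[k]
    n_peaks[k] <- sum(ok)
    hits[k] <- paste(peak_names[ok], collapse = ";")
  }
  elements$n_peaks <- n_peaks
  elements$peaks <- hits
  elements
}
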