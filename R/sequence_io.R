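# Sequence and interval I/O.
#
# Sequences travel as upper-case character strings over {A,C,G,T,N}; multi-
# record collections are named character vectors (one element per FASTA
# record). Intervals are data frames with columns chrom/start/end/strand,
# 0-based half-open internally; human-readable reports print 1-based
# inclusive coordinates.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

normalize_residues <- function(x, id = "<sequence>") {
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                 substr(x[i], bad[i], bad[i]), bad[i],
                 if (length(id) >= i) id[i] else id[1L]))
  }
  x
}

#' Read promoter sequences from a FASTA file
#'
#' Residues are upper-cased (soft-masked lower case is accepted and
#' normalised); any character outside `A,C,G,T,N` is rejected with the record
#' and position named. Record identifiers must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- names(set)
  # first whitespace-delimited token, FASTA convention
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  res <- as.character(set)
  stats::setNames(normalize_residues(res, ids), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residues.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement with `N -> N`, order reversed. The p53
#' consensus is palindromic, so minus-strand scanning reduces to scanning the
#' reverse complement.
#'
#' @param x Character vector of residue strings over `A,C,G,T,N`.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  x <- normalize_residues(x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Construct genomic intervals (0-based, half-open)
#'
#' @param chrom Chromosome / sequence name(s).
#' @param start,end Integer coordinates, 0-based half-open; `start < end`.
#' @param strand One of `+`, `-`, `.` per interval.
#' @param name Optional feature name(s).
#' @return A data frame with columns `chrom, start, end, name, score, strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".", name = ".") {
  start <- as.integer(start); end <- as.integer(end)
  n <- max(length(chrom), length(start))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = 0L,
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "interval") {
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(where, ": non-integer coordinates")
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s %d: need 0 <= start < end, got [%s, %s)",
                 where, bad[1L], df$start[bad[1L]], df$end[bad[1L]]))
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(where, ": strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Extract a sequence window
#'
#' Returns the subsequence `[start, end)` of `seq`; for a minus-strand
#' interval the reverse complement is returned. The result is named
#' `<id>:<start+1>-<end>(<strand>)` (1-based inclusive, the reporting
#' convention).
#'
#' @param seq A single residue string (optionally named with its identifier).
#' @param interval A one-row interval data frame (see [genomic_interval()]),
#'   or a list with `start`, `end` and optional `strand`.
#' @return A single named residue string.
#' @export
extract_window <- function(seq, interval) {
  stopifnot(length(seq) == 1L)
  start <- as.integer(interval$start); end <- as.integer(interval$end)
  strand <- if (is.null(interval$strand)) "+" else as.character(interval$strand)
  if (strand == ".") strand <- "+"
  L <- nchar(seq)
  if (is.na(start) || is.na(end) || start < 0L || end > L || start >= end)
    stop(sprintf("window [%s, %s) out of bounds for sequence of length %d",
                 start, end, L))
  sub <- substr(seq, start + 1L, end)
  if (strand == "-") sub <- unname(reverse_complement(sub))
  id <- if (is.null(names(seq))) "seq" else names(seq)
  stats::setNames(sub, sprintf("%s:%d-%d(%s)", id, start + 1L, end, strand))
}

#' Read intervals from a BED file
#'
#' Accepts BED3 or BED6, tab-separated, 0-based half-open. Malformed lines
#' (non-integer coordinates, `start >= end`) are reported with their line
#' number.
#'
#' @param path Path to a BED file.
#' @return A data frame `chrom, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("%s line %d: expected >= 3 tab-separated fields", path, i))
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("%s line %d: non-integer coordinates '%s', '%s'",
                   path, i, f[2L], f[3L]))
    if (start < 0L || start >= end)
      stop(sprintf("%s line %d: need 0 <= start < end, got [%d, %d)",
                   path, i, start, end))
    data.frame(chrom = f[1L], start = start, end = end,
               name = if (length(f) >= 4L) f[4L] else ".",
               score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0,
               strand = if (length(f) >= 6L) f[6L] else ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_intervals(out, where = paste0(path, " line"))
  out
}

#' Write intervals to a BED file
#'
#' Writes BED6; read/write round-trips are identity for valid intervals.
#'
#' @param intervals Interval data frame (see [genomic_interval()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start, end = intervals$end,
                   name = if (is.null(intervals$name)) "." else intervals$name,
                   score = if (is.null(intervals$score)) 0L else intervals$score,
                   strand = if (is.null(intervals$strand)) "." else intervals$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
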