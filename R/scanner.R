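# Response-element scanner.
#
# A half-site hit is a decamer window whose mismatch count against the
# degenerate consensus is within the per-half budget; a full element pairs
# two half-site hits across an admissible spacer under the total budget.
# Minus-strand hits are reported at their plus-strand window; because the
# consensus is self-reverse-complementary, a window can match identically on
# both strands (same physical mismatch columns) and is then reported once,
# strand "+". Coordinates are 0-based half-open throughout.

# logical matrix: rows A,C,G,T,N x 10 pattern columns; TRUE = mismatch.
# N always mismatches (sites are never called on ambiguous bases).
mismatch_lookup <- function(allowed_sets) {
  m <- matrix(TRUE, nrow = 5L, ncol = 10L,
              dimnames = list(DNA_ALPHABET, NULL))
  for (j in 1:10) m[allowed_sets[[j]], j] <- FALSE
  m["N", ] <- TRUE
  m
}

# per-offset mismatch counts for all decamer windows of idx (1..5 codes)
window_mismatch_counts <- function(idx, mm_lookup) {
  L <- length(idx)
  n_win <- L - 10L + 1L
  if (n_win <= 0L) return(integer(0))
  counts <- integer(n_win)
  for (j in 1:10) counts <- counts + mm_lookup[idx[j:(j + n_win - 1L)], j]
  counts
}

#' Match one decamer window against the half-site consensus
#'
#' Position `i` (1-based on the decamer) mismatches iff the observed base is
#' outside the allowed set of consensus symbol `i`; `N` mismatches
#' everywhere.
#'
#' @param window A 10-residue string.
#' @param pattern A [p53_pattern()].
#' @return A list with `observed`, `mismatch_count` and integer
#'   `mismatch_positions` (1-10).
#' @examples
#' match_half_site("GAACATGTCC", p53_pattern())$mismatch_count  # 0
#' @export
match_half_site <- function(window, pattern = p53_pattern()) {
  window <- normalize_residues(window)
  if (nchar(window) != 10L)
    stop("window must be a decamer, got ", nchar(window), " residues")
  chars <- strsplit(window, "")[[1]]
  pos <- which(vapply(1:10, function(i)
    !(chars[i] %in% pattern$allowed[[i]]) || chars[i] == "N", logical(1)))
  list(observed = window, mismatch_count = length(pos),
       mismatch_positions = as.integer(pos))
}

# mismatch positions (pattern coordinates) for a window at 0-based offset
hit_positions <- function(chars, offset, sets) {
  w <- chars[(offset + 1L):(offset + 10L)]
  as.integer(which(vapply(1:10, function(i)
    !(w[i] %in% sets[[i]]) || w[i] == "N", logical(1))))
}

#' Scan a sequence for half-site hits on both strands
#'
#' Reports every decamer window, on either strand, with at most
#' `pattern$max_mm_per_half` mismatches. Minus-strand hits are given at their
#' plus-strand window with `observed` the plus-strand decamer; a window whose
#' minus-strand match has the same physical mismatch columns as its
#' plus-strand match is reported once with strand `+`.
#'
#' @param seq A residue string (optionally named).
#' @param pattern A [p53_pattern()].
#' @return A data frame with columns `offset` (0-based), `strand`,
#'   `observed`, `mismatch_count` and list-column `mismatch_positions`
#'   (1-based on the matched decamer, pattern orientation).
#' @export
scan_half_sites <- function(seq, pattern = p53_pattern()) {
  seq <- normalize_residues(seq)
  chars <- strsplit(unname(seq), "")[[1]]
  idx <- match(chars, DNA_ALPHABET)
  plus_sets <- pattern$allowed
  minus_sets <- revcomp_pattern_sets(pattern)
  mm_plus <- window_mismatch_counts(idx, mismatch_lookup(plus_sets))
  mm_minus <- window_mismatch_counts(idx, mismatch_lookup(minus_sets))
  budget <- pattern$max_mm_per_half
  keep_plus <- which(mm_plus <= budget)
  keep_minus <- which(mm_minus <= budget)

  rows <- list()
  for (o in keep_plus) {
    rows[[length(rows) + 1L]] <- list(
      offset = o - 1L, strand = "+",
      observed = paste(chars[o:(o + 9L)], collapse = ""),
      mismatch_count = mm_plus[o],
      mismatch_positions = hit_positions(chars, o - 1L, plus_sets))
  }
  for (o in keep_minus) {
    # positions on the minus-strand decamer: pattern position p sits at
    # physical plus-strand column 11 - p of the window
    ppos <- hit_positions(chars, o - 1L, minus_sets)  # physical columns
    minus_positions <- sort(11L - ppos)
    if (o %in% keep_plus) {
      plus_phys <- hit_positions(chars, o - 1L, plus_sets)
      if (mm_minus[o] == mm_plus[o] && setequal(ppos, plus_phys)) next
    }
    rows[[length(rows) + 1L]] <- list(
      offset = o - 1L, strand = "-",
      observed = paste(chars[o:(o + 9L)], collapse = ""),
      mismatch_count = mm_minus[o],
      mismatch_positions = minus_positions)
  }
  if (!length(rows)) return(empty_half_site_df())
  df <- data.frame(
    offset = vapply(rows, `[[`, integer(1), "offset"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    observed = vapply(rows, `[[`, character(1), "observed"),
    mismatch_count = vapply(rows, `[[`, integer(1), "mismatch_count"),
    stringsAsFactors = FALSE)
  df$mismatch_positions <- lapply(rows, `[[`, "mismatch_positions")
  df[order(df$offset, df$strand), , drop = FALSE]
}

empty_half_site_df <- function() {
  df <- data.frame(offset = integer(0), strand = character(0),
                   observed = character(0), mismatch_count = integer(0),
                   stringsAsFactors = FALSE)
  df$mismatch_positions <- list()
  df
}

empty_element_df <- function() {
  data.frame(start = integer(0), end = integer(0),
             spacer_length = integer(0),
             mm_half1 = integer(0), mm_half2 = integer(0),
             total_mismatches = integer(0),
             strand_half1 = character(0), strand_half2 = character(0),
             observed = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Pair half-site hits into full response elements
#'
#' Every ordered pair of half-site hits whose spacer (gap between the end of
#' the upstream decamer and the start of the downstream one) lies within the
#' pattern's spacer range, and whose summed mismatches are within the total
#' budget, becomes an element. `half1` is always the upstream half on the
#' plus strand. Elements are sorted by total mismatches, then spacer length,
#' then start.
#'
#' @param halves Half-site data frame from [scan_half_sites()].
#' @param pattern A [p53_pattern()].
#' @param seq Optional: the scanned sequence, to fill the elements' observed
#'   sequence (both halves plus spacer).
#' @return An element data frame with columns `start, end, spacer_length,
#'   mm_half1, mm_half2, total_mismatches, strand_half1, strand_half2,
#'   observed, label`.
#' @export
pair_full_sites <- function(halves, pattern = p53_pattern(), seq = NULL) {
  if (nrow(halves) < 2L) return(empty_element_df())
  n <- nrow(halves)
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  spacer <- halves$offset[jj] - (halves$offset[ii] + 10L)
  ok <- spacer >= pattern$spacer_min & spacer <= pattern$spacer_max
  total <- halves$mismatch_count[ii] + halves$mismatch_count[jj]
  ok <- ok & total <= pattern$max_mm_total
  if (!any(ok)) return(empty_element_df())
  i <- ii[ok]; j <- jj[ok]
  df <- data.frame(
    start = halves$offset[i],
    end = halves$offset[j] + 10L,
    spacer_length = spacer[ok],
    mm_half1 = halves$mismatch_count[i],
    mm_half2 = halves$mismatch_count[j],
    total_mismatches = total[ok],
    strand_half1 = halves$strand[i],
    strand_half2 = halves$strand[j],
    stringsAsFactors = FALSE)
  df$observed <- if (!is.null(seq))
    substring(unname(seq), df$start + 1L, df$end) else NA_character_
  df$label <- NA_character_
  df <- df[order(df$total_mismatches, df$spacer_length, df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan a sequence for full p53 response elements
#'
#' Composition of [scan_half_sites()] and [pair_full_sites()]. With
#' `non_overlapping = TRUE`, a greedy pass ranked by (total mismatches,
#' spacer length, leftmost start) keeps the best element and drops any later
#' element whose interval overlaps one already kept.
#'
#' @param seq A residue string.
#' @param pattern A [p53_pattern()].
#' @param non_overlapping Keep only mutually non-overlapping elements.
#' @return An element data frame (see [pair_full_sites()]).
#' @examples
#' scan_response_elements(paste0("GAACATGTCC", "TTTTT", "AAACTTGTTT"))
#' @export
scan_response_elements <- function(seq, pattern = p53_pattern(),
                                   non_overlapping = FALSE) {
  halves <- scan_half_sites(seq, pattern)
  el <- pair_full_sites(halves, pattern, seq = seq)
  if (non_overlapping && nrow(el) > 1L) {
    keep <- logical(nrow(el))
    for (k in seq_len(nrow(el))) {
      clash <- keep & el$start < el$end[k] & el$start[k] < el$end
      keep[k] <- !any(clash)
    }
    el <- el[keep, , drop = FALSE]
    rownames(el) <- NULL
  }
  el
}

#' Export response elements as BED6
#'
#' Score is `1000 - 100 * total_mismatches`, clamped to `[0, 1000]`; names
#' are the element labels or `RE_<k>`.
#'
#' @param elements Element data frame.
#' @param path Output BED path.
#' @param chrom Chromosome/sequence name for column 1.
#' @return `path`, invisibly.
#' @export
elements_to_bed <- function(elements, path, chrom = "seq") {
  name <- elements$label
  auto <- sprintf("RE_%d", seq_len(nrow(elements)))
  name[is.na(name)] <- auto[is.na(name)]
  df <- data.frame(chrom = chrom, start = elements$start, end = elements$end,
                   name = name,
                   score = pmin(1000L, pmax(0L, 1000L - 100L * elements$total_mismatches)),
                   strand = "+", stringsAsFactors = FALSE)
  write_bed(df, path)
}

#' Export response elements as a TSV report
#'
#' One row per element with observed sequences and mismatch annotations;
#' coordinates are printed 1-based inclusive.
#'
#' @param elements Element data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
elements_to_tsv <- function(elements, path) {
  out <- elements
  out$start <- out$start + 1L  # 1-based inclusive for reporting
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
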