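# Global alignment and interval projection.
#
# Cross-species site projection aligns two whole promoter windows globally
# and maps the reference site's columns onto the query. Linear scoring
# (match +1, mismatch -1, gap -2 by default) with a deterministic traceback
# keeps projections reproducible.

#' Globally align two sequences (Needleman-Wunsch)
#'
#' Linear gap penalty; traceback ties are broken deterministically
#' (diagonal, then gap-in-query, then gap-in-reference).
#'
#' @param ref,query Residue strings (optionally named with identifiers).
#' @param match,mismatch,gap Scoring parameters (defaults +1/-1/-2).
#' @return An object of class `pairwise_alignment`: list with `ref_id`,
#'   `query_id`, equal-length gapped strings `aligned_ref`/`aligned_query`,
#'   `score` and `params`.
#' @export
global_align <- function(ref, query, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(ref) || !nzchar(query))
    stop("global_align requires two non-empty sequences")
  r <- normalize_residues(unname(ref))
  q <- normalize_residues(unname(query))
  aln <- nw_align_cpp(r, q, match, mismatch, gap)
  structure(
    list(ref_id = if (is.null(names(ref))) "ref" else names(ref),
         query_id = if (is.null(names(query))) "query" else names(query),
         aligned_ref = aln$aligned_ref, aligned_query = aln$aligned_query,
         score = aln$score,
         params = c(match = match, mismatch = mismatch, gap = gap)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("Global alignment: %s vs %s (score %g)\n",
              x$ref_id, x$query_id, x$score))
  n <- nchar(x$aligned_ref)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    a <- substr(x$aligned_ref, s, e)
    b <- substr(x$aligned_query, s, e)
    bar <- paste(ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]] &
                          strsplit(a, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(a, "\n", bar, "\n", b, "\n\n", sep = "")
  }
  invisible(x)
}

#' Project a reference interval through an alignment
#'
#' Maps a 0-based half-open interval on the reference onto the query: the
#' query positions aligned to the interval's columns. If every column is a
#' query gap the projection is empty (`deleted = TRUE`) and `start == end`
#' gives the insertion point in the query.
#'
#' @param aln A [global_align()] result.
#' @param start,end 0-based half-open interval on the (ungapped) reference.
#' @return List with `start`, `end` (0-based half-open on the query) and
#'   logical `deleted`.
#' @export
project_interval <- function(aln, start, end) {
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  qc <- strsplit(aln$aligned_query, "")[[1]]
  ref_len <- sum(rc != "-")
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > ref_len || start >= end)
    stop(sprintf("interval [%d, %d) out of reference range [0, %d)",
                 start, end, ref_len))
  ref_pos <- cumsum(rc != "-")          # per-column ref position (1-based)
  q_pos <- cumsum(qc != "-")            # per-column query position (1-based)
  cols <- which(rc != "-" & ref_pos > start & ref_pos <= end)
  qhit <- cols[qc[cols] != "-"]
  if (!length(qhit)) {
    before <- if (min(cols) > 1L) q_pos[min(cols) - 1L] else 0L
    return(list(start = as.integer(before), end = as.integer(before),
                deleted = TRUE))
  }
  list(start = as.integer(q_pos[min(qhit)] - 1L),
       end = as.integer(q_pos[max(qhit)]),
       deleted = FALSE)
}
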