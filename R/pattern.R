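# Degenerate consensus pattern for the p53 response element.
#
# A full element is two copies of the decamer half-site consensus RRRCWWGYYY
# separated by a spacer of 0-13 bp. Matching is mismatch-counting against the
# IUPAC-degenerate half-site; an N in the scanned sequence mismatches every
# consensus symbol (a site is never called on ambiguous sequence).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D"
)

#' Define a p53 response-element consensus pattern
#'
#' Holds the degenerate decamer half-site (default the canonical p53 consensus
#' `RRRCWWGYYY`), the admissible spacer range between the two half-sites, and
#' the mismatch budgets under which a site is still called.
#'
#' @param half_site Degenerate decamer (IUPAC codes); must be 10 symbols.
#' @param spacer_min,spacer_max Inclusive spacer range in bp between the two
#'   half-sites. Defaults 0 and 13.
#' @param max_mm_per_half Maximum mismatches tolerated in one half-site.
#' @param max_mm_total Maximum mismatches summed over both half-sites.
#' @return An object of class `p53_pattern`: a list with the fields above plus
#'   `allowed`, a list of allowed-base sets per half-site position.
#' @examples
#' p53_pattern()
#' p53_pattern(max_mm_per_half = 1, max_mm_total = 2)
#' @export
p53_pattern <- function(half_site = "RRRCWWGYYY",
                        spacer_min = 0L, spacer_max = 13L,
                        max_mm_per_half = 2L, max_mm_total = 3L) {
  half_site <- toupper(half_site)
  if (nchar(half_site) != 10L)
    stop("half_site must be a decamer (10 IUPAC symbols), got ",
         nchar(half_site), " symbols")
  syms <- strsplit(half_site, "")[[1]]
  bad <- setdiff(syms, names(IUPAC_SETS))
  if (length(bad))
    stop("unknown IUPAC symbol(s) in half_site: ", paste(bad, collapse = ", "))
  spacer_min <- as.integer(spacer_min)
  spacer_max <- as.integer(spacer_max)
  if (spacer_min < 0L || spacer_min > spacer_max)
    stop("need 0 <= spacer_min <= spacer_max")
  max_mm_per_half <- as.integer(max_mm_per_half)
  max_mm_total <- as.integer(max_mm_total)
  if (max_mm_per_half < 0L || max_mm_total < 0L)
    stop("mismatch budgets must be >= 0")
  structure(
    list(half_site = half_site,
         allowed = IUPAC_SETS[syms],
         spacer_min = spacer_min, spacer_max = spacer_max,
         max_mm_per_half = max_mm_per_half, max_mm_total = max_mm_total),
    class = "p53_pattern")
}

#' @export
print.p53_pattern <- function(x, ...) {
  cat("p53 response-element pattern\n")
  cat("  half-site consensus:", x$half_site, "\n")
  cat(sprintf("  spacer: %d-%d bp\n", x$spacer_min, x$spacer_max))
  cat(sprintf("  mismatch budget: %d per half-site, %d total\n",
              x$max_mm_per_half, x$max_mm_total))
  invisible(x)
}

# Reverse-complemented degenerate half-site (the allowed-set view of scanning
# the minus strand at the same plus-strand window).
revcomp_pattern_sets <- function(pattern) {
  syms <- strsplit(pattern$half_site, "")[[1]]
  rc <- rev(unname(DNA_COMPLEMENT[syms]))
  IUPAC_SETS[rc]
}
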