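# Synthetic data with exact ground truth.
#
# Generates background promoters, plants full response elements with chosen
# per-half mismatch counts and spacer lengths, derives orthologous "species"
# sequences by per-base substitution/indel divergence (with optional
# targeted site ablation), and simulates coverage tracks — each output
# accompanied by a truth table so every pipeline stage can be checked
# against known answers. All randomness flows through R's global RNG:
# set a seed (or use the `seed` field of a cohort spec) for byte-stable
# output. The generator exists to exercise the pipeline, not to model
# molecular evolution.

DNA_BASES <- c("A", "C", "G", "T")

#' Realise a half-site with an exact mismatch count
#'
#' Draws a decamer with exactly `n_mismatches` positions outside their
#' allowed consensus sets: positions chosen uniformly, the violating base
#' uniformly from the disallowed bases, matching bases uniformly from the
#' allowed set.
#'
#' @param pattern A [p53_pattern()].
#' @param n_mismatches Integer in 0..10.
#' @return A decamer string with `match_half_site()` mismatch count exactly
#'   `n_mismatches`.
#' @export
realize_half_site <- function(pattern = p53_pattern(), n_mismatches = 0L) {
  n_mismatches <- as.integer(n_mismatches)
  if (is.na(n_mismatches) || n_mismatches < 0L || n_mismatches > 10L)
    stop("n_mismatches must be in 0..10")
  mm_pos <- sample.int(10L, n_mismatches)
  chars <- character(10L)
  for (i in 1:10) {
    allowed <- pattern$allowed[[i]]
    pool <- if (i %in% mm_pos) setdiff(DNA_BASES, allowed) else allowed
    if (!length(pool))
      stop("position ", i, " admits every base; cannot place a mismatch there")
    chars[i] <- pool[sample.int(length(pool), 1L)]
  }
  paste(chars, collapse = "")
}

#' Generate i.i.d. background sequence at a target GC fraction
#'
#' @param length Sequence length in bp.
#' @param gc_fraction P(G) + P(C); bases drawn i.i.d. with
#'   `P(G) = P(C) = gc/2`, `P(A) = P(T) = (1 - gc)/2`.
#' @return A residue string.
#' @export
generate_background <- function(length, gc_fraction = 0.5) {
  length <- as.integer(length)
  stopifnot(length >= 0L, gc_fraction >= 0, gc_fraction <= 1)
  if (length == 0L) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Plant full response elements into a background sequence
#'
#' Each planted site is `realize_half_site(mm_half1)` + a uniform-random
#' spacer + `realize_half_site(mm_half2)`, written at the stated position.
#' Sites must fit within the sequence and be mutually disjoint.
#'
#' @param background A residue string.
#' @param planted List of site specs, each a list with `position` (0-based),
#'   `spacer_length` (0-13), `mm_half1`, `mm_half2`, `label`.
#' @param pattern A [p53_pattern()].
#' @return List with `sequence` (the background with sites written in) and
#'   `truth`, a data frame with one row per planted site: `label, start,
#'   end, spacer_length, mm_half1, mm_half2, total_mismatches, site_seq`.
#' @export
plant_sites <- function(background, planted, pattern = p53_pattern()) {
  L <- nchar(background)
  if (!length(planted))
    return(list(sequence = background, truth = empty_truth_df()))
  start <- vapply(planted, function(s) as.integer(s$position), integer(1))
  spacer <- vapply(planted, function(s) as.integer(s$spacer_length), integer(1))
  if (any(spacer < pattern$spacer_min | spacer > pattern$spacer_max))
    stop("planted spacer length outside the pattern's spacer range")
  end <- start + 20L + spacer
  if (any(start < 0L | end > L)) stop("planted site does not fit the sequence")
  o <- order(start)
  if (length(start) > 1L && any(start[o][-1L] < end[o][-length(end)]))
    stop("planted sites overlap")
  seq <- background
  rows <- vector("list", length(planted))
  for (k in seq_along(planted)) {
    s <- planted[[k]]
    h1 <- realize_half_site(pattern, s$mm_half1)
    sp <- if (spacer[k] > 0L)
      paste(sample(DNA_BASES, spacer[k], replace = TRUE), collapse = "") else ""
    h2 <- realize_half_site(pattern, s$mm_half2)
    site <- paste0(h1, sp, h2)
    substr(seq, start[k] + 1L, end[k]) <- site
    rows[[k]] <- data.frame(
      label = as.character(s$label), start = start[k], end = end[k],
      spacer_length = spacer[k],
      mm_half1 = as.integer(s$mm_half1), mm_half2 = as.integer(s$mm_half2),
      total_mismatches = as.integer(s$mm_half1) + as.integer(s$mm_half2),
      site_seq = site, stringsAsFactors = FALSE)
  }
  list(sequence = seq, truth = do.call(rbind, rows))
}

empty_truth_df <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             spacer_length = integer(0), mm_half1 = integer(0),
             mm_half2 = integer(0), total_mismatches = integer(0),
             site_seq = character(0), stringsAsFactors = FALSE)
}

#' Derive a diverged "species" sequence from a reference
#'
#' Applies, per base: substitution with probability `substitution_rate`
#' (uniform among the three alternatives) and indel initiation with
#' probability `indel_rate` (insertion or deletion with equal probability,
#' length 1-3 uniform; insertions are placed after the initiating base,
#' inserted/ablated bases drawn from the reference's base composition).
#' Sites named in `ablate` are first overwritten with random sequence of the
#' same length. The truth table is updated with each site's projected
#' interval in the diverged sequence and a present/absent verdict obtained
#' by rescanning the projected window with the pattern.
#'
#' @param reference Reference residue string.
#' @param substitution_rate,indel_rate Per-base event probabilities in
#'   `[0, 1]`.
#' @param ablate Character vector of truth-table labels to ablate.
#' @param truth Truth table from [plant_sites()].
#' @param pattern A [p53_pattern()].
#' @return List with `sequence` and `truth` (columns of the input truth plus
#'   `new_start`, `new_end`, `present`, `mm_observed`).
#' @export
diverge_species <- function(reference, substitution_rate = 0,
                            indel_rate = 0, ablate = character(),
                            truth = empty_truth_df(),
                            pattern = p53_pattern()) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  chars <- strsplit(reference, "")[[1]]
  L <- length(chars)
  freq <- table(factor(chars[chars %in% DNA_BASES], levels = DNA_BASES))
  comp <- if (sum(freq) > 0) as.numeric(freq) / sum(freq) else rep(0.25, 4)

  miss <- setdiff(ablate, truth$label)
  if (length(miss)) stop("ablate names unknown site(s): ",
                         paste(miss, collapse = ", "))
  for (lab in ablate) {
    k <- which(truth$label == lab)
    span <- (truth$start[k] + 1L):truth$end[k]
    chars[span] <- sample(DNA_BASES, length(span), replace = TRUE, prob = comp)
  }
  # substitutions
  sub_mask <- runif(L) < substitution_rate
  if (any(sub_mask)) {
    for (i in which(sub_mask)) {
      alt <- setdiff(DNA_BASES, chars[i])
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  # indels: deletion removes bases i..i+len-1; insertion adds after base i
  keep <- rep(TRUE, L)
  ins_after <- vector("list", L)
  init <- which(runif(L) < indel_rate)
  for (i in init) {
    len <- sample.int(3L, 1L)
    if (runif(1) < 0.5) {
      keep[i:min(L, i + len - 1L)] <- FALSE
    } else {
      ins_after[[i]] <- sample(DNA_BASES, len, replace = TRUE, prob = comp)
    }
  }
  n_ins <- vapply(ins_after, length, integer(1))
  emitted <- as.integer(keep) + n_ins
  # new 0-based coordinate of the boundary before original base i (1-based):
  boundary <- c(0L, cumsum(emitted))
  pieces <- character(L)
  pieces[keep] <- chars[keep]
  for (i in which(n_ins > 0L))
    pieces[i] <- paste0(pieces[i], paste(ins_after[[i]], collapse = ""))
  seq_out <- paste(pieces, collapse = "")

  tr <- truth
  if (nrow(tr)) {
    tr$new_start <- boundary[tr$start + 1L]
    tr$new_end <- boundary[tr$end + 1L]
    tr$present <- FALSE
    tr$mm_observed <- NA_integer_
    for (k in seq_len(nrow(tr))) {
      if (tr$new_end[k] <= tr$new_start[k]) next
      win <- substr(seq_out, tr$new_start[k] + 1L, tr$new_end[k])
      hits <- scan_response_elements(win, pattern)
      if (nrow(hits)) {
        tr$present[k] <- TRUE
        tr$mm_observed[k] <- min(hits$total_mismatches)
      }
    }
  }
  list(sequence = seq_out, truth = tr)
}

#' Simulate a coverage track with planted peaks
#'
#' Piecewise-constant per-base track: Poisson-jittered background plus a
#' triangular peak (apex `peak_height` at the window centre) for each stated
#' window; run-length encoded into a [coverage_track()].
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, `height` (apex
#'   height added over background; must be >= 0). May have zero rows.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param background_depth Mean background depth (Poisson rate).
#' @param total_reads Declared library size for the track.
#' @return List with `track` (raw, un-normalised [coverage_track()]) and
#'   `truth` (the peaks data frame).
#' @export
synth_coverage <- function(peaks, chrom_lengths, background_depth = 1,
                           total_reads = 1e7) {
  stopifnot(!is.null(names(chrom_lengths)), background_depth >= 0)
  if (nrow(peaks) && any(peaks$height < 0))
    stop("peak heights must be >= 0")
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[chrom]])
    depth <- as.numeric(rpois(L, background_depth))
    pk <- if (nrow(peaks)) peaks[peaks$chrom == chrom, , drop = FALSE]
          else peaks
    for (k in seq_len(nrow(pk))) {
      s <- pk$start[k]; e <- pk$end[k]
      if (s < 0L || e > L || s >= e) stop("peak window outside chromosome")
      x <- seq(s + 1L, e)
      centre <- (s + e + 1) / 2
      halfw <- (e - s) / 2
      tri <- pk$height[k] * pmax(0, 1 - abs(x - centre) / halfw)
      depth[x] <- depth[x] + tri
    }
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                depth = r$values, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[df$depth > 0, , drop = FALSE]  # bedGraph convention: omit zeros
  list(track = coverage_track(df, total_reads), truth = peaks)
}

#' Generate a full orthologue cohort with ground truth
#'
#' Builds a reference promoter with planted sites, then one diverged
#' sequence per species. The cohort spec fixes every random draw through its
#' `seed`.
#'
#' @param spec A list with `promoter_length`, `gc_fraction`, `planted` (list
#'   of site specs, see [plant_sites()]), `species` (list of lists with
#'   `name`, `substitution_rate`, `indel_rate`, `ablate`), and `seed`.
#' @param pattern A [p53_pattern()].
#' @return List with `reference` (named residue string), `truth` (reference
#'   truth table), `species` (named list of [diverge_species()] results) and
#'   `presence_truth` (logical species x site matrix from the per-species
#'   truth tables).
#' @export
synth_cohort <- function(spec, pattern = p53_pattern()) {
  stopifnot(!is.null(spec$seed))
  set.seed(as.integer(spec$seed))
  bg <- generate_background(spec$promoter_length,
                            if (is.null(spec$gc_fraction)) 0.5
                            else spec$gc_fraction)
  ref <- plant_sites(bg, spec$planted, pattern)
  out <- list(reference = stats::setNames(ref$sequence, "reference"),
              truth = ref$truth, species = list())
  pres <- list()
  for (sp in spec$species) {
    d <- diverge_species(ref$sequence,
                         substitution_rate = sp$substitution_rate,
                         indel_rate = sp$indel_rate,
                         ablate = if (is.null(sp$ablate)) character()
                                  else sp$ablate,
                         truth = ref$truth, pattern = pattern)
    out$species[[sp$name]] <- d
    pres[[sp$name]] <- d$truth$present
  }
  if (length(pres) && nrow(ref$truth)) {
    out$presence_truth <- do.call(rbind, pres)
    colnames(out$presence_truth) <- ref$truth$label
  }
  out
}
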