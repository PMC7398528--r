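# Cross-species site conservation and site-swap construct design.
#
# A reference site (called on the reference promoter) is projected into each
# species promoter through a global alignment; the projected window, widened
# by a small slack to absorb indels, is rescanned with the consensus
# pattern. A site is "present" in a species iff the rescan yields a full
# element within the mismatch budgets. Divergence from the reference is
# summarised separately as substitution columns and indel columns over the
# aligned site region.

#' Assess conservation of one reference site in one species promoter
#'
#' @param ref_site One element (a one-row data frame from
#'   [scan_response_elements()], or a list with `start`, `end`,
#'   `total_mismatches`, `label`).
#' @param ref_promoter Reference promoter residue string.
#' @param species_promoter Species promoter residue string.
#' @param pattern A [p53_pattern()].
#' @param slack Bases added on each side of the projected interval before
#'   rescanning (default 5), absorbing small indels.
#' @param species Species name for the record (defaults to the promoter's
#'   name attribute).
#' @return A one-row data frame: `species, site, proj_start, proj_end,
#'   deleted, projected_sequence, mm_to_consensus, mm_to_reference,
#'   indel_columns, present`. `mm_to_consensus` is the best (lowest) total
#'   mismatch count of any element found in the projected window, `NA` when
#'   none; `mm_to_reference` counts substitution columns between the aligned
#'   site region of reference and query (indel columns reported separately).
#' @export
assess_site_conservation <- function(ref_site, ref_promoter, species_promoter,
                                     pattern = p53_pattern(), slack = 5L,
                                     species = NULL) {
  if (is.null(species))
    species <- if (!is.null(names(species_promoter))) names(species_promoter)
               else "species"
  start <- as.integer(ref_site$start); end <- as.integer(ref_site$end)
  label <- if (!is.null(ref_site$label) && !is.na(ref_site$label))
    as.character(ref_site$label) else sprintf("site_%d-%d", start + 1L, end)
  aln <- global_align(ref_promoter, species_promoter)
  proj <- project_interval(aln, start, end)

  # substitution / indel columns over the aligned site region
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  qc <- strsplit(aln$aligned_query, "")[[1]]
  ref_pos <- cumsum(rc != "-")
  cols <- which(ref_pos > start & ref_pos <= end & rc != "-")
  # include query-insertion columns interior to the site region
  if (length(cols)) cols <- seq(min(cols), max(cols))
  sub_cols <- sum(rc[cols] != "-" & qc[cols] != "-" & rc[cols] != qc[cols])
  indel_cols <- sum(xor(rc[cols] == "-", qc[cols] == "-"))

  qlen <- nchar(species_promoter)
  if (proj$deleted) {
    return(data.frame(
      species = species, site = label,
      proj_start = proj$start, proj_end = proj$end, deleted = TRUE,
      projected_sequence = "", mm_to_consensus = NA_integer_,
      mm_to_reference = sub_cols, indel_columns = indel_cols,
      present = FALSE, stringsAsFactors = FALSE))
  }
  w_start <- max(0L, proj$start - as.integer(slack))
  w_end <- min(qlen, proj$end + as.integer(slack))
  window <- substr(unname(species_promoter), w_start + 1L, w_end)
  hits <- scan_response_elements(window, pattern)
  data.frame(
    species = species, site = label,
    proj_start = proj$start, proj_end = proj$end, deleted = FALSE,
    projected_sequence = substr(unname(species_promoter),
                                proj$start + 1L, proj$end),
    mm_to_consensus = if (nrow(hits)) min(hits$total_mismatches)
                      else NA_integer_,
    mm_to_reference = sub_cols, indel_columns = indel_cols,
    present = nrow(hits) > 0L, stringsAsFactors = FALSE)
}

#' Build the full species-by-site conservation table
#'
#' One record per (species, site): each reference site projected into each
#' species promoter and rescanned, mirroring a per-species row annotation of
#' the reference elements.
#'
#' @param ref_promoter Reference promoter residue string.
#' @param ref_sites Element data frame of reference sites (with labels, e.g.
#'   `BS1`/`BS2`).
#' @param species_promoters Named character vector of species promoters.
#' @param pattern A [p53_pattern()].
#' @param slack See [assess_site_conservation()].
#' @return A data frame of class `conservation_table`, one row per
#'   (species, site).
#' @export
conservation_table <- function(ref_promoter, ref_sites, species_promoters,
                               pattern = p53_pattern(), slack = 5L) {
  if (!length(species_promoters)) stop("need at least one species promoter")
  if (is.null(names(species_promoters)))
    stop("species_promoters must be named")
  if (!nrow(ref_sites)) {
    out <- assess_site_conservation(
      list(start = 0L, end = 1L), "A", "A")[0, ]
    class(out) <- c("conservation_table", "data.frame")
    return(out)
  }
  rows <- list()
  for (sp in names(species_promoters)) {
    for (k in seq_len(nrow(ref_sites))) {
      rows[[length(rows) + 1L]] <- assess_site_conservation(
        ref_sites[k, ], ref_promoter, species_promoters[[sp]],
        pattern = pattern, slack = slack, species = sp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conservation_table", "data.frame")
  out
}

#' @export
print.conservation_table <- function(x, ...) {
  cat(sprintf("Site conservation table: %d species x %d sites\n",
              length(unique(x$species)), length(unique(x$site))))
  df <- as.data.frame(x)
  df$proj_start <- df$proj_start + 1L  # print 1-based inclusive
  print(df, ...)
  invisible(x)
}

#' Write a conservation table as TSV
#'
#' Coordinates are printed 1-based inclusive.
#'
#' @param x A [conservation_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df$proj_start <- df$proj_start + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Swap a promoter segment for a donor sequence
#'
#' Replaces the wild-type interval `[start, end)` with `replacement` —
#' the in-silico analogue of moving one species' binding-site sequence into
#' another species' promoter to test sufficiency.
#'
#' @param wild_type Wild-type promoter residue string (optionally named).
#' @param target One-row interval (list or data frame with `start`, `end`,
#'   0-based half-open) on the wild type.
#' @param replacement Donor residue string.
#' @param name Construct name (e.g. `"BS1mut"`).
#' @param donor Donor label recorded with the swap.
#' @return An object of class `mutant_construct`: list with `name`,
#'   `sequence` (named residue string) and `swaps` (data frame of applied
#'   swaps in wild-type coordinates).
#' @export
swap_site <- function(wild_type, target, replacement, name = "mut",
                      donor = "donor") {
  apply_swaps(wild_type,
              list(list(start = target$start, end = target$end,
                        replacement = replacement, donor = donor)),
              name = name)
}

#' Apply several swaps to one wild-type promoter
#'
#' Targets are given in wild-type coordinates and must be disjoint; the
#' result is independent of the order in which the swaps are listed.
#'
#' @param wild_type Wild-type promoter residue string.
#' @param swaps List of swaps, each a list with `start`, `end` (0-based
#'   half-open on the wild type), `replacement`, and optional `donor`.
#' @param name Construct name.
#' @return A `mutant_construct` (see [swap_site()]).
#' @export
apply_swaps <- function(wild_type, swaps, name = "mut") {
  L <- nchar(wild_type)
  df <- data.frame(
    start = vapply(swaps, function(s) as.integer(s$start), integer(1)),
    end = vapply(swaps, function(s) as.integer(s$end), integer(1)),
    replacement = vapply(swaps, function(s)
      normalize_residues(s$replacement), character(1)),
    donor = vapply(swaps, function(s)
      if (is.null(s$donor)) "donor" else as.character(s$donor), character(1)),
    stringsAsFactors = FALSE)
  if (any(df$start < 0L | df$start >= df$end | df$end > L))
    stop("swap target out of wild-type bounds")
  o <- order(df$start)
  df <- df[o, , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    stop("swap targets overlap")
  seq <- unname(wild_type)
  for (k in rev(seq_len(nrow(df)))) {  # right to left: stable coordinates
    seq <- paste0(substr(seq, 1L, df$start[k]),
                  df$replacement[k],
                  substr(seq, df$end[k] + 1L, nchar(seq)))
  }
  rownames(df) <- NULL
  structure(list(name = name,
                 sequence = stats::setNames(seq, name),
                 wild_type_length = L, swaps = df),
            class = "mutant_construct")
}

#' @export
print.mutant_construct <- function(x, ...) {
  cat(sprintf("Mutant construct '%s': %d bp (wild type %d bp), %d swap(s)\n",
              x$name, nchar(x$sequence), x$wild_type_length, nrow(x$swaps)))
  for (k in seq_len(nrow(x$swaps)))
    cat(sprintf("  [%d-%d] <- %s (%d bp, donor %s)\n",
                x$swaps$start[k] + 1L, x$swaps$end[k],
                x$swaps$replacement[k], nchar(x$swaps$replacement[k]),
                x$swaps$donor[k]))
  invisible(x)
}

#' Suggest primer arms for a swapped region
#'
#' For each swap in a construct, returns the replacement with `flank` bases
#' of mutant-context sequence on each side, plus its reverse complement —
#' candidate overlap-extension arms. No thermodynamic optimisation is
#' attempted.
#'
#' @param construct A `mutant_construct`.
#' @param flank Flank length in bp (default 25).
#' @return Data frame with one row per swap: `donor`, `forward_arm`,
#'   `reverse_arm`.
#' @export
suggest_primer_arms <- function(construct, flank = 25L) {
  df <- construct$swaps
  seq <- unname(construct$sequence)
  # mutant coordinates: earlier swaps shift later ones
  shift <- cumsum(c(0L, nchar(df$replacement) - (df$end - df$start)))
  rows <- lapply(seq_len(nrow(df)), function(k) {
    s <- df$start[k] + shift[k]
    e <- s + nchar(df$replacement[k])
    fs <- max(0L, s - flank); fe <- min(nchar(seq), e + flank)
    fwd <- substr(seq, fs + 1L, fe)
    data.frame(donor = df$donor[k], forward_arm = fwd,
               reverse_arm = unname(reverse_complement(fwd)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
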