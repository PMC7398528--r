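# Independent brute-force oracles. Each one recomputes a quantity by literal
# enumeration, sharing no code path with the package internals it checks.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# literal mismatch count of a decamer against the consensus, one position at
# a time; N always mismatches
oracle_match <- function(window, half_site = "RRRCWWGYYY") {
  wc <- strsplit(window, "")[[1]]
  pc <- strsplit(half_site, "")[[1]]
  pos <- integer(0)
  for (i in 1:10) {
    if (wc[i] == "N" || !(wc[i] %in% ORACLE_IUPAC[[pc[i]]]))
      pos <- c(pos, i)
  }
  pos
}

# every (offset, strand) decamer window, with the documented dedup rule:
# a window whose minus-strand match has the same physical mismatch columns
# and count as its plus-strand match is reported once, strand "+"
oracle_scan_halves <- function(seq, pattern) {
  L <- nchar(seq)
  out <- list()
  if (L < 10L) return(out)
  for (o in 0:(L - 10L)) {
    win <- substr(seq, o + 1L, o + 10L)
    plus_pos <- oracle_match(win, pattern$half_site)
    minus_pos_rc <- oracle_match(oracle_revcomp(win), pattern$half_site)
    minus_phys <- sort(11L - minus_pos_rc)  # physical columns of the window
    if (length(plus_pos) <= pattern$max_mm_per_half)
      out[[length(out) + 1L]] <- list(offset = o, strand = "+",
                                      mm = length(plus_pos),
                                      pos = plus_pos)
    if (length(minus_pos_rc) <= pattern$max_mm_per_half) {
      dup <- length(plus_pos) <= pattern$max_mm_per_half &&
        length(minus_pos_rc) == length(plus_pos) &&
        setequal(minus_phys, plus_pos)
      if (!dup)
        out[[length(out) + 1L]] <- list(offset = o, strand = "-",
                                        mm = length(minus_pos_rc),
                                        pos = sort(minus_pos_rc))
    }
  }
  out
}

# literal pairing of every ordered half pair
oracle_pair <- function(halves, pattern) {
  out <- list()
  for (h1 in halves) for (h2 in halves) {
    spacer <- h2$offset - (h1$offset + 10L)
    if (spacer < pattern$spacer_min || spacer > pattern$spacer_max) next
    if (h1$mm + h2$mm > pattern$max_mm_total) next
    out[[length(out) + 1L]] <- list(start = h1$offset,
                                    end = h2$offset + 10L,
                                    spacer = spacer,
                                    total = h1$mm + h2$mm,
                                    s1 = h1$strand, s2 = h2$strand)
  }
  out
}

oracle_scan_elements <- function(seq, pattern) {
  oracle_pair(oracle_scan_halves(seq, pattern), pattern)
}

# canonical string keys so hit sets can be compared as sets
half_keys <- function(df) {
  sort(sprintf("%d|%s|%d|%s", df$offset, df$strand, df$mismatch_count,
               vapply(df$mismatch_positions, paste, "", collapse = ",")))
}
oracle_half_keys <- function(lst) {
  sort(vapply(lst, function(h)
    sprintf("%d|%s|%d|%s", h$offset, h$strand, h$mm,
            paste(h$pos, collapse = ",")), ""))
}
element_keys <- function(df) {
  sort(sprintf("%d|%d|%d|%d|%s|%s", df$start, df$end, df$spacer_length,
               df$total_mismatches, df$strand_half1, df$strand_half2))
}
oracle_element_keys <- function(lst) {
  sort(vapply(lst, function(e)
    sprintf("%d|%d|%d|%d|%s|%s", e$start, e$end, e$spacer, e$total,
            e$s1, e$s2), ""))
}

# exhaustive global-alignment score by plain recursion (tiny inputs only)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nchar(a)) return(nchar(b) * gap)
  if (!nchar(b)) return(nchar(a) * gap)
  ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  s <- if (ha == hb) match else mismatch
  max(oracle_nw_score(ta, tb, match, mismatch, gap) + s,
      oracle_nw_score(ta, b, match, mismatch, gap) + gap,
      oracle_nw_score(a, tb, match, mismatch, gap) + gap)
}

# naive UPGMA: cluster distances recomputed each round as the plain mean
# over all leaf pairs (no recurrence); same lexicographic tie rule.
# Returns the sorted vector of merge heights.
oracle_upgma_heights <- function(m) {
  D <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m)))
    D[i, j] <- mean(xor(m[i, ], m[j, ]))
  clusters <- as.list(rownames(m))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))),
                   collapse = "\r")
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && key < best_key)) {
        best <- c(i, j); best_d <- d; best_key <- key
      }
    }
    heights <- c(heights, best_d / 2)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# merge heights actually encoded in a Newick string (via ape):
# node height = max root-to-leaf distance minus node depth
newick_merge_heights <- function(nwk) {
  tr <- ape::read.tree(text = nwk)
  depths <- ape::node.depth.edgelength(tr)
  total <- max(depths[seq_along(tr$tip.label)])
  sort(total - depths[(length(tr$tip.label) + 1L):length(depths)])
}

# per-base expansion of a coverage track over a window
oracle_window_signal <- function(track, chrom, ws, we) {
  v <- numeric(we - ws)
  sub <- track[track$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(sub))) {
    s <- max(sub$start[k], ws); e <- min(sub$end[k], we)
    if (s < e) v[(s - ws + 1L):(e - ws)] <- sub$depth[k]
  }
  c(max = if (length(v)) max(v) else 0, mean = mean(v))
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
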