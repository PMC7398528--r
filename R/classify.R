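# Species classification from site presence/absence.
#
# The per-species conservation records collapse to a boolean species x site
# presence matrix; with the two proximal sites BS1/BS2 each species falls in
# one of four categories (both, BS1 only, BS2 only, none). Species are also
# clustered on simple-matching distance with UPGMA — a classification
# dendrogram over two binary characters, not an evolutionary inference.

#' Build the species-by-site presence matrix
#'
#' @param records Conservation records (data frame with `species`, `site`,
#'   `present`), covering every (species, site) pair exactly once.
#' @return A logical matrix, rows = species (input order), columns = sites
#'   (input order).
#' @export
build_presence_matrix <- function(records) {
  stopifnot(all(c("species", "site", "present") %in% names(records)))
  species <- unique(records$species)
  sites <- unique(records$site)
  key <- paste(records$species, records$site, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    p <- strsplit(dup[1L], "\r")[[1]]
    stop(sprintf("duplicate record for (%s, %s)", p[1L], p[2L]))
  }
  m <- matrix(NA, nrow = length(species), ncol = length(sites),
              dimnames = list(species, sites))
  m[cbind(match(records$species, species), match(records$site, sites))] <-
    records$present
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing record for (%s, %s)",
                 species[miss[1L]], sites[miss[2L]]))
  }
  storage.mode(m) <- "logical"
  m
}

S2_CATEGORY_COLORS <- c(both = "red", BS1_only = "yellow",
                        BS2_only = "light blue", none = "deep blue")

#' Categorise species by BS1/BS2 presence
#'
#' Maps each species row to one of four categories: `(T,T) -> both`,
#' `(T,F) -> BS1_only`, `(F,T) -> BS2_only`, `(F,F) -> none`. Defined only
#' for the site pair `{BS1, BS2}`.
#'
#' @param m Presence matrix from [build_presence_matrix()] with columns
#'   exactly `BS1` and `BS2`.
#' @return Data frame with `species`, `category` and a display `color`
#'   (red / yellow / light blue / deep blue), in matrix row order.
#' @export
categorize_species <- function(m) {
  if (!setequal(colnames(m), c("BS1", "BS2")))
    stop("categories are defined only for sites {BS1, BS2}; got: ",
         paste(colnames(m), collapse = ", "))
  bs1 <- m[, "BS1"]; bs2 <- m[, "BS2"]
  category <- ifelse(bs1 & bs2, "both",
              ifelse(bs1, "BS1_only",
              ifelse(bs2, "BS2_only", "none")))
  data.frame(species = rownames(m), category = unname(category),
             color = unname(S2_CATEGORY_COLORS[category]),
             stringsAsFactors = FALSE)
}

#' Simple-matching distance between species rows
#'
#' Fraction of sites on which two species' presence calls differ.
#'
#' @param m Logical presence matrix.
#' @return A symmetric numeric distance matrix.
#' @export
presence_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- mean(xor(m[i, ], m[j, ]))
  d
}

#' Cluster species by site presence (UPGMA)
#'
#' Average-linkage agglomeration on simple-matching distance, with
#' deterministic tie-breaking: among equally close cluster pairs the pair
#' whose (lexicographically smallest member, then second member) sorts first
#' is merged. Node heights are half the merge distance, so the dendrogram is
#' ultrametric.
#'
#' @param m Logical presence matrix with >= 2 species.
#' @return A Newick string with branch lengths (terminated by `;`).
#' @export
cluster_species <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("clustering needs at least 2 species")
  if (anyDuplicated(rownames(m)))
    stop("duplicate species names")
  D <- presence_distance(m)
  members <- as.list(rownames(m))               # cluster -> species names
  newick <- rownames(m)                         # cluster -> subtree string
  heights <- rep(0, n)                          # cluster node heights
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  Dw <- D                                       # working distances
  repeat {
    idx <- which(active)
    if (length(idx) == 1L) break
    # candidate pairs among active clusters
    best <- NULL; best_d <- Inf
    for (a in idx) for (b in idx) {
      if (a >= b) next
      d <- Dw[a, b]
      if (d < best_d - 1e-12) { best <- c(a, b); best_d <- d }
      else if (abs(d - best_d) <= 1e-12) {
        key_new <- pair_key(members[[a]], members[[b]])
        key_old <- pair_key(members[[best[1L]]], members[[best[2L]]])
        if (key_new < key_old) best <- c(a, b)
      }
    }
    a <- best[1L]; b <- best[2L]
    h <- best_d / 2
    # order children lexicographically for a stable rendering
    kids <- order(c(min(members[[a]]), min(members[[b]])))
    subtrees <- c(
      sprintf("%s:%.10g", newick[a], h - heights[a]),
      sprintf("%s:%.10g", newick[b], h - heights[b]))[kids]
    new_id <- length(members) + 1L
    members[[new_id]] <- sort(c(members[[a]], members[[b]]))
    newick[new_id] <- sprintf("(%s,%s)", subtrees[1L], subtrees[2L])
    heights[new_id] <- h
    sizes[new_id] <- sizes[a] + sizes[b]
    # UPGMA update: size-weighted average over the original leaves
    Dw <- rbind(cbind(Dw, 0), 0)
    for (k in idx) {
      if (k == a || k == b) next
      Dw[new_id, k] <- Dw[k, new_id] <-
        (sizes[a] * Dw[a, k] + sizes[b] * Dw[b, k]) / (sizes[a] + sizes[b])
    }
    active[c(a, b)] <- FALSE
    active[new_id] <- TRUE
  }
  paste0(newick[which(active)], ";")
}

pair_key <- function(ma, mb) {
  k <- sort(c(min(ma), min(mb)))
  paste(k, collapse = "\r")
}

#' Write categories and dendrogram files
#'
#' @param m Presence matrix.
#' @param categories_path Output TSV for [categorize_species()] output.
#' @param newick_path Output `.nwk` for [cluster_species()] output.
#' @return Invisibly, a list with the categories data frame and the Newick
#'   string.
#' @export
write_classification <- function(m, categories_path = NULL,
                                 newick_path = NULL) {
  cats <- categorize_species(m)
  nwk <- cluster_species(m)
  if (!is.null(categories_path))
    write.table(cats, categories_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  invisible(list(categories = cats, newick = nwk))
}
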