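test_that("realised half-sites carry exactly the requested mismatches", {
  pat <- p53_pattern()
  set.seed(1001)
  for (n in 0:10) {
    for (rep in 1:10) {
      hs <- realize_half_site(pat, n)
      expect_equal(match_half_site(hs, pat)$mismatch_count, n)
    }
  }
  expect_error(realize_half_site(pat, 11), "0..10")
  expect_error(realize_half_site(pat, -1), "0..10")
})

test_that("background sequence matches the requested composition", {
  set.seed(1002)
  expect_equal(generate_background(0, 0.5), "")
  only_gc <- generate_background(500, 1.0)
  expect_true(grepl("^[GC]+$", only_gc))
  big <- generate_background(1e5, 0.42)
  gc <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.42), 0.01)  # binomial: 4 sd ~ 0.006 at n = 1e5
})

test_that("planted sites are written at their stated coordinates", {
  set.seed(1003)
  bg <- generate_background(300, 0.5)
  out <- plant_sites(bg, list())
  expect_equal(out$sequence, bg)
  expect_equal(nrow(out$truth), 0L)

  planted <- list(
    list(label = "BS1", position = 40L, spacer_length = 0L,
         mm_half1 = 0L, mm_half2 = 2L),
    list(label = "BS2", position = 150L, spacer_length = 13L,
         mm_half1 = 1L, mm_half2 = 1L))
  out2 <- plant_sites(bg, planted)
  tr <- out2$truth
  expect_equal(tr$end - tr$start, 20L + tr$spacer_length)
  expect_equal(tr$total_mismatches, tr$mm_half1 + tr$mm_half2)
  for (k in 1:2) {
    written <- substr(out2$sequence, tr$start[k] + 1, tr$end[k])
    expect_equal(written, tr$site_seq[k])
    h1 <- match_half_site(substr(written, 1, 10))
    h2 <- match_half_site(substr(written, nchar(written) - 9,
                                 nchar(written)))
    expect_equal(h1$mismatch_count, tr$mm_half1[k])
    expect_equal(h2$mismatch_count, tr$mm_half2[k])
  }
  # outside the planted intervals the background is untouched
  expect_equal(substr(out2$sequence, 1, 40), substr(bg, 1, 40))
  expect_equal(substr(out2$sequence, 61, 150), substr(bg, 61, 150))

  expect_error(plant_sites(bg, list(
    list(label = "a", position = 10L, spacer_length = 0L,
         mm_half1 = 0L, mm_half2 = 0L),
    list(label = "b", position = 25L, spacer_length = 0L,
         mm_half1 = 0L, mm_half2 = 0L))), "overlap")
  expect_error(plant_sites(bg, list(
    list(label = "a", position = 290L, spacer_length = 0L,
         mm_half1 = 0L, mm_half2 = 0L))), "fit")
})

test_that("scanner recovers planted sites at exact coordinates", {
  set.seed(1004)
  pat <- p53_pattern()
  for (rep in 1:50) {
    n_sites <- sample(1:3, 1)
    pos <- sort(sample(seq(0, 1100, by = 40), n_sites))
    planted <- lapply(seq_len(n_sites), function(k)
      list(label = paste0("S", k), position = pos[k],
           spacer_length = sample(0:13, 1),
           mm_half1 = sample(0:2, 1), mm_half2 = sample(0:1, 1)))
    out <- plant_sites(generate_background(1200, 0.45), planted, pat)
    hits <- scan_response_elements(out$sequence, pat)
    for (k in seq_len(n_sites)) {
      hit <- hits[hits$start == out$truth$start[k] &
                    hits$end == out$truth$end[k], , drop = FALSE]
      expect_gte(nrow(hit), 1)
      expect_true(any(hit$total_mismatches <= out$truth$total_mismatches[k]))
    }
  }
})

test_that("zero-rate divergence is the identity; ablation removes sites", {
  set.seed(1005)
  out <- plant_sites(generate_background(400, 0.5), list(
    list(label = "BS1", position = 60L, spacer_length = 3L,
         mm_half1 = 0L, mm_half2 = 1L),
    list(label = "BS2", position = 200L, spacer_length = 0L,
         mm_half1 = 1L, mm_half2 = 0L)))
  same <- diverge_species(out$sequence, 0, 0, truth = out$truth)
  expect_equal(same$sequence, out$sequence)
  expect_true(all(same$truth$present))
  expect_equal(same$truth$new_start, out$truth$start)
  expect_equal(same$truth$new_end, out$truth$end)
  expect_equal(same$truth$mm_observed, out$truth$total_mismatches)

  gone <- diverge_species(out$sequence, 0, 0, ablate = c("BS1", "BS2"),
                          truth = out$truth)
  expect_false(any(gone$truth$present))
  expect_error(diverge_species(out$sequence, 0, 0, ablate = "BS9",
                               truth = out$truth), "unknown site")
})

test_that("site survival under substitution matches the enumerated bound", {
  # perfect site, per-position mismatch-creation probability under uniform
  # substitution: 2r/3 at the 8 two-base degenerate positions per half,
  # r at the 2 fixed C/G positions; survival = both halves <= 2 mm and
  # total <= 3 (the plus-strand route; window rescans can only add calls)
  r <- 0.02
  half_pmf <- function() {
    p <- c(rep(2 * r / 3, 8), rep(r, 2))
    pmf <- 1
    for (pi in p) pmf <- convolve(c(pmf, 0), rev(c(1 - pi, pi)),
                                  type = "open")
    pmf
  }
  pmf <- half_pmf()
  p_exact <- 0
  for (m1 in 0:2) for (m2 in 0:2)
    if (m1 + m2 <= 3) p_exact <- p_exact + pmf[m1 + 1] * pmf[m2 + 1]
  expect_gt(p_exact, 0.99)  # sanity on the enumeration itself

  set.seed(1006)
  n_rep <- 200
  survived <- 0L
  for (i in 1:n_rep) {
    out <- plant_sites(generate_background(100, 0.5), list(
      list(label = "S", position = 30L, spacer_length = sample(0:13, 1),
           mm_half1 = 0L, mm_half2 = 0L)))
    d <- diverge_species(out$sequence, r, 0, truth = out$truth)
    survived <- survived + d$truth$present
  }
  obs <- survived / n_rep
  sd4 <- 4 * sqrt(p_exact * (1 - p_exact) / n_rep)
  expect_gte(obs, p_exact - sd4)
  expect_lte(obs, 1)
})

test_that("indels shift the projected truth coordinates consistently", {
  set.seed(1007)
  for (i in 1:10) {
    out <- plant_sites(generate_background(500, 0.5), list(
      list(label = "S", position = 240L, spacer_length = 2L,
           mm_half1 = 0L, mm_half2 = 0L)))
    d <- diverge_species(out$sequence, 0, 0.01, truth = out$truth)
    tr <- d$truth
    # the projected window holds whatever survives of the planted site
    expect_gte(tr$new_end, tr$new_start)
    if (tr$present) {
      win <- substr(d$sequence, tr$new_start + 1, tr$new_end)
      expect_gte(nrow(scan_response_elements(win)), 1)
    }
  }
})

test_that("cohort generation is byte-stable for a fixed seed", {
  spec <- list(
    promoter_length = 600, gc_fraction = 0.5, seed = 4242,
    planted = list(list(label = "BS1", position = 100L, spacer_length = 1L,
                        mm_half1 = 0L, mm_half2 = 0L),
                   list(label = "BS2", position = 320L, spacer_length = 5L,
                        mm_half1 = 1L, mm_half2 = 1L)),
    species = list(
      list(name = "rat", substitution_rate = 0.02, indel_rate = 0.002,
           ablate = character()),
      list(name = "human", substitution_rate = 0.05, indel_rate = 0.002,
           ablate = c("BS1", "BS2"))))
  a <- synth_cohort(spec)
  b <- synth_cohort(spec)
  expect_identical(a, b)
  expect_equal(rownames(a$presence_truth), c("rat", "human"))
  expect_equal(colnames(a$presence_truth), c("BS1", "BS2"))
  expect_false(any(a$presence_truth["human", ]))
})

test_that("simulated coverage carries peaks where the truth says", {
  set.seed(1008)
  flat <- synth_coverage(data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), height = numeric(0)),
                         chrom_lengths = c(chr1 = 400L),
                         background_depth = 3, total_reads = 1e7)
  tr <- normalize_to_10M(flat$track)
  sig <- window_signal(tr, list(chrom = "chr1", start = 0L, end = 400L))
  expect_lt(sig[["max"]], 15)  # Poisson(3) jitter only

  peaked <- synth_coverage(data.frame(chrom = "chr1", start = 100L,
                                      end = 200L, height = 40),
                           chrom_lengths = c(chr1 = 400L),
                           background_depth = 3, total_reads = 1e7)
  tr2 <- normalize_to_10M(peaked$track)
  inside <- window_signal(tr2, list(chrom = "chr1", start = 100L, end = 200L))
  outside <- window_signal(tr2, list(chrom = "chr1", start = 250L, end = 350L))
  expect_gt(inside[["max"]], outside[["max"]] + 20)
})
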