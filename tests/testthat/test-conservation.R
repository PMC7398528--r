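make_ref_with_sites <- function(seed = 1, length = 600, labels = c("BS1", "BS2"),
                                positions = c(120L, 320L), spacers = c(1L, 4L),
                                mm = c(0L, 1L)) {
  set.seed(seed)
  bg <- generate_background(length, 0.45)
  planted <- Map(function(lab, pos, sp, m)
    list(label = lab, position = pos, spacer_length = sp,
         mm_half1 = m, mm_half2 = 0L),
    labels, positions, spacers, mm)
  plant_sites(bg, unname(planted))
}

test_that("a promoter is fully conserved against itself", {
  ref <- make_ref_with_sites()
  site <- as.list(ref$truth[1, ])
  rec <- assess_site_conservation(site, ref$sequence, ref$sequence,
                                  species = "self")
  expect_true(rec$present)
  expect_equal(rec$mm_to_reference, 0L)
  expect_equal(rec$indel_columns, 0L)
  expect_equal(rec$proj_start, site$start)
  expect_equal(rec$proj_end, site$end)
  expect_equal(rec$mm_to_consensus, ref$truth$total_mismatches[1])
})

test_that("complement-substituted site region is called absent", {
  ref <- make_ref_with_sites(seed = 3)
  site <- as.list(ref$truth[1, ])
  s <- ref$sequence
  region <- substr(s, site$start + 1, site$end)
  # complement without reversal violates every informative consensus position
  comp <- chartr("ACGT", "TGCA", region)
  mutated <- paste0(substr(s, 1, site$start), comp,
                    substr(s, site$end + 1, nchar(s)))
  rec <- assess_site_conservation(site, s, mutated, species = "mut")
  expect_false(rec$present)
  # the aligner absorbs part of the complemented region as indels, so the
  # substitution-column count is a lower bound on the per-base differences
  expect_gt(rec$mm_to_reference + rec$indel_columns, 10)
  expect_gt(rec$mm_to_reference, 4)
})

test_that("conservation verdicts match the generator truth table", {
  cohort <- synth_cohort(list(
    promoter_length = 800, gc_fraction = 0.45, seed = 97,
    planted = list(
      list(label = "BS1", position = 150L, spacer_length = 2L,
           mm_half1 = 0L, mm_half2 = 1L),
      list(label = "BS2", position = 430L, spacer_length = 6L,
           mm_half1 = 1L, mm_half2 = 0L)),
    species = list(
      list(name = "ratlike", substitution_rate = 0.02, indel_rate = 0,
           ablate = character()),
      list(name = "doglike", substitution_rate = 0.02, indel_rate = 0,
           ablate = c("BS1", "BS2")),
      list(name = "humanlike", substitution_rate = 0.05, indel_rate = 0,
           ablate = c("BS1", "BS2")),
      list(name = "lemurlike", substitution_rate = 0.02, indel_rate = 0,
           ablate = "BS2"))))
  promoters <- stats::setNames(
    vapply(cohort$species, `[[`, "", "sequence"), names(cohort$species))
  sites <- cohort$truth
  sites$label <- cohort$truth$label
  tab <- conservation_table(cohort$reference, sites, promoters)
  for (k in seq_len(nrow(tab))) {
    truth_row <- cohort$species[[tab$species[k]]]$truth
    expect_equal(tab$present[k],
                 truth_row$present[truth_row$label == tab$site[k]],
                 info = sprintf("%s/%s", tab$species[k], tab$site[k]))
  }
  m <- build_presence_matrix(tab)
  expect_equal(m[rownames(cohort$presence_truth), colnames(cohort$presence_truth)],
               cohort$presence_truth)
})

test_that("site swaps replace exactly the target and are reversible", {
  set.seed(9)
  wt <- c(human = random_dna(300))
  target <- list(start = 100L, end = 120L)
  region <- substr(wt, 101, 120)

  same <- swap_site(wt, target, region, name = "identity")
  expect_equal(unname(same$sequence), unname(wt))

  donor <- strrep("GAACATGTCC", 2)  # perfect site, spacer 0
  mut <- swap_site(wt, target, donor, name = "BS1mut", donor = "mouse_BS1")
  expect_equal(unname(nchar(mut$sequence)), unname(nchar(wt)))
  # outside the swap the construct is untouched
  expect_equal(unname(substr(mut$sequence, 1, 100)),
               unname(substr(wt, 1, 100)))
  expect_equal(unname(substr(mut$sequence, 121, 300)),
               unname(substr(wt, 121, 300)))
  # swapping the original region back restores the wild type
  back <- swap_site(mut$sequence, target, region, name = "revert")
  expect_equal(unname(back$sequence), unname(wt))
})

test_that("a swapped-in perfect site becomes detectable at the target", {
  set.seed(13)
  pat <- p53_pattern()
  repeat {  # draw a wild type with no element near the target window
    wt <- random_dna(260)
    if (nrow(scan_response_elements(substr(wt, 81, 180), pat)) == 0) break
  }
  target <- list(start = 120L, end = 140L)
  expect_equal(nrow(scan_response_elements(substr(wt, 101, 160), pat)), 0L)
  mut <- swap_site(wt, target, strrep("GAACATGTCC", 2), name = "BS1mut")
  hits <- scan_response_elements(mut$sequence, pat)
  over <- hits[hits$start < 140 & hits$end > 120, , drop = FALSE]
  expect_gte(nrow(over), 1)
  expect_equal(min(over$total_mismatches), 0L)
})

test_that("disjoint swaps commute and overlapping swaps are rejected", {
  set.seed(17)
  wt <- random_dna(400)
  s1 <- list(start = 50L, end = 70L, replacement = strrep("GAACATGTCC", 2),
             donor = "BS1")
  s2 <- list(start = 200L, end = 220L, replacement = strrep("AGGCAAGTCT", 2),
             donor = "BS2")
  ab <- apply_swaps(wt, list(s1, s2), name = "BS1/2mut")
  ba <- apply_swaps(wt, list(s2, s1), name = "BS1/2mut")
  expect_equal(unname(ab$sequence), unname(ba$sequence))
  # length bookkeeping with an indel-introducing replacement
  s3 <- list(start = 300L, end = 310L, replacement = "ACGT", donor = "short")
  tri <- apply_swaps(wt, list(s1, s3), name = "mix")
  expect_equal(unname(nchar(tri$sequence)), 400L + (20L - 20L) + (4L - 10L))
  expect_error(apply_swaps(wt, list(s1, list(start = 60L, end = 80L,
                                             replacement = "AAAA"))),
               "overlap")
  expect_error(apply_swaps(wt, list(list(start = 390L, end = 420L,
                                         replacement = "AA"))),
               "bounds")
})

test_that("primer arms flank the swapped-in donor", {
  set.seed(19)
  wt <- random_dna(200)
  donor <- strrep("GAACATGTCC", 2)
  mut <- swap_site(wt, list(start = 90L, end = 110L), donor, name = "BS1mut")
  arms <- suggest_primer_arms(mut, flank = 25)
  expect_equal(nrow(arms), 1L)
  expect_true(grepl(donor, arms$forward_arm, fixed = TRUE))
  expect_equal(nchar(arms$forward_arm), 20L + 50L)
  expect_equal(arms$reverse_arm,
               unname(reverse_complement(arms$forward_arm)))
})

test_that("conservation table covers the species x site grid", {
  ref <- make_ref_with_sites(seed = 23)
  tab <- conservation_table(ref$sequence, ref$truth,
                            c(self = ref$sequence))
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$present))
  expect_true(all(tab$mm_to_reference == 0))

  empty <- conservation_table(ref$sequence, ref$truth[0, ],
                              c(self = ref$sequence))
  expect_equal(nrow(empty), 0L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_conservation_tsv(tab, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 2L)
  expect_equal(back$proj_start, tab$proj_start + 1L)  # 1-based in reports
})
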