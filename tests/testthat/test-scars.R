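# HRD-LOH, telomeric allelic imbalance and large-scale transition scores.

arms <- hg19_arms()

test_that("HRD-LOH counts long partial-chromosome LOH regions only", {
  genome <- neutral_genome()
  # 20 Mb LOH on a partially-LOH chromosome
  q1 <- arms[arms$arm_id == "1q", ]
  partial <- patch_genome(genome, "chr1", q1$start + 30e6,
                          q1$start + 50e6 - 1, 1, 0)
  expect_equal(score_hrd_loh(partial)$hrd_loh, 1L)
  # whole-chromosome LOH is excluded
  whole <- patch_genome(genome, "chr2", 1, max(arms$end[arms$chrom == "chr2"]),
                        1, 0)
  expect_equal(score_hrd_loh(whole)$hrd_loh, 0L)
  # 10 Mb is below the 15 Mb floor
  short <- patch_genome(genome, "chr3", q1$start, q1$start + 10e6 - 1, 1, 0)
  expect_equal(score_hrd_loh(short)$hrd_loh, 0L)
  # exactly at the floor: strictly-greater convention
  at_floor <- patch_genome(genome, "chr4", 52660118, 52660118 + 15e6 - 1,
                           1, 0)
  expect_equal(score_hrd_loh(at_floor)$hrd_loh, 0L)
})

test_that("whole-genome LOH scores zero HRD-LOH", {
  loh_genome <- neutral_genome() |>
    dplyr::mutate(n_total = 2L, n_minor = 0L)
  expect_equal(score_hrd_loh(loh_genome)$hrd_loh, 0L)
})

test_that("TAI needs telomere contact within one arm", {
  genome <- neutral_genome()
  p2 <- arms[arms$arm_id == "2p", ]
  # 12 Mb AI abutting the p telomere
  telo <- patch_genome(genome, "chr2", p2$start, p2$start + 12e6 - 1, 3, 1)
  expect_equal(score_tai(telo)$tai, 1L)
  # AI spanning the centromere touches no telomere after clipping
  cen <- arms[arms$chrom == "chr6" & arms$arm == "p", ]
  spanning <- patch_genome(genome, "chr6", cen$cen_start - 5e6,
                           cen$cen_end + 5e6, 3, 1)
  expect_equal(score_tai(spanning)$tai, 0L)
  # interstitial AI
  inter <- patch_genome(genome, "chr7", 2e6, 20e6, 3, 1)
  expect_equal(score_tai(inter)$tai, 0L)
  # whole-arm UPD is telomeric allelic imbalance too
  q9 <- arms[arms$arm_id == "9q", ]
  upd_arm <- patch_genome(genome, "chr9", q9$start, q9$end, 2, 0)
  expect_equal(score_tai(upd_arm)$tai, 1L)
})

test_that("LST counts 10 Mb / 3 Mb breakpoints within arms", {
  q3 <- arms[arms$arm_id == "3q", ]
  s <- q3$start
  two_blocks <- function(gap_bp, len2 = 12e6) {
    tibble::tibble(
      sample = "S1", chrom = "chr3",
      start = as.integer(c(s, s + 12e6 + gap_bp)),
      end = as.integer(c(s + 12e6 - 1, s + 12e6 + gap_bp + len2 - 1)),
      n_total = c(3L, 1L), n_minor = c(1L, 0L)
    )
  }
  expect_equal(score_lst(two_blocks(1e6))$lst, 1L)
  expect_equal(score_lst(two_blocks(5e6))$lst, 0L)
  expect_equal(score_lst(two_blocks(1e6, len2 = 8e6))$lst, 0L)
  # adjacent same-state halves merge: no break inside one region
  solid <- tibble::tibble(sample = "S1", chrom = "chr3",
                          start = as.integer(s),
                          end = as.integer(s + 30e6 - 1),
                          n_total = 3L, n_minor = 1L)
  expect_equal(score_lst(split_segments(solid))$lst,
               score_lst(solid)$lst)
  # the flanking-pair break against a long neutral tail also counts
  tail_neutral <- dplyr::bind_rows(
    two_blocks(1e6),
    tibble::tibble(sample = "S1", chrom = "chr3",
                   start = as.integer(s + 25e6), end = as.integer(q3$end),
                   n_total = 2L, n_minor = 1L)
  )
  expect_equal(score_lst(tail_neutral)$lst, 2L)
})

test_that("scar scores match brute-force interval-scan oracles", {
  for (seed in 1:10) {
    segs <- random_profile(seed, chroms = c("chr1", "chr8", "chr13",
                                            "chr17", "chr21"))
    expect_equal(score_hrd_loh(segs)$hrd_loh,
                 oracle_hrd_loh_one(segs, arms), info = paste("seed", seed))
    expect_equal(score_tai(segs)$tai,
                 oracle_tai_one(segs, arms), info = paste("seed", seed))
    expect_equal(score_lst(segs)$lst,
                 oracle_lst_one(segs, arms), info = paste("seed", seed))
  }
})

test_that("scores are invariant under same-state splitting", {
  for (seed in 11:14) {
    segs <- random_profile(seed)
    expect_equal(hrd_score(split_segments(segs)), hrd_score(segs),
                 info = paste("seed", seed))
  }
})

test_that("the HRD score is the sum of its components", {
  genome <- neutral_genome()
  q1 <- arms[arms$arm_id == "1q", ]
  p2 <- arms[arms$arm_id == "2p", ]
  q3 <- arms[arms$arm_id == "3q", ]
  combined <- genome |>
    patch_genome("chr1", q1$start + 30e6, q1$start + 50e6 - 1, 1, 0) |>
    patch_genome("chr2", p2$start, p2$start + 12e6 - 1, 3, 1) |>
    patch_genome("chr3", q3$start, q3$start + 12e6 - 1, 3, 1) |>
    patch_genome("chr3", q3$start + 13e6, q3$start + 25e6 - 1, 1, 0)
  sc <- hrd_score(combined)
  expect_equal(sc$hrd_loh, score_hrd_loh(combined)$hrd_loh)
  expect_equal(sc$tai, score_tai(combined)$tai)
  expect_equal(sc$lst, score_lst(combined)$lst)
  expect_equal(sc$hrd_total, sc$hrd_loh + sc$tai + sc$lst)
  # an all-neutral diploid genome has no scars at all
  expect_equal(unlist(hrd_score(genome)[, c("hrd_loh", "tai", "lst",
                                            "hrd_total")]) |> unname(),
               c(0L, 0L, 0L, 0L))
})
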