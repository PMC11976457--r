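# The synthetic-cohort generator: determinism, planted parameters,
# structural invariants and fixture round-trips.

test_that("generation is deterministic for a fixed seed", {
  spec <- cohort_spec(seed = 7L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$spectra, c2$spectra)
  # a different seed changes the draw
  c3 <- generate_cohort(cohort_spec(seed = 8L))
  expect_false(identical(c1$variants, c3$variants))
})

test_that("invalid specs are rejected with a message", {
  expect_error(cohort_spec(n_denovo = 0L), "positive")
  expect_error(cohort_spec(upd_arm_rate = c(primary_luad = -0.1,
                                            transformed = 0.2,
                                            denovo = 0.1)),
               "probability")
  expect_error(cohort_spec(signature_mix = list(
    primary_luad = c(SBS1 = 0.7, SBS5 = 0.7),
    transformed = c(SBS1 = 1),
    denovo = c(SBS1 = 1)
  )), "summing to 1")
  expect_error(generate_cohort(cohort_spec(signature_mix = list(
    primary_luad = c(NOPE = 1), transformed = c(SBS1 = 1),
    denovo = c(SBS1 = 1)
  ))), "NOPE")
})

test_that("cohort sizes and driver plants match the study design", {
  cohort <- generate_cohort(cohort_spec(seed = 3L))
  sizes <- dplyr::count(cohort$clinical, cohort)
  expect_equal(sizes$n[match(c("primary_luad", "transformed", "denovo"),
                             sizes$cohort)],
               c(5L, 10L, 18L))
  # EGFR is mutated in every LUAD and transformed sample (rate 1.0)
  egfr <- cohort$variants |>
    dplyr::filter(gene == "EGFR", true_somatic) |>
    dplyr::distinct(sample)
  luad_trans <- cohort$clinical$sample[cohort$clinical$cohort !=
                                         "denovo"]
  expect_true(all(luad_trans %in% egfr$sample))
})

test_that("planted UPD arm rates are recovered within binomial error", {
  spec <- cohort_spec(
    n_transformed = 10L,
    upd_arm_rate = c(primary_luad = 0.03, transformed = 0.3,
                     denovo = 0.05),
    seed = 13L
  )
  cohort <- generate_cohort(spec)
  trans <- cohort$clinical$sample[cohort$clinical$cohort == "transformed"]
  ev <- arm_events(cohort$segments |>
                     dplyr::filter(sample %in% trans))
  n_arms <- 10 * 39
  p_hat <- mean(ev$state == "upd")
  se <- sqrt(0.3 * 0.7 / n_arms)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("segments tile the analysable arms without overlap", {
  cohort <- generate_cohort(cohort_spec(n_primary_luad = 2L,
                                        n_transformed = 2L,
                                        n_denovo = 2L, seed = 5L))
  arms <- hg19_arms()
  arm_bp <- sum(as.numeric(arms$end) - as.numeric(arms$start) + 1)
  per_sample <- cohort$segments |>
    dplyr::group_by(sample) |>
    dplyr::arrange(chrom, start, .by_group = TRUE)
  # no overlap within a chromosome
  overlaps <- per_sample |>
    dplyr::group_by(sample, chrom) |>
    dplyr::mutate(prev_end = dplyr::lag(end)) |>
    dplyr::filter(!is.na(prev_end), start <= prev_end)
  expect_equal(nrow(overlaps), 0L)
  # complete coverage: summed bp equals the arm-table bp per sample
  bp <- cohort$segments |>
    dplyr::group_by(sample) |>
    dplyr::summarise(bp = sum(as.numeric(end) - as.numeric(start) + 1))
  expect_true(all(bp$bp == arm_bp))
})

test_that("spectrum counts are non-negative integers on the 96 contexts", {
  cohort <- generate_cohort(cohort_spec(n_primary_luad = 2L,
                                        n_transformed = 2L,
                                        n_denovo = 2L, seed = 9L))
  expect_true(all(cohort$spectra$count >= 0))
  expect_true(all(cohort$spectra$context %in% sbs_contexts()))
  expect_equal(nrow(cohort$spectra), 6L * 96L)
})

test_that("fixtures round-trip losslessly through the package readers", {
  cohort <- generate_cohort(cohort_spec(n_primary_luad = 2L,
                                        n_transformed = 2L,
                                        n_denovo = 2L, seed = 17L))
  dir <- withr::local_tempdir()
  write_fixture(cohort, dir)
  back <- read_fixture(dir)
  expect_equal(back$clinical, cohort$clinical)
  expect_equal(back$segments[names(cohort$segments)], cohort$segments)
  expect_equal(
    back$spectra |> dplyr::arrange(sample, context),
    cohort$spectra |> dplyr::arrange(sample, context)
  )
  ord <- function(v) {
    v |>
      dplyr::select(dplyr::all_of(intersect(names(v), names(back$variants)))) |>
      dplyr::arrange(sample, caller, chrom, pos, alt, tumor_vaf)
  }
  expect_equal(ord(back$variants), ord(cohort$variants), tolerance = 1e-9)
})

test_that("a full-size fixture re-reads with the study cohort sizes", {
  cohort <- generate_cohort(cohort_spec(seed = 23L))
  dir <- withr::local_tempdir()
  write_fixture(cohort, dir, format = "tsv")
  back <- read_fixture(dir)
  sizes <- dplyr::count(back$clinical, cohort)
  expect_equal(sort(sizes$n), c(5L, 10L, 18L))
  expect_equal(dplyr::n_distinct(back$variants$sample), 33L)
})

test_that("writing an empty cohort errors", {
  cohort <- generate_cohort(cohort_spec(n_primary_luad = 1L,
                                        n_transformed = 1L,
                                        n_denovo = 1L, seed = 2L))
  cohort$clinical <- cohort$clinical[0, ]
  expect_error(write_fixture(cohort, withr::local_tempdir()), "non-empty")
})
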