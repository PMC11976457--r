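# Dual-caller consensus filtering, the tumor-only path and variant I/O.

make_variant <- function(..., sample = "S1", caller = "A") {
  defaults <- list(
    sample = sample, caller = caller, chrom = "chr1", pos = 1000L,
    ref = "C", alt = "T", class = "SNV", somatic_p = 0.01,
    tumor_vaf = 0.2, normal_vaf = 0, normal_alt_reads = 0L,
    af_1kg = 0, af_exac = 0, af_esp = 0, af_gnomad = 0,
    gene = "G1", effect = "missense", sift = "tolerated",
    polyphen = "benign", truncating = FALSE, context = "ACA"
  )
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("the consensus rules admit and reject the canonical cases", {
  # in both callers, all gates satisfied
  a <- make_variant(somatic_p = 0.05, tumor_vaf = 0.06)
  b <- make_variant(somatic_p = 0.05, tumor_vaf = 0.06, caller = "B")
  out <- consensus_filter_matched(a, b)
  expect_equal(nrow(out), 1L)
  expect_equal(out$provenance, "both_callers")

  # solely in caller B with VAF at 4%: fails the >5% solo rule
  out2 <- consensus_filter_matched(a[0, ],
                                   make_variant(tumor_vaf = 0.04,
                                                caller = "B"))
  expect_equal(nrow(out2), 0L)
  # ... but 6% passes
  out3 <- consensus_filter_matched(a[0, ],
                                   make_variant(tumor_vaf = 0.06,
                                                caller = "B"))
  expect_equal(out3$provenance, "solo_caller_b")

  # INDEL somatic p bound is 0.05: p = 0.08 in both callers is rejected
  ai <- make_variant(class = "INDEL", ref = "CA", alt = "C",
                     somatic_p = 0.08)
  bi <- dplyr::mutate(ai, caller = "B")
  expect_equal(nrow(consensus_filter_matched(ai, bi)), 0L)

  # solely in caller A is never rescued
  expect_equal(nrow(consensus_filter_matched(a, b[0, ])), 0L)
})

test_that("germline, repeat-region and population gates are enforced", {
  a <- make_variant()
  b <- dplyr::mutate(a, caller = "B")
  # normal VAF gate at 1% is strict
  expect_equal(nrow(consensus_filter_matched(
    dplyr::mutate(a, normal_vaf = 0.01),
    dplyr::mutate(b, normal_vaf = 0.01))), 0L)
  # normal alt reads: < 5 for SNV, < 2 for INDEL
  expect_equal(nrow(consensus_filter_matched(
    dplyr::mutate(a, normal_alt_reads = 5L),
    dplyr::mutate(b, normal_alt_reads = 5L))), 0L)
  expect_equal(nrow(consensus_filter_matched(
    dplyr::mutate(a, normal_alt_reads = 4L),
    dplyr::mutate(b, normal_alt_reads = 4L))), 1L)
  # repeat-region exclusion on the variant position
  rep_bed <- tibble::tibble(chrom = "chr1", start = 900L, end = 1100L)
  expect_equal(nrow(consensus_filter_matched(a, b, repeats = rep_bed)), 0L)
  # population frequency: minimum across databases must be < 1%
  common_a <- make_variant(af_1kg = 0.05, af_exac = 0.04, af_esp = 0.02)
  common_b <- dplyr::mutate(common_a, caller = "B")
  expect_equal(nrow(consensus_filter_matched(common_a, common_b)), 0L)
  # one rare database is enough under the minimum rule
  rare_a <- make_variant(af_1kg = 0.05, af_exac = 0.0001, af_esp = 0.02)
  rare_b <- dplyr::mutate(rare_a, caller = "B")
  expect_equal(nrow(consensus_filter_matched(rare_a, rare_b)), 1L)
})

test_that("mismatched samples are rejected", {
  a <- make_variant(sample = "S1")
  b <- make_variant(sample = "S2", caller = "B")
  expect_error(consensus_filter_matched(a, b), "identical sample")
})

test_that("filter output is order-independent and monotone in popfreq_cut", {
  pair <- random_caller_pair(300, seed = 42)
  out <- consensus_filter_matched(pair$a, pair$b)
  shuffled <- consensus_filter_matched(pair$a[sample(nrow(pair$a)), ],
                                       pair$b[sample(nrow(pair$b)), ])
  expect_equal(out, shuffled)
  cuts <- c(0.05, 0.02, 0.01, 0.005, 0.001)
  sets <- lapply(cuts, function(cut) {
    res <- consensus_filter_matched(pair$a, pair$b, popfreq_cut = cut)
    paste(res$chrom, res$pos, res$ref, res$alt)
  })
  for (i in 2:length(sets)) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]),
                info = paste("cut", cuts[i]))
  }
})

test_that("filter matches the naive per-variant rule evaluator", {
  for (seed in c(7, 8)) {
    pair <- random_caller_pair(200, seed = seed)
    reps <- random_repeats(seed + 100)
    got <- consensus_filter_matched(pair$a, pair$b, repeats = reps)
    got_keys <- sort(paste(got$chrom, got$pos, got$ref, got$alt, got$class))
    want <- oracle_filter_matched(pair$a, pair$b, repeats = reps)
    expect_equal(got_keys, want, info = paste("seed", seed))
  }
})

test_that("the panel of normals is an exact key union", {
  n1 <- dplyr::bind_rows(make_variant(pos = 1L), make_variant(pos = 2L))
  n2 <- dplyr::bind_rows(make_variant(pos = 2L), make_variant(pos = 3L))
  pon <- build_pon(list(n1, n2))
  expect_equal(nrow(pon), 3L)
  expect_error(build_pon(list()), "at least one")
})

test_that("the tumor-only path is PON-subtracted, frequency-capped and
           pathogenicity-gated", {
  pon <- build_pon(make_variant(pos = 500L))
  truncating <- make_variant(pos = 1L, truncating = TRUE,
                             effect = "frameshift")
  benign <- make_variant(pos = 2L)
  damaging <- make_variant(pos = 3L, sift = "damaged")
  common <- make_variant(pos = 4L, sift = "damaged", af_gnomad = 0.002)
  in_pon <- make_variant(pos = 500L, sift = "damaged")
  unannotated <- make_variant(pos = 5L, sift = NA, polyphen = NA,
                              truncating = NA)
  v <- dplyr::bind_rows(truncating, benign, damaging, common, in_pon,
                        unannotated)
  expect_warning(out <- consensus_filter_tumor_only(v, pon), "unannotated")
  expect_equal(sort(out$pos), c(1L, 3L))
  expect_setequal(out$provenance,
                  c("tumor_only_truncating", "tumor_only_damaging"))
})

test_that("multi-allelic VCF rows split into per-ALT records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=TVAF,Number=A,Type=Float,Description="t">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t123\t.\tC\tT,G\t.\tPASS\tTVAF=0.1,0.3"
  ), path)
  v <- read_caller_variants(path, "A")
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("T", "G"))
  expect_equal(v$tumor_vaf, c(0.1, 0.3))
  expect_equal(v$pos, c(123L, 123L))
})

test_that("header-only VCFs read as empty tables", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), path)
  expect_equal(nrow(read_caller_variants(path, "A")), 0L)
})

test_that("variant tables round-trip through the VCF writer and reader", {
  pair <- random_caller_pair(50, seed = 3)
  v <- dplyr::slice_head(pair$a, n = 50) |>
    dplyr::distinct(chrom, pos, ref, alt, .keep_all = TRUE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_caller_vcf(v, path)
  back <- read_caller_variants(path, "A", sample_id = "S1")
  expect_equal(nrow(back), nrow(v))
  ord <- function(x) dplyr::arrange(x, chrom, pos, alt)
  v2 <- ord(v)[names(back)]
  expect_equal(ord(back), v2, tolerance = 1e-9)
})
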