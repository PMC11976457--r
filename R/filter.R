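# Consensus somatic-variant filtering. Two paths:
#   matched     — dual-caller consensus with quality, germline-leakage,
#                 repeat-region and population-frequency gates
#   tumor-only  — panel-of-normals subtraction plus a stricter population
#                 cut and a pathogenicity requirement
# Threshold inclusivity follows the stated rules exactly: "<=" gates are
# inclusive, ">" and "<" gates strict.

variant_key <- c("chrom", "pos", "ref", "alt")

min_pop_af <- function(tbl) {
  af <- cbind(tbl$af_1kg, tbl$af_exac, tbl$af_esp)
  af[is.na(af)] <- 0
  apply(af, 1, min)
}

in_intervals <- function(tbl, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, nrow(tbl)))
  }
  hits <- tbl |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::inner_join(
      intervals |> dplyr::select("chrom", i_start = "start", i_end = "end"),
      by = dplyr::join_by("chrom", "pos" >= "i_start", "pos" <= "i_end")
    )
  seq_len(nrow(tbl)) %in% hits$.row
}

check_same_sample <- function(a, b) {
  sa <- unique(a$sample)
  sb <- unique(b$sample)
  if (length(sa) > 1 || length(sb) > 1 ||
      (length(sa) == 1 && length(sb) == 1 && sa != sb)) {
    abort("caller variant lists must come from a single, identical sample")
  }
}

mutation_output <- function(tbl) {
  keep <- intersect(
    c("sample", "chrom", "pos", "ref", "alt", "class", "gene", "tumor_vaf",
      "effect", "truncating", "context", "provenance"),
    names(tbl)
  )
  tbl |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
}

#' Consensus filter for matched tumor-normal variant calls
#'
#' Implements the dual-caller consensus cascade for matched samples. A
#' variant is admitted when either
#' \itemize{
#'   \item it is called by both callers with somatic p-value <= 0.1 for SNVs
#'     (<= 0.05 for INDELs) and tumor VAF > 2\%, or
#'   \item it is called solely by the solo-rescue caller (the VarScan2 role,
#'     caller B by default) with tumor VAF > 5\%;
#' }
#' and additionally passes the germline-leakage gates (normal VAF < 1\%,
#' normal alt-supporting reads < 5 for SNVs / < 2 for INDELs), does not fall
#' in a simple-repeat/segmental-duplication region, and has minimum
#' population allele frequency across the annotation databases below
#' `popfreq_cut`. For variants seen by both callers the evidence fields are
#' taken from caller B when present (its native somatic p-value), falling
#' back to caller A. Missing normal evidence passes the germline gates
#' (no evidence of germline origin).
#'
#' @param a,b Variant tibbles from caller A and caller B for the same sample
#'   (see [read_caller_variants()]).
#' @param repeats Optional tibble of excluded regions (`chrom`, `start`,
#'   `end`, 1-based inclusive; see [read_bed()]). Overlap is tested on the
#'   variant start position.
#' @param popfreq_cut Population-frequency cut, strict upper bound
#'   (default 0.01).
#' @param solo_vaf Minimum tumor VAF (strict) for solo caller-B rescues
#'   (default 0.05).
#' @return A tibble of consensus somatic mutations with a `provenance`
#'   column recording which rule admitted each variant
#'   (`"both_callers"` or `"solo_caller_b"`).
#' @export
consensus_filter_matched <- function(a, b, repeats = NULL,
                                     popfreq_cut = 0.01, solo_vaf = 0.05) {
  check_same_sample(a, b)
  filter_matched_impl(a, b, repeats, popfreq_cut, solo_vaf)
}

#' Consensus-filter a whole cohort of matched samples
#'
#' Applies [consensus_filter_matched()] to every sample of a combined
#' variant table in one pass (the join is keyed by sample, so samples never
#' mix). Equivalent to filtering each sample separately, but much faster on
#' large cohorts.
#'
#' @param variants Multi-sample variant tibble with a `caller` column
#'   (`"A"`/`"B"`).
#' @inheritParams consensus_filter_matched
#' @return A tibble of consensus somatic mutations across all samples.
#' @export
consensus_filter_cohort <- function(variants, repeats = NULL,
                                    popfreq_cut = 0.01, solo_vaf = 0.05) {
  filter_matched_impl(
    dplyr::filter(variants, .data$caller == "A"),
    dplyr::filter(variants, .data$caller == "B"),
    repeats, popfreq_cut, solo_vaf
  )
}

filter_matched_impl <- function(a, b, repeats = NULL,
                                popfreq_cut = 0.01, solo_vaf = 0.05) {
  merged <- dplyr::full_join(
    a, b, by = c("sample", variant_key, "class"),
    suffix = c("_a", "_b")
  )
  # evidence fields: caller B's native value wins, caller A is the fallback
  merged <- merged |>
    dplyr::mutate(
      in_a = !is.na(.data$tumor_vaf_a) | !is.na(.data$somatic_p_a) |
        !is.na(.data$gene_a),
      in_b = !is.na(.data$tumor_vaf_b) | !is.na(.data$somatic_p_b) |
        !is.na(.data$gene_b),
      somatic_p = dplyr::coalesce(.data$somatic_p_b, .data$somatic_p_a),
      tumor_vaf = dplyr::coalesce(.data$tumor_vaf_b, .data$tumor_vaf_a),
      normal_vaf = dplyr::coalesce(.data$normal_vaf_b, .data$normal_vaf_a),
      normal_alt_reads = dplyr::coalesce(.data$normal_alt_reads_b,
                                         .data$normal_alt_reads_a),
      af_1kg = dplyr::coalesce(.data$af_1kg_b, .data$af_1kg_a),
      af_exac = dplyr::coalesce(.data$af_exac_b, .data$af_exac_a),
      af_esp = dplyr::coalesce(.data$af_esp_b, .data$af_esp_a),
      gene = dplyr::coalesce(.data$gene_b, .data$gene_a),
      effect = dplyr::coalesce(.data$effect_b, .data$effect_a),
      truncating = dplyr::coalesce(.data$truncating_b, .data$truncating_a),
      context = dplyr::coalesce(.data$context_b, .data$context_a)
    )
  p_cut <- dplyr::if_else(merged$class == "INDEL", 0.05, 0.1)
  nar_cut <- dplyr::if_else(merged$class == "INDEL", 2L, 5L)
  consensus_ok <- merged$in_a & merged$in_b &
    !is.na(merged$somatic_p) & merged$somatic_p <= p_cut &
    !is.na(merged$tumor_vaf) & merged$tumor_vaf > 0.02
  solo_b_ok <- !merged$in_a & merged$in_b &
    !is.na(merged$tumor_vaf) & merged$tumor_vaf > solo_vaf
  normal_ok <- (is.na(merged$normal_vaf) | merged$normal_vaf < 0.01) &
    (is.na(merged$normal_alt_reads) | merged$normal_alt_reads < nar_cut)
  pop_ok <- min_pop_af(merged) < popfreq_cut
  repeat_hit <- in_intervals(merged, repeats)
  merged |>
    dplyr::mutate(
      pass = (consensus_ok | solo_b_ok) & normal_ok & pop_ok & !repeat_hit,
      provenance = dplyr::if_else(consensus_ok, "both_callers",
                                  "solo_caller_b")
    ) |>
    dplyr::filter(.data$pass) |>
    mutation_output()
}

#' Build a panel of normals (PON)
#'
#' Unions the variant keys (`chrom`, `pos`, `ref`, `alt`) seen in a set of
#' normal samples into a blacklist used to remove artifacts and germline
#' leakage from tumor-only calls.
#'
#' @param normals Either a single variant tibble covering all normals or a
#'   list of per-normal variant tibbles.
#' @return A tibble of unique variant keys.
#' @export
build_pon <- function(normals) {
  if (is.data.frame(normals)) normals <- list(normals)
  if (length(normals) == 0) abort("build_pon() needs at least one normal")
  dplyr::bind_rows(lapply(normals, function(x) {
    dplyr::select(x, dplyr::all_of(variant_key))
  })) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Tumor-only variant filter
#'
#' The stricter path used when no matched normal is available: a variant is
#' kept only if it is absent from the panel of normals, its population
#' allele frequency in both the 1000 Genomes and gnomAD databases is at most
#' `popfreq_cut`, and it is pathogenic-coding — judged damaging by either
#' predictor (SIFT or PolyPhen) or truncating. Candidates with no
#' annotation at all are rejected (the path fails closed) with a warning.
#'
#' @param v Variant tibble for one tumor-only sample.
#' @param pon Panel of normals from [build_pon()].
#' @param popfreq_cut Inclusive upper bound on the 1000 Genomes / gnomAD
#'   allele frequency (default 0.001).
#' @return A tibble of somatic mutations with `provenance` set to
#'   `"tumor_only_damaging"` or `"tumor_only_truncating"`.
#' @export
consensus_filter_tumor_only <- function(v, pon, popfreq_cut = 0.001) {
  pon_hit <- dplyr::mutate(v, .row = dplyr::row_number()) |>
    dplyr::semi_join(pon, by = variant_key) |>
    dplyr::pull(".row")
  af1 <- dplyr::coalesce(v$af_1kg, 0)
  afg <- dplyr::coalesce(v$af_gnomad, 0)
  pop_ok <- af1 <= popfreq_cut & afg <= popfreq_cut
  unannotated <- is.na(v$sift) & is.na(v$polyphen) & is.na(v$truncating)
  if (any(unannotated)) {
    warn(paste0(sum(unannotated),
                " unannotated candidate(s) rejected in tumor-only filtering"))
  }
  damaging <- (!is.na(v$sift) & v$sift == "damaged") |
    (!is.na(v$polyphen) & v$polyphen == "damaged")
  truncating <- !is.na(v$truncating) & v$truncating
  v |>
    dplyr::mutate(
      pass = !(dplyr::row_number() %in% pon_hit) & pop_ok &
        !unannotated & (damaging | truncating),
      provenance = dplyr::if_else(truncating, "tumor_only_truncating",
                                  "tumor_only_damaging")
    ) |>
    dplyr::filter(.data$pass) |>
    mutation_output()
}
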