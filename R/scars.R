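# Genomic scar scores: HRD-LOH, telomeric allelic imbalance (TAI) and
# large-scale state transitions (LST), computed from allele-specific
# copy-number segments. Conventions follow the published scar definitions:
#   HRD-LOH : LOH regions > 15 Mb that do not span a whole chromosome
#   TAI     : allelic-imbalance regions reaching a telomere without crossing
#             the centromere
#   LST     : breakpoints between adjacent >= 10 Mb regions separated by
#             <= 3 Mb, after dropping segments < 3 Mb
# The merge/scan machinery is vectorised over the whole multi-sample table
# (ordered rows plus lag comparisons) rather than per-group loops.

# Assign region ids to clipped pieces ordered by (sample, unit, ov_start).
# A new region starts at every sample/unit change and wherever the gap to
# the previous piece exceeds `max_gap` — unless `bridge_centromere` and the
# gap lies inside the centromere — or (with `same_key`) the allele-specific
# copy number changes.
merge_pieces <- function(pieces, unit, same_key = FALSE, max_gap = 1,
                         bridge_centromere = FALSE, tol = 1) {
  p <- pieces |>
    dplyr::mutate(.unit = .data[[unit]]) |>
    dplyr::arrange(.data$sample, .data$.unit, .data$ov_start)
  same_run <- p$sample == dplyr::lag(p$sample, default = "") &
    p$.unit == dplyr::lag(p$.unit, default = "")
  gap <- p$ov_start - dplyr::lag(p$ov_end, default = 0L) - 1
  gap_in_cen <- if (bridge_centromere) {
    dplyr::lag(p$ov_end, default = 0L) >= p$cen_start - 1 - tol &
      p$ov_start <= p$cen_end + 1 + tol
  } else {
    rep(FALSE, nrow(p))
  }
  key_change <- if (same_key) {
    p$n_total != dplyr::lag(p$n_total, default = -1L) |
      p$n_minor != dplyr::lag(p$n_minor, default = -1L)
  } else {
    rep(FALSE, nrow(p))
  }
  new_region <- !same_run | (gap > max_gap & !gap_in_cen) | key_change
  p$region <- cumsum(new_region)
  p
}

arm_clip <- function(segs, arms) {
  segs <- ensure_sample_col(classify_segments(segs))
  overlap_with_arms(segs, arms) |>
    dplyr::left_join(
      arms |> dplyr::distinct(.data$chrom, .data$cen_start, .data$cen_end),
      by = "chrom"
    )
}

complete_counts <- function(counts, samples, col) {
  tibble::tibble(sample = samples) |>
    dplyr::left_join(counts, by = "sample") |>
    dplyr::mutate("{col}" := as.integer(dplyr::coalesce(.data[[col]], 0L)))
}

hrd_loh_from_pieces <- function(clipped, arms, min_bp, tol) {
  pieces <- dplyr::filter(clipped, .data$is_loh)
  chrom_bp <- arms |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(chrom_arm_bp = sum(as.numeric(.data$end) -
                                          as.numeric(.data$start) + 1))
  merge_pieces(pieces, unit = "chrom", max_gap = tol,
               bridge_centromere = TRUE, tol = tol) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$region) |>
    dplyr::summarise(covered_bp = sum(as.numeric(.data$ov_len)),
                     .groups = "drop") |>
    dplyr::left_join(chrom_bp, by = "chrom") |>
    dplyr::filter(.data$covered_bp > min_bp,
                  .data$covered_bp < .data$chrom_arm_bp - tol) |>
    dplyr::count(.data$sample, name = "hrd_loh")
}

tai_from_pieces <- function(clipped, min_bp, telomere_tol) {
  pieces <- clipped |>
    dplyr::filter(2 * .data$n_minor != .data$n_total)
  if (nrow(pieces) == 0) {
    return(tibble::tibble(sample = character(0), tai = integer(0)))
  }
  merge_pieces(pieces, unit = "arm_id", max_gap = 1) |>
    dplyr::group_by(.data$sample, .data$arm_id, .data$arm, .data$region,
                    .data$arm_start, .data$arm_end) |>
    dplyr::summarise(r_start = min(.data$ov_start),
                     r_end = max(.data$ov_end), .groups = "drop") |>
    dplyr::filter(
      .data$r_end - .data$r_start + 1 > min_bp,
      (.data$arm == "p" & .data$r_start <= .data$arm_start + telomere_tol) |
        (.data$arm == "q" & .data$r_end >= .data$arm_end - telomere_tol)
    ) |>
    dplyr::count(.data$sample, name = "tai")
}

lst_from_pieces <- function(clipped, min_flank_bp, max_gap_bp, smooth_bp) {
  pieces <- dplyr::filter(clipped, .data$ov_len >= smooth_bp)
  if (nrow(pieces) == 0) {
    return(tibble::tibble(sample = character(0), lst = integer(0)))
  }
  regions <- merge_pieces(pieces, unit = "arm_id", same_key = TRUE,
                          max_gap = Inf) |>
    dplyr::group_by(.data$sample, .data$arm_id, .data$region) |>
    dplyr::summarise(r_start = min(.data$ov_start),
                     r_end = max(.data$ov_end), .groups = "drop") |>
    dplyr::arrange(.data$sample, .data$arm_id, .data$r_start)
  same_run <- regions$sample == dplyr::lag(regions$sample, default = "") &
    regions$arm_id == dplyr::lag(regions$arm_id, default = "")
  len <- regions$r_end - regions$r_start + 1
  gap <- regions$r_start - dplyr::lag(regions$r_end, default = 0L) - 1
  is_lst <- same_run & gap <= max_gap_bp & len >= min_flank_bp &
    dplyr::lag(len, default = 0) >= min_flank_bp
  regions |>
    dplyr::mutate(lst = is_lst) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(lst = sum(.data$lst), .groups = "drop")
}

#' HRD-LOH score
#'
#' Counts loss-of-heterozygosity regions longer than 15 Mb that do not span a
#' whole chromosome. LOH bp (minor-allele copy number 0 with at least one
#' remaining copy) is clipped to the arm table, touching LOH pieces are merged
#' into maximal regions (a gap exactly spanning the centromere is bridged, so
#' a chromosome that is LOH on both arms forms one region), and a region's
#' length is its covered bp. Regions covering every analysable arm of their
#' chromosome within `tol` bp are excluded as whole-chromosome events.
#'
#' @param segs Segment tibble (`chrom`, `start`, `end`, `n_total`, `n_minor`,
#'   optional `sample`).
#' @param arms Arm table, see [hg19_arms()].
#' @param min_bp Minimum region length in bp, exclusive (default 15 Mb).
#' @param tol Tolerance in bp for the whole-chromosome test and for bridging
#'   the centromere.
#' @return A tibble with `sample` and `hrd_loh`.
#' @export
score_hrd_loh <- function(segs, arms = hg19_arms(), min_bp = 15e6, tol = 1) {
  segs <- ensure_sample_col(segs)
  counts <- hrd_loh_from_pieces(arm_clip(segs, arms), arms, min_bp, tol)
  complete_counts(counts, unique(segs$sample), "hrd_loh")
}

#' Telomeric allelic imbalance (TAI) score
#'
#' Counts allelic-imbalance regions (unequal parental allele copy numbers,
#' i.e. `2 * n_minor != n_total`) that reach a telomeric chromosome end.
#' Imbalanced bp is clipped to arms, touching imbalanced pieces are merged
#' into maximal regions per arm (so regions never cross the centromere), and
#' a region counts when its boundary lies within `telomere_tol` of the arm's
#' telomeric end (the start of a p arm, the end of a q arm) and it is longer
#' than `min_bp`.
#'
#' @inheritParams score_hrd_loh
#' @param min_bp Minimum region length in bp, exclusive (default 1 Mb, a
#'   probe-noise floor).
#' @param telomere_tol Maximum distance in bp between the region boundary and
#'   the telomeric arm end (default 1000).
#' @return A tibble with `sample` and `tai`.
#' @export
score_tai <- function(segs, arms = hg19_arms(), min_bp = 1e6,
                      telomere_tol = 1000) {
  segs <- ensure_sample_col(segs)
  counts <- tai_from_pieces(arm_clip(segs, arms), min_bp, telomere_tol)
  complete_counts(counts, unique(segs$sample), "tai")
}

#' Large-scale state transition (LST) score
#'
#' Counts chromosomal breaks between adjacent copy-number regions of at least
#' 10 Mb separated by at most 3 Mb. Segments are clipped to arms (no break is
#' counted across the centromere), pieces shorter than `smooth_bp` are
#' dropped, remaining adjacent pieces with identical allele-specific copy
#' number are merged, and each junction between two different-state regions
#' with both flanks >= `min_flank_bp` and gap <= `max_gap_bp` counts one LST.
#'
#' @inheritParams score_hrd_loh
#' @param min_flank_bp Minimum length of both flanking regions (default 10 Mb).
#' @param max_gap_bp Maximum distance between the flanking regions (default 3 Mb).
#' @param smooth_bp Segments shorter than this are ignored before scanning
#'   (default 3 Mb).
#' @return A tibble with `sample` and `lst`.
#' @export
score_lst <- function(segs, arms = hg19_arms(), min_flank_bp = 10e6,
                      max_gap_bp = 3e6, smooth_bp = 3e6) {
  segs <- ensure_sample_col(segs)
  counts <- lst_from_pieces(arm_clip(segs, arms), min_flank_bp, max_gap_bp,
                            smooth_bp)
  complete_counts(counts, unique(segs$sample), "lst")
}

#' Combined HRD scar score
#'
#' Computes HRD-LOH, TAI and LST per sample and their sum, the HRD score
#' used as a genomic-scar proxy for homologous-recombination deficiency.
#' The three components are computed from one shared arm-clipped view of the
#' segments and equal the standalone [score_hrd_loh()], [score_tai()] and
#' [score_lst()] results.
#'
#' @inheritParams score_hrd_loh
#' @param min_loh_bp,loh_tol Passed to the HRD-LOH component.
#' @param min_tai_bp,telomere_tol Passed to the TAI component.
#' @param min_flank_bp,max_gap_bp,smooth_bp Passed to the LST component.
#' @return A tibble with `sample`, `hrd_loh`, `tai`, `lst`, `hrd_total`.
#' @examples
#' segs <- tibble::tibble(chrom = "chr1", start = 1, end = 121535433,
#'                        n_total = 2L, n_minor = 1L)
#' hrd_score(segs)
#' @export
hrd_score <- function(segs, arms = hg19_arms(), min_loh_bp = 15e6,
                      loh_tol = 1, min_tai_bp = 1e6, telomere_tol = 1000,
                      min_flank_bp = 10e6, max_gap_bp = 3e6,
                      smooth_bp = 3e6) {
  segs <- ensure_sample_col(segs)
  samples <- unique(segs$sample)
  clipped <- arm_clip(segs, arms)
  loh <- complete_counts(hrd_loh_from_pieces(clipped, arms, min_loh_bp,
                                             loh_tol),
                         samples, "hrd_loh")
  tai <- complete_counts(tai_from_pieces(clipped, min_tai_bp, telomere_tol),
                         samples, "tai")
  lst <- complete_counts(lst_from_pieces(clipped, min_flank_bp, max_gap_bp,
                                         smooth_bp),
                         samples, "lst")
  loh |>
    dplyr::left_join(tai, by = "sample") |>
    dplyr::left_join(lst, by = "sample") |>
    dplyr::mutate(hrd_total = .data$hrd_loh + .data$tai + .data$lst)
}
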