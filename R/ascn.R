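# Allele-specific copy-number segments: classification into gain / loss /
# UPD (copy-neutral LOH), log-ratio discretisation for tumor-only profiles,
# arm-level aggregation and per-sample SCNA fractions.

ensure_sample_col <- function(segs) {
  if (!"sample" %in% names(segs)) segs$sample <- "sample1"
  segs
}

validate_segments <- function(segs) {
  needed <- c("chrom", "start", "end", "n_total", "n_minor")
  missing <- setdiff(needed, names(segs))
  if (length(missing) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(segs$end < segs$start)) abort("segment end < start")
  if (any(segs$n_total < 0) || any(segs$n_minor < 0)) {
    abort("copy numbers must be non-negative")
  }
  bad <- segs$n_total > 0 & segs$n_minor > segs$n_total - segs$n_minor
  if (any(bad)) {
    abort("n_minor must be the smaller allele count (n_minor <= n_total - n_minor)")
  }
  invisible(segs)
}

#' Classify allele-specific copy-number segments
#'
#' Assigns each segment a copy-number state relative to a diploid reference:
#' `upd` (copy-neutral LOH: total 2, minor 0), `loss` (total below the
#' reference ploidy), `gain` (total above it), `neutral` otherwise. An
#' independent logical `is_loh` marks any segment with minor-allele copy
#' number 0 and at least one remaining copy, so losses and gains with LOH are
#' flagged without being re-labelled.
#'
#' @param segs A tibble of segments with `chrom`, `start`, `end` (1-based
#'   inclusive bp), `n_total`, `n_minor`, and optionally `sample`.
#' @param ploidy_ref Reference ploidy the states are called against
#'   (default 2; tumour-ploidy adjustment is deliberately out of scope).
#' @return The input tibble with `state` and `is_loh` columns added.
#' @examples
#' segs <- tibble::tibble(chrom = "chr17", start = 1, end = 2e7,
#'                        n_total = 2L, n_minor = 0L)
#' classify_segments(segs)$state
#' @export
classify_segments <- function(segs, ploidy_ref = 2L) {
  validate_segments(segs)
  segs |>
    dplyr::mutate(
      state = dplyr::case_when(
        .data$n_total == ploidy_ref & .data$n_minor == 0 ~ "upd",
        .data$n_total < ploidy_ref ~ "loss",
        .data$n_total > ploidy_ref ~ "gain",
        TRUE ~ "neutral"
      ),
      is_loh = .data$n_minor == 0 & .data$n_total >= 1
    )
}

#' Discretise copy-number log-ratios
#'
#' Maps tumor/normal depth log-ratios to integer total copy number 0-4 using
#' the fixed cut points -1.1, -0.4, 0.3 and 0.7 (lower-exclusive,
#' upper-inclusive bins), the convention used to infer copy number for
#' tumor-only profiles.
#'
#' @param logR Numeric vector of log-ratios; must be finite.
#' @param cuts The four increasing cut points.
#' @return Integer vector of copy numbers in 0..4.
#' @examples
#' discretize_log_ratio(c(-2, -1.1, 0, 0.5, 0.71))
#' @export
discretize_log_ratio <- function(logR, cuts = c(-1.1, -0.4, 0.3, 0.7)) {
  if (any(!is.finite(logR))) abort("logR values must be finite")
  stopifnot(length(cuts) == 4, !is.unsorted(cuts))
  as.integer(cut(logR, breaks = c(-Inf, cuts, Inf), right = TRUE,
                 labels = FALSE)) - 1L
}

# Overlap segments with arms; returns one row per (segment, arm) overlap with
# the overlap interval and its length. Segments crossing the centromere are
# thereby split into per-arm pieces; bp inside the centromere is dropped.
overlap_with_arms <- function(segs, arms) {
  segs |>
    dplyr::inner_join(
      arms |>
        dplyr::select("chrom", "arm", "arm_id",
                      arm_start = "start", arm_end = "end"),
      by = dplyr::join_by("chrom", "start" <= "arm_end", "end" >= "arm_start")
    ) |>
    dplyr::mutate(
      ov_start = pmax(.data$start, .data$arm_start),
      ov_end = pmin(.data$end, .data$arm_end),
      ov_len = .data$ov_end - .data$ov_start + 1
    )
}

#' Call arm-level copy-number events
#'
#' Aggregates classified segments to chromosome arms. An arm carries a
#' non-neutral state when at least `min_fraction` of its length is covered by
#' segments in that state; when several states reach the threshold the one
#' with the larger covered fraction wins, ties broken by the priority
#' UPD > loss > gain. Segments crossing the centromere are split at its
#' edges before accounting.
#'
#' @param segs Segment tibble (see [classify_segments()]); a `sample` column
#'   is honoured.
#' @param arms Arm table as returned by [hg19_arms()].
#' @param min_fraction Minimum covered fraction of the arm required to call a
#'   state (default 0.5).
#' @return A tibble with one row per sample and arm: `sample`, `arm_id`,
#'   `chrom`, `arm`, `state`, `fraction` (covered fraction of the arm in the
#'   called state).
#' @export
arm_events <- function(segs, arms = hg19_arms(), min_fraction = 0.5) {
  segs <- ensure_sample_col(classify_segments(segs))
  arm_len <- arms |>
    dplyr::mutate(arm_len = .data$end - .data$start + 1) |>
    dplyr::select("arm_id", "chrom", "arm", "arm_len")

  cov <- overlap_with_arms(segs, arms) |>
    dplyr::group_by(.data$sample, .data$arm_id, .data$state) |>
    dplyr::summarise(bp = sum(.data$ov_len), .groups = "drop") |>
    dplyr::left_join(arm_len, by = "arm_id") |>
    dplyr::mutate(fraction = .data$bp / .data$arm_len)

  prio <- c(upd = 1, loss = 2, gain = 3)
  calls <- cov |>
    dplyr::filter(.data$state != "neutral", .data$fraction >= min_fraction) |>
    dplyr::arrange(.data$sample, .data$arm_id,
                   dplyr::desc(.data$fraction), prio[.data$state]) |>
    dplyr::distinct(.data$sample, .data$arm_id, .keep_all = TRUE)

  neutral_cov <- cov |>
    dplyr::filter(.data$state == "neutral") |>
    dplyr::select("sample", "arm_id", neutral_fraction = "fraction")

  grid <- tidyr::expand_grid(sample = unique(segs$sample),
                             arm_id = arms$arm_id)
  grid |>
    dplyr::left_join(calls |>
                       dplyr::select("sample", "arm_id", "state", "fraction"),
                     by = c("sample", "arm_id")) |>
    dplyr::left_join(neutral_cov, by = c("sample", "arm_id")) |>
    dplyr::mutate(
      fraction = dplyr::if_else(is.na(.data$state),
                                dplyr::coalesce(.data$neutral_fraction, 0),
                                .data$fraction),
      state = dplyr::coalesce(.data$state, "neutral")
    ) |>
    dplyr::select(-"neutral_fraction") |>
    dplyr::left_join(arm_len, by = "arm_id") |>
    dplyr::select("sample", "arm_id", "chrom", "arm", "state", "fraction") |>
    dplyr::arrange(.data$sample, match(.data$arm_id, arms$arm_id))
}

#' Genome-wide SCNA fractions per sample
#'
#' Fraction of the analysable autosomal genome (the bp covered by the arm
#' table) in gain, loss and UPD states. Fractions are independent bp ratios
#' and are not forced to sum to one.
#'
#' @inheritParams arm_events
#' @return A tibble with `sample`, `fraction_gain`, `fraction_loss`,
#'   `fraction_upd`.
#' @export
scna_fractions <- function(segs, arms = hg19_arms()) {
  segs <- ensure_sample_col(classify_segments(segs))
  total_bp <- sum(as.numeric(arms$end) - as.numeric(arms$start) + 1)
  bp <- overlap_with_arms(segs, arms) |>
    dplyr::group_by(.data$sample, .data$state) |>
    dplyr::summarise(bp = sum(.data$ov_len), .groups = "drop")
  tidyr::expand_grid(sample = unique(segs$sample),
                     state = c("gain", "loss", "upd")) |>
    dplyr::left_join(bp, by = c("sample", "state")) |>
    dplyr::mutate(fraction = dplyr::coalesce(.data$bp, 0) / total_bp) |>
    dplyr::select("sample", "state", "fraction") |>
    tidyr::pivot_wider(names_from = "state", values_from = "fraction",
                       names_prefix = "fraction_") |>
    dplyr::select("sample", "fraction_gain", "fraction_loss", "fraction_upd")
}

#' Read / write SEG-like allele-specific segment tables
#'
#' Tab-separated tables with columns `sample`, `chrom`, `start`, `end`,
#' `n_total`, `n_minor` and optionally `logR`, `baf`; coordinates are 1-based
#' inclusive.
#'
#' @param path File path.
#' @return `read_seg()` returns the segment tibble; `write_seg()` returns
#'   `path` invisibly.
#' @export
read_seg <- function(path) {
  segs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  segs <- dplyr::mutate(
    segs,
    dplyr::across(dplyr::any_of(c("start", "end", "n_total", "n_minor")),
                  as.integer)
  )
  validate_segments(segs)
  tibble::as_tibble(segs)
}

#' @rdname read_seg
#' @param segs Segment tibble.
#' @export
write_seg <- function(segs, path) {
  validate_segments(segs)
  readr::write_tsv(segs, path, progress = FALSE)
  invisible(path)
}
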