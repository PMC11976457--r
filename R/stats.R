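# Tumor mutational burden and the between-cohort comparisons: Wilcoxon
# rank-sum for continuous omics features, Fisher's exact test for gene/arm
# alteration proportions, BH adjustment across a frequency scan.

nonsyn_effects <- c("missense", "nonsense", "frameshift", "splice",
                    "inframe_indel", "stoploss", "startloss")

#' Tumor mutational burden
#'
#' Mutations per megabase of targeted exome. By default only nonsynonymous
#' coding mutations qualify; the denominator defaults to the 38 Mb of a
#' standard whole-exome capture design and is configurable.
#'
#' @param mutations Filtered somatic mutation tibble with an `effect` column
#'   and optionally `sample`.
#' @param exome_mb Targeted exome size in Mb (must be positive).
#' @param nonsyn_only Count only nonsynonymous coding mutations
#'   (default `TRUE`).
#' @param samples Optional character vector of sample ids; samples without
#'   qualifying mutations then appear with a TMB of 0.
#' @return A tibble with `sample`, `n_mutations`, `tmb`.
#' @examples
#' m <- tibble::tibble(sample = "s1", effect = rep("missense", 76))
#' compute_tmb(m) # 2 mutations/Mb
#' @export
compute_tmb <- function(mutations, exome_mb = 38, nonsyn_only = TRUE,
                        samples = NULL) {
  if (!is.numeric(exome_mb) || exome_mb <= 0) {
    abort("exome_mb must be positive")
  }
  mutations <- ensure_sample_col(mutations)
  if (nonsyn_only) {
    mutations <- dplyr::filter(mutations, .data$effect %in% nonsyn_effects)
  }
  out <- mutations |>
    dplyr::count(.data$sample, name = "n_mutations")
  if (!is.null(samples)) {
    out <- tibble::tibble(sample = samples) |>
      dplyr::left_join(out, by = "sample") |>
      dplyr::mutate(n_mutations = dplyr::coalesce(.data$n_mutations, 0L))
  }
  dplyr::mutate(out, tmb = .data$n_mutations / exome_mb)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. For small samples
#' without ties the exact p-value is computed; otherwise the normal
#' approximation with continuity and tie correction is used. When every
#' value in both groups is identical the comparison is degenerate and p = 1
#' is returned with a flag.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A one-row tibble: `statistic` (the rank-sum W), `p_value`,
#'   `method` (`"exact"`, `"normal_approx"` or `"degenerate"`),
#'   `degenerate`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approx",
    degenerate = FALSE
  )
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table (the probability-mass definition), with the
#' conditional maximum-likelihood odds ratio — both as implemented in
#' `stats::fisher.test()`. A table with a zero margin carries no
#' information: p = 1 is returned, the odds ratio is `NA` and the result is
#' flagged degenerate.
#'
#' @param a,b,c_,d_ Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c_, d_), 2, 2, byrow = TRUE)`.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `degenerate`.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  counts <- c(a, b, c_, d_)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(odds_ratio = NA_real_, p_value = 1,
                          degenerate = TRUE))
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  tibble::tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                 degenerate = FALSE)
}

#' Scan alteration frequencies between two cohorts
#'
#' Per-feature Fisher exact comparison of alteration proportions (mutated
#' gene, gained/lost/UPD arm, ...) between two named cohorts, with
#' Benjamini-Hochberg adjustment across the scan. Features altered in no
#' sample of either cohort are skipped and reported in the `skipped`
#' attribute.
#'
#' @param alterations Long tibble with `sample`, `feature` and a logical or
#'   0/1 `altered` column.
#' @param clinical Tibble mapping `sample` to `cohort`.
#' @param cohorts Length-2 character vector naming the cohorts to compare.
#' @param adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A tibble sorted by p-value: `feature`, per-cohort altered/total
#'   counts, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
frequency_scan <- function(alterations, clinical,
                           cohorts = c("transformed", "denovo"),
                           adjust = "BH") {
  if (length(cohorts) != 2) abort("exactly two cohorts must be named")
  lab <- clinical |>
    dplyr::filter(.data$cohort %in% cohorts) |>
    dplyr::select("sample", "cohort")
  if (length(unique(lab$cohort)) < 2) {
    abort("both cohorts must contain samples")
  }
  totals <- dplyr::count(lab, .data$cohort, name = "total")
  tab <- alterations |>
    dplyr::inner_join(lab, by = "sample") |>
    dplyr::group_by(.data$feature, .data$cohort) |>
    dplyr::summarise(altered = sum(as.logical(.data$altered)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "altered",
                       values_fill = 0L)
  for (ch in cohorts) if (!ch %in% names(tab)) tab[[ch]] <- 0L
  n1 <- totals$total[match(cohorts[1], totals$cohort)]
  n2 <- totals$total[match(cohorts[2], totals$cohort)]
  tab <- tab |>
    dplyr::mutate(a1 = .data[[cohorts[1]]], a2 = .data[[cohorts[2]]])
  skipped <- tab$feature[tab$a1 + tab$a2 == 0]
  if (length(skipped) > 0) {
    message(length(skipped), " feature(s) altered in no sample; skipped")
  }
  tab <- dplyr::filter(tab, .data$a1 + .data$a2 > 0)
  tests <- purrr::pmap_dfr(list(tab$a1, tab$a2), function(a1, a2) {
    fisher_exact_2x2(a1, n1 - a1, a2, n2 - a2)
  })
  out <- tab |>
    dplyr::transmute(
      feature = .data$feature,
      "altered_{cohorts[1]}" := .data$a1,
      "total_{cohorts[1]}" := n1,
      "altered_{cohorts[2]}" := .data$a2,
      "total_{cohorts[2]}" := n2,
      odds_ratio = tests$odds_ratio,
      p_value = tests$p_value
    ) |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, method = adjust)) |>
    dplyr::arrange(.data$p_value, .data$feature)
  attr(out, "skipped") <- as.character(skipped)
  out
}

#' Assemble the per-sample omics feature table
#'
#' Combines TMB, SCNA fractions and genomic-scar scores into one row per
#' sample, joined to cohort labels — the substrate for the between-cohort
#' omics comparison.
#'
#' @param mutations Filtered somatic mutations (multi-sample).
#' @param segments Allele-specific segments (multi-sample).
#' @param clinical Tibble with `sample` and `cohort`.
#' @param arms Arm table.
#' @param exome_mb,nonsyn_only Passed to [compute_tmb()].
#' @return A tibble with `sample`, `cohort`, `tmb`, `fraction_gain`,
#'   `fraction_loss`, `fraction_upd`, `scna_fraction` (their sum),
#'   `hrd_loh`, `tai`, `lst`, `hrd_total`.
#' @export
cohort_features <- function(mutations, segments, clinical,
                            arms = hg19_arms(), exome_mb = 38,
                            nonsyn_only = TRUE) {
  tmb <- compute_tmb(mutations, exome_mb = exome_mb,
                     nonsyn_only = nonsyn_only)
  fr <- scna_fractions(segments, arms)
  sc <- hrd_score(segments, arms)
  clinical |>
    dplyr::select("sample", "cohort") |>
    dplyr::left_join(tmb, by = "sample") |>
    dplyr::left_join(fr, by = "sample") |>
    dplyr::left_join(sc, by = "sample") |>
    dplyr::mutate(
      tmb = dplyr::coalesce(.data$tmb, 0),
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      scna_fraction = .data$fraction_gain + .data$fraction_loss +
        .data$fraction_upd
    )
}

#' Compare omics features between two cohorts
#'
#' Runs the Wilcoxon rank-sum comparison for each numeric feature column
#' between two cohorts and reports group medians alongside the p-value —
#' the TMB / SCNA / HRD / gain / loss / UPD / LOH / TAI / LST panel of the
#' study design.
#'
#' @param features Feature table from [cohort_features()].
#' @param cohorts Length-2 character vector; the test contrasts
#'   `cohorts[1]` against `cohorts[2]`.
#' @param feature_cols Columns to test; defaults to every numeric column
#'   except `n_mutations`.
#' @return A tibble: `feature`, medians per cohort, `statistic`, `p_value`,
#'   `method`, `higher_in` (cohort with the larger median, `NA` on ties).
#' @export
compare_features <- function(features, cohorts = c("denovo", "transformed"),
                             feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))],
      "n_mutations"
    )
  }
  f1 <- dplyr::filter(features, .data$cohort == cohorts[1])
  f2 <- dplyr::filter(features, .data$cohort == cohorts[2])
  if (nrow(f1) == 0 || nrow(f2) == 0) abort("both cohorts must have samples")
  purrr::map_dfr(feature_cols, function(col) {
    res <- wilcoxon_rank_sum(f1[[col]], f2[[col]])
    m1 <- stats::median(f1[[col]])
    m2 <- stats::median(f2[[col]])
    tibble::tibble(
      feature = col,
      "median_{cohorts[1]}" := m1,
      "median_{cohorts[2]}" := m2,
      statistic = res$statistic,
      p_value = res$p_value,
      method = res$method,
      higher_in = dplyr::case_when(m1 > m2 ~ cohorts[1],
                                   m2 > m1 ~ cohorts[2],
                                   TRUE ~ NA_character_)
    )
  }) |>
    dplyr::arrange(.data$p_value)
}
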