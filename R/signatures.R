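# 96-context single-base-substitution spectra and reference-signature
# deconvolution by non-negative least squares with the usual drop/refit of
# minor signatures.

#' Canonical 96 trinucleotide mutation contexts
#'
#' The pyrimidine-strand contexts in the conventional order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the sixteen
#' 5'/3' flanking-base combinations in alphabetical order, labelled e.g.
#' `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t3) {
      paste0(f, "[", s, "]", t3)
    })))
  }))
}

#' Bundled demonstration signature matrix
#'
#' A small synthetic reference of four 96-context signatures for tests and
#' examples: a clock-like CpG C>T signature (`SBS1`), a smoking-style C>A
#' signature (`SBS4`), a broad C>T / T>C signature (`SBS5`) and a uniform
#' `flat` component. These are simplified stand-ins constructed in code, not
#' the COSMIC catalogue; supply the real COSMIC matrix via
#' [read_signature_matrix()] for real analyses.
#'
#' @return A 96 x 4 numeric matrix; rows named by [sbs_contexts()], columns
#'   by signature id, each column summing to 1.
#' @export
toy_signature_matrix <- function() {
  ctx <- sbs_contexts()
  sub_of <- sub(".*\\[(.*)\\].*", "\\1", ctx)
  three_of <- substr(ctx, 7, 7)
  sbs1 <- rep(0.24 / 92, 96)
  cpg_ct <- sub_of == "C>T" & three_of == "G"
  sbs1[cpg_ct] <- 0.19
  sbs4 <- rep(0.2 / 80, 96)
  sbs4[sub_of == "C>A"] <- 0.05
  sbs5 <- rep(0.1 / 64, 96)
  sbs5[sub_of == "C>T"] <- 0.6 / 16
  sbs5[sub_of == "T>C"] <- 0.3 / 16
  flat <- rep(1 / 96, 96)
  m <- cbind(SBS1 = sbs1, SBS4 = sbs4, SBS5 = sbs5, flat = flat)
  rownames(m) <- ctx
  m
}

#' Read or write a signature matrix TSV
#'
#' The interchange format is a TSV with a `context` column (96 rows in the
#' canonical order, see [sbs_contexts()]) and one numeric column per
#' signature, each summing to 1.
#'
#' @param path File path.
#' @return `read_signature_matrix()` returns a 96 x K matrix.
#' @export
read_signature_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[setdiff(names(tbl), "context")])
  rownames(m) <- tbl$context
  validate_signature_matrix(m)
  m
}

#' @rdname read_signature_matrix
#' @param sigs Signature matrix with row names in context order.
#' @export
write_signature_matrix <- function(sigs, path) {
  validate_signature_matrix(sigs)
  tbl <- tibble::tibble(context = rownames(sigs)) |>
    dplyr::bind_cols(tibble::as_tibble(sigs))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

validate_signature_matrix <- function(sigs) {
  if (!identical(rownames(sigs), sbs_contexts())) {
    abort("signature matrix rows must be the 96 canonical contexts in order")
  }
  if (any(sigs < 0)) abort("signature matrix entries must be non-negative")
  if (any(abs(colSums(sigs) - 1) > 1e-6)) {
    abort("each signature column must sum to 1 (tolerance 1e-6)")
  }
  invisible(sigs)
}

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' Build a 96-context mutation spectrum
#'
#' Collapses single-nucleotide substitutions onto the pyrimidine strand and
#' counts them in the 96 canonical trinucleotide contexts. Mutations whose
#' class is not SNV are ignored; their number is recorded in the
#' `n_non_snv` attribute of the result.
#'
#' @param mutations Mutation tibble with `ref`, `alt` and a 3-base `context`
#'   column (the reference trinucleotide around the variant); a `class`
#'   column marks INDELs.
#' @return A tibble with `context` (96 rows, canonical order) and `count`.
#' @examples
#' m <- tibble::tibble(ref = "C", alt = "A", class = "SNV", context = "ACA")
#' build_spectrum(m)[1, ]
#' @export
build_spectrum <- function(mutations) {
  ctx_order <- sbs_contexts()
  is_snv <- if ("class" %in% names(mutations)) {
    !is.na(mutations$class) & mutations$class == "SNV"
  } else {
    nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1
  }
  n_non_snv <- sum(!is_snv)
  snv <- mutations[is_snv, , drop = FALSE]
  if (nrow(snv) > 0) {
    bad <- is.na(snv$context) | !grepl("^[ACGT]{3}$", snv$context) |
      substr(snv$context, 2, 2) != snv$ref
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("unusable trinucleotide context for mutation ",
                   snv$chrom[i] %||% "?", ":", snv$pos[i] %||% "?",
                   " ", snv$ref[i], ">", snv$alt[i]))
    }
    flip <- snv$ref %in% c("A", "G")
    ref <- ifelse(flip, chartr("ACGT", "TGCA", snv$ref), snv$ref)
    alt <- ifelse(flip, chartr("ACGT", "TGCA", snv$alt), snv$alt)
    ctx <- ifelse(flip, revcomp(snv$context), snv$context)
    label <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                    substr(ctx, 3, 3))
    unknown <- !label %in% ctx_order
    if (any(unknown)) {
      i <- which(unknown)[1]
      abort(paste0("mutation does not map to a canonical context: ",
                   label[i]))
    }
    counts <- table(factor(label, levels = ctx_order))
  } else {
    counts <- setNames(rep(0L, 96), ctx_order)
  }
  out <- tibble::tibble(context = ctx_order, count = as.integer(counts))
  attr(out, "n_non_snv") <- n_non_snv
  out
}

#' @rdname build_spectrum
#' @description `build_spectra()` builds one spectrum per sample from a
#'   multi-sample mutation table.
#' @return `build_spectra()` returns a long tibble with `sample`, `context`,
#'   `count`.
#' @export
build_spectra <- function(mutations) {
  mutations <- ensure_sample_col(mutations)
  mutations |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(~ build_spectrum(.x)) |>
    dplyr::ungroup()
}

#' Read or write spectra
#'
#' Long-format TSV with columns `sample`, `context`, `count`.
#' @param path File path.
#' @export
read_spectra <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' @rdname read_spectra
#' @param spectra Long spectra tibble.
#' @export
write_spectra <- function(spectra, path) {
  readr::write_tsv(spectra, path, progress = FALSE)
  invisible(path)
}

spectrum_vector <- function(spectrum) {
  if (is.numeric(spectrum)) {
    if (length(spectrum) != 96) abort("spectrum must have 96 entries")
    return(as.numeric(spectrum))
  }
  if (!identical(spectrum$context, sbs_contexts())) {
    abort("spectrum contexts must be the 96 canonical contexts in order")
  }
  as.numeric(spectrum$count)
}

#' Fit signature exposures by non-negative least squares
#'
#' Decomposes a normalized 96-context spectrum into non-negative mixture
#' weights over reference signatures. The spectrum is scaled to sum one,
#' weights are fitted by non-negative least squares, signatures whose
#' normalized weight falls below `drop_threshold` are removed and the
#' remaining set refitted until stable, and the final weights are
#' renormalized to sum one. Signature activities are mixture proportions and
#' cannot be negative, hence the constrained fit.
#'
#' @param spectrum A spectrum tibble from [build_spectrum()] or a numeric
#'   vector of 96 counts; total must be positive.
#' @param sigs Reference signature matrix (96 x K, columns summing to 1);
#'   defaults to the bundled demonstration matrix.
#' @param active Optional character vector restricting the fit to a subset
#'   of signature ids.
#' @param drop_threshold Minimum normalized weight a signature must reach to
#'   stay in the fit (default 0.06).
#' @return An object of class `exposure_fit` with elements `weights` (named,
#'   summing to 1), `residual` (Euclidean norm of the fit residual on the
#'   normalized spectrum), `n_mutations` and `dropped`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @examples
#' sigs <- toy_signature_matrix()
#' fit <- fit_exposures(round(1000 * sigs[, "SBS1"]), sigs)
#' tidy(fit)
#' @export
fit_exposures <- function(spectrum, sigs = toy_signature_matrix(),
                          active = NULL, drop_threshold = 0.06) {
  validate_signature_matrix(sigs)
  x <- spectrum_vector(spectrum)
  if (any(x < 0)) abort("spectrum counts must be non-negative")
  total <- sum(x)
  if (total <= 0) abort("spectrum has no mutations; cannot fit exposures")
  p <- x / total
  all_ids <- colnames(sigs)
  act <- if (is.null(active)) all_ids else {
    missing <- setdiff(active, all_ids)
    if (length(missing) > 0) {
      abort(paste0("unknown signature id(s): ", paste(missing, collapse = ", ")))
    }
    active
  }
  repeat {
    fit <- pracma::lsqnonneg(sigs[, act, drop = FALSE], p)
    w <- setNames(fit$x, act)
    if (sum(w) <= 0) break
    wn <- w / sum(w)
    keep <- names(wn)[wn >= drop_threshold]
    if (length(keep) == length(act) || length(keep) == 0) break
    act <- keep
  }
  resid <- sqrt(sum((p - sigs[, act, drop = FALSE] %*% fit$x)^2))
  weights <- setNames(rep(0, length(all_ids)), all_ids)
  if (sum(w) > 0) weights[names(w)] <- w / sum(w)
  structure(
    list(weights = weights, residual = resid, n_mutations = total,
         dropped = setdiff(if (is.null(active)) all_ids else active, act),
         drop_threshold = drop_threshold),
    class = "exposure_fit"
  )
}

#' Fit exposures for every sample in a cohort
#'
#' @param spectra Long spectra tibble (`sample`, `context`, `count`).
#' @inheritParams fit_exposures
#' @return A tibble with `sample`, `signature`, `weight`, `residual`,
#'   `n_mutations`. Samples with empty spectra are skipped with a warning.
#' @export
fit_cohort_exposures <- function(spectra, sigs = toy_signature_matrix(),
                                 active = NULL, drop_threshold = 0.06) {
  by_sample <- split(spectra, spectra$sample)
  empty <- names(by_sample)[vapply(by_sample, function(s) sum(s$count) == 0,
                                   logical(1))]
  if (length(empty) > 0) {
    warn(paste0("skipping sample(s) with empty spectra: ",
                paste(empty, collapse = ", ")))
  }
  purrr::map_dfr(setdiff(names(by_sample), empty), function(id) {
    f <- fit_exposures(by_sample[[id]], sigs, active, drop_threshold)
    tidy(f) |>
      dplyr::mutate(sample = id, residual = f$residual,
                    n_mutations = f$n_mutations, .before = 1)
  })
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposure fit (", x$n_mutations, " mutations)\n", sep = "")
  on <- x$weights[x$weights > 0]
  for (id in names(on)) cat(sprintf("  %-8s %.3f\n", id, on[id]))
  cat(sprintf("  residual norm %.4f\n", x$residual))
  invisible(x)
}

#' Tidy a signature exposure fit
#'
#' @param x An `exposure_fit` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `signature` and `weight`; `glance()`: a
#'   one-row tibble with `residual`, `n_active`, `n_mutations`.
#' @method tidy exposure_fit
#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble::tibble(signature = names(x$weights), weight = unname(x$weights))
}

#' @rdname tidy.exposure_fit
#' @method glance exposure_fit
#' @export
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual,
                 n_active = sum(x$weights > 0),
                 n_mutations = x$n_mutations)
}

#' @rdname tidy.exposure_fit
#' @param object An `exposure_fit` object.
#' @method autoplot exposure_fit
#' @export
autoplot.exposure_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$signature, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "exposure weight") +
    ggplot2::theme_minimal()
}
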