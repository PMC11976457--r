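# Seeded synthetic-cohort generator. Emulates the study's group structure —
# primary LUAD, transformed SCLC and de novo SCLC — with the contrasts the
# downstream modules are designed to detect: EGFR mutation in every
# LUAD/transformed sample but a minority of de novo ones, TP53/RB1 driver
# frequencies per group, elevated UPD/loss arm burden in transformed
# samples, higher mutation counts and a smoking-signature component only in
# de novo samples. Two pseudo-callers with configurable overlap and a
# contamination class give the consensus filter something to remove.

cohort_levels <- c("primary_luad", "transformed", "denovo")

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the generator. The defaults are the study
#' conditions: cohort sizes 5 / 10 / 18 (primary LUAD / transformed SCLC
#' post-QC / de novo SCLC), EGFR mutated in all LUAD and transformed samples
#' and 17\% of de novo, TP53 at 60 / 70 / 89\% and RB1 at 40 / 30 / 50\%,
#' more UPD and loss arms in transformed samples, higher mutation burden and
#' a smoking-signature (SBS4) component only in de novo samples.
#'
#' @param n_primary_luad,n_transformed,n_denovo Cohort sizes (all > 0).
#' @param mean_tmb Named vector (one entry per cohort) of expected
#'   nonsynonymous somatic mutations per Mb planted per sample.
#' @param upd_arm_rate,loss_arm_rate,gain_arm_rate Named vectors of per-arm
#'   event probabilities per cohort.
#' @param signature_mix Named list (per cohort) of named signature-weight
#'   vectors; each must sum to 1 over columns of the signature matrix used.
#' @param driver_freqs Named list (per gene) of named per-cohort mutation
#'   probabilities.
#' @param caller_overlap Fraction of true variants reported by both
#'   pseudo-callers; the remainder splits evenly between caller-A-only and
#'   caller-B-only calls.
#' @param contamination_rate Expected contaminating (germline-leakage /
#'   artifact / low-quality) variants as a fraction of the true burden.
#' @param exome_mb Exome size used to convert mutations/Mb to counts.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_primary_luad = 5L,
                        n_transformed = 10L,
                        n_denovo = 18L,
                        mean_tmb = c(primary_luad = 3, transformed = 4,
                                     denovo = 8),
                        upd_arm_rate = c(primary_luad = 0.03,
                                         transformed = 0.15,
                                         denovo = 0.05),
                        loss_arm_rate = c(primary_luad = 0.08,
                                          transformed = 0.20,
                                          denovo = 0.15),
                        gain_arm_rate = c(primary_luad = 0.05,
                                          transformed = 0.08,
                                          denovo = 0.10),
                        signature_mix = list(
                          primary_luad = c(SBS1 = 0.5, SBS5 = 0.5),
                          transformed = c(SBS1 = 0.6, SBS5 = 0.4),
                          denovo = c(SBS1 = 0.3, SBS4 = 0.4, SBS5 = 0.3)
                        ),
                        driver_freqs = list(
                          EGFR = c(primary_luad = 1, transformed = 1,
                                   denovo = 0.17),
                          TP53 = c(primary_luad = 0.60, transformed = 0.70,
                                   denovo = 0.89),
                          RB1 = c(primary_luad = 0.40, transformed = 0.30,
                                  denovo = 0.50)
                        ),
                        caller_overlap = 0.85,
                        contamination_rate = 0.25,
                        exome_mb = 38,
                        seed = 1L) {
  spec <- structure(
    list(n_primary_luad = n_primary_luad, n_transformed = n_transformed,
         n_denovo = n_denovo, mean_tmb = mean_tmb,
         upd_arm_rate = upd_arm_rate, loss_arm_rate = loss_arm_rate,
         gain_arm_rate = gain_arm_rate, signature_mix = signature_mix,
         driver_freqs = driver_freqs, caller_overlap = caller_overlap,
         contamination_rate = contamination_rate, exome_mb = exome_mb,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  sizes <- c(spec$n_primary_luad, spec$n_transformed, spec$n_denovo)
  if (any(sizes <= 0) || any(sizes != round(sizes))) {
    abort("cohort sizes must be positive integers")
  }
  prob_fields <- c("upd_arm_rate", "loss_arm_rate", "gain_arm_rate")
  for (f in prob_fields) {
    v <- spec[[f]][cohort_levels]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      abort(paste0(f, " must give a probability in [0,1] for every cohort"))
    }
  }
  total_event <- sapply(cohort_levels, function(g) {
    spec$upd_arm_rate[[g]] + spec$loss_arm_rate[[g]] + spec$gain_arm_rate[[g]]
  })
  if (any(total_event > 1)) {
    abort("per-arm event probabilities must sum to at most 1 per cohort")
  }
  for (g in cohort_levels) {
    mix <- spec$signature_mix[[g]]
    if (is.null(mix) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-8) {
      abort(paste0("signature_mix for ", g,
                   " must be non-negative weights summing to 1"))
    }
  }
  for (gene in names(spec$driver_freqs)) {
    v <- spec$driver_freqs[[gene]][cohort_levels]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      abort(paste0("driver_freqs for ", gene,
                   " must give probabilities in [0,1] for every cohort"))
    }
  }
  if (any(spec$mean_tmb[cohort_levels] <= 0) ||
      any(is.na(spec$mean_tmb[cohort_levels]))) {
    abort("mean_tmb must be positive for every cohort")
  }
  if (spec$caller_overlap < 0 || spec$caller_overlap > 1) {
    abort("caller_overlap must be in [0,1]")
  }
  spec
}

# context bookkeeping: parse the 96 labels once
context_parts <- function() {
  ctx <- sbs_contexts()
  tibble::tibble(
    label = ctx,
    ref = substr(ctx, 3, 3),
    alt = substr(ctx, 5, 5),
    trinuc = paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 7, 7))
  )
}

sample_contexts <- function(n, mix, sigs) {
  if (n == 0) return(integer(0))
  sig_ids <- sample(names(mix), n, replace = TRUE, prob = mix)
  idx <- integer(n)
  for (s in unique(sig_ids)) {
    which_s <- sig_ids == s
    idx[which_s] <- sample.int(96, sum(which_s), replace = TRUE,
                               prob = sigs[, s])
  }
  idx
}

draw_true_variants <- function(clinical, spec, sigs, genes) {
  info <- hg19_chrom_info()
  parts <- context_parts()
  groups <- clinical$cohort
  lambda <- spec$mean_tmb[groups] * spec$exome_mb
  n_nonsyn <- rpois(nrow(clinical), lambda)
  n_syn <- rpois(nrow(clinical), 0.2 * lambda)
  n_all <- n_nonsyn + n_syn
  v <- tibble::tibble(
    sample = rep(clinical$sample, n_all),
    cohort = rep(groups, n_all),
    effect = unlist(purrr::map2(n_nonsyn, n_syn, function(a, b) {
      c(sample(c("missense", "nonsense"), a, replace = TRUE,
               prob = c(0.9, 0.1)),
        rep("synonymous", b))
    }))
  )
  n <- nrow(v)
  ci <- sample.int(nrow(info), n, replace = TRUE,
                   prob = as.numeric(info$length))
  v$chrom <- info$chrom[ci]
  v$pos <- as.integer(ceiling(runif(n) * info$length[ci]))
  # ~8% of nonsynonymous variants are frameshift INDELs (no context)
  is_indel <- v$effect != "synonymous" & runif(n) < 0.08
  v$class <- ifelse(is_indel, "INDEL", "SNV")
  v$effect[is_indel] <- "frameshift"
  ctx_idx <- integer(n)
  for (g in cohort_levels) {
    rows <- which(v$cohort == g)
    ctx_idx[rows] <- sample_contexts(length(rows), spec$signature_mix[[g]],
                                     sigs)
  }
  flip <- runif(n) < 0.5
  v$ref <- ifelse(flip, chartr("ACGT", "TGCA", parts$ref[ctx_idx]),
                  parts$ref[ctx_idx])
  v$alt <- ifelse(flip, chartr("ACGT", "TGCA", parts$alt[ctx_idx]),
                  parts$alt[ctx_idx])
  v$context <- ifelse(flip, revcomp(parts$trinuc[ctx_idx]),
                      parts$trinuc[ctx_idx])
  ins <- is_indel & runif(n) < 0.5
  bases <- c("A", "C", "G", "T")
  v$ref[is_indel & !ins] <- paste0(v$ref[is_indel & !ins],
                                   sample(bases, sum(is_indel & !ins),
                                          replace = TRUE))
  v$alt[is_indel & !ins] <- substr(v$ref[is_indel & !ins], 1, 1)
  v$alt[ins] <- paste0(v$ref[ins], sample(bases, sum(ins), replace = TRUE))
  v$context[is_indel] <- NA_character_
  v$gene <- NA_character_

  # planted driver mutations (always SNVs inside the gene body)
  drv <- tidyr::expand_grid(gene = names(spec$driver_freqs),
                            sample = clinical$sample) |>
    dplyr::left_join(clinical |> dplyr::select("sample", "cohort"),
                     by = "sample") |>
    dplyr::left_join(genes, by = "gene")
  p_mut <- vapply(seq_len(nrow(drv)), function(i) {
    spec$driver_freqs[[drv$gene[i]]][[drv$cohort[i]]]
  }, numeric(1))
  drv <- drv[runif(nrow(drv)) < p_mut, , drop = FALSE]
  if (nrow(drv) > 0) {
    nd <- nrow(drv)
    ctx_idx <- integer(nd)
    for (g in cohort_levels) {
      rows <- which(drv$cohort == g)
      ctx_idx[rows] <- sample_contexts(length(rows),
                                       spec$signature_mix[[g]], sigs)
    }
    drv_v <- tibble::tibble(
      sample = drv$sample, cohort = drv$cohort,
      effect = ifelse(drv$gene == "EGFR", "missense",
                      sample(c("missense", "nonsense"), nd, replace = TRUE,
                             prob = c(0.6, 0.4))),
      chrom = drv$chrom,
      pos = as.integer(drv$start +
                         floor(runif(nd) * (drv$end - drv$start + 1))),
      class = "SNV",
      ref = context_parts()$ref[ctx_idx],
      alt = context_parts()$alt[ctx_idx],
      context = context_parts()$trinuc[ctx_idx],
      gene = drv$gene
    )
    v <- dplyr::bind_rows(v, drv_v)
  }
  # passenger gene assignment where a passenger lands in a panel gene
  hit <- v |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::filter(is.na(.data$gene)) |>
    dplyr::inner_join(
      genes |> dplyr::select(panel_gene = "gene", "chrom",
                             g_start = "start", g_end = "end"),
      by = dplyr::join_by("chrom", "pos" >= "g_start", "pos" <= "g_end")
    )
  v$gene[hit$.row] <- hit$panel_gene
  v$gene[is.na(v$gene)] <- paste0("GENE_", v$chrom[is.na(v$gene)], "_",
                                  v$pos[is.na(v$gene)] %/% 1000000L)
  v
}

add_evidence <- function(v, spec) {
  n <- nrow(v)
  p_cut <- ifelse(v$class == "INDEL", 0.05, 0.1)
  pass_p <- runif(n) < 0.9
  v$somatic_p <- round(ifelse(pass_p, runif(n) * p_cut,
                              p_cut + runif(n) * (0.5 - p_cut)), 6)
  v$tumor_vaf <- round(0.02 + stats::rbeta(n, 4, 10) * 0.9, 6)
  v$normal_vaf <- 0
  v$normal_alt_reads <- ifelse(runif(n) < 0.8, 0L, 1L)
  v$af_1kg <- round(ifelse(runif(n) < 0.1, runif(n) * 0.005, 0), 6)
  v$af_exac <- 0
  v$af_esp <- 0
  v$af_gnomad <- 0
  v$sift <- sample(c("damaged", "tolerated"), n, replace = TRUE,
                   prob = c(0.4, 0.6))
  v$polyphen <- sample(c("damaged", "benign"), n, replace = TRUE,
                       prob = c(0.4, 0.6))
  v$truncating <- v$effect %in% c("nonsense", "frameshift")
  # caller membership; caller-B-only calls get VAFs straddling the 5% rule
  u <- runif(n)
  solo_share <- (1 - spec$caller_overlap) / 2
  v$caller_set <- dplyr::case_when(
    u < spec$caller_overlap ~ "both",
    u < spec$caller_overlap + solo_share ~ "A",
    TRUE ~ "B"
  )
  b_only <- v$caller_set == "B"
  v$tumor_vaf[b_only] <- round(runif(sum(b_only), 0.02, 0.08), 6)
  # planted drivers are clonal events: high VAF, confidently called by both
  # callers, so the planted per-group frequencies survive the filter
  drv <- v$gene %in% names(spec$driver_freqs)
  v$somatic_p[drv] <- round(runif(sum(drv)) * 0.04, 6)
  v$tumor_vaf[drv] <- round(runif(sum(drv), 0.15, 0.5), 6)
  v$caller_set[drv] <- "both"
  v
}

draw_contamination <- function(clinical, spec) {
  lambda <- spec$contamination_rate * spec$mean_tmb[clinical$cohort] *
    spec$exome_mb
  n_per <- rpois(nrow(clinical), lambda)
  n <- sum(n_per)
  info <- hg19_chrom_info()
  ci <- sample.int(nrow(info), n, replace = TRUE,
                   prob = as.numeric(info$length))
  parts <- context_parts()
  ctx_idx <- sample.int(96, n, replace = TRUE)
  v <- tibble::tibble(
    sample = rep(clinical$sample, n_per),
    cohort = rep(clinical$cohort, n_per),
    effect = "missense",
    chrom = info$chrom[ci],
    pos = as.integer(ceiling(runif(n) * info$length[ci])),
    class = "SNV",
    ref = parts$ref[ctx_idx],
    alt = parts$alt[ctx_idx],
    context = parts$trinuc[ctx_idx],
    gene = paste0("GENE_", info$chrom[ci], "_", 1L),
    somatic_p = round(runif(n) * 0.08, 6),
    tumor_vaf = round(0.05 + runif(n) * 0.3, 6),
    normal_vaf = 0,
    normal_alt_reads = 0L,
    af_1kg = 0, af_exac = 0, af_esp = 0, af_gnomad = 0,
    sift = "tolerated", polyphen = "benign", truncating = FALSE,
    caller_set = "both"
  )
  mode <- sample(c("germline", "popfreq", "low_quality", "low_vaf"), n,
                 replace = TRUE)
  gl <- mode == "germline"
  v$normal_vaf[gl] <- round(runif(sum(gl), 0.2, 0.5), 6)
  v$normal_alt_reads[gl] <- 5L + rpois(sum(gl), 15)
  pf <- mode == "popfreq"
  common <- round(runif(sum(pf), 0.02, 0.2), 6)
  v$af_1kg[pf] <- common
  v$af_exac[pf] <- common
  v$af_esp[pf] <- common
  v$af_gnomad[pf] <- common
  lq <- mode == "low_quality"
  v$somatic_p[lq] <- round(0.12 + runif(sum(lq)) * 0.4, 6)
  lv <- mode == "low_vaf"
  v$tumor_vaf[lv] <- round(runif(sum(lv), 0.002, 0.019), 6)
  v
}

generate_segments <- function(clinical, spec) {
  arms <- hg19_arms()
  grid <- tidyr::expand_grid(
    clinical |> dplyr::select("sample", "cohort"),
    arms |> dplyr::select("chrom", "arm", "start", "end")
  )
  n <- nrow(grid)
  p_upd <- spec$upd_arm_rate[grid$cohort]
  p_loss <- spec$loss_arm_rate[grid$cohort]
  p_gain <- spec$gain_arm_rate[grid$cohort]
  u <- runif(n)
  state <- dplyr::case_when(
    u < p_upd ~ "upd",
    u < p_upd + p_loss ~ "loss",
    u < p_upd + p_loss + p_gain ~ "gain",
    TRUE ~ "neutral"
  )
  arm_len <- grid$end - grid$start + 1
  f <- ifelse(runif(n) < 0.6, 1, runif(n, 0.6, 1))
  ev_len <- ifelse(state == "neutral", 0L, pmax(2L, round(f * arm_len)))
  # events are anchored at the telomeric end of the arm
  ev_start <- ifelse(grid$arm == "p", grid$start, grid$end - ev_len + 1)
  ev_end <- ifelse(grid$arm == "p", grid$start + ev_len - 1, grid$end)
  split <- state != "neutral" & ev_len >= 2 & runif(n) < 0.3
  brk <- ev_start + pmax(0L, floor(runif(n) * (ev_len - 1)))
  cn <- list(upd = c(2L, 0L), loss = c(1L, 0L), gain = c(3L, 1L),
             neutral = c(2L, 1L))
  nt <- unname(vapply(state, function(s) cn[[s]][1], integer(1)))
  nm <- unname(vapply(state, function(s) cn[[s]][2], integer(1)))
  ev <- state != "neutral"
  piece <- function(sel, s, e, total, minor) {
    tibble::tibble(sample = grid$sample[sel], chrom = grid$chrom[sel],
                   start = as.integer(s[sel]), end = as.integer(e[sel]),
                   n_total = total[sel], n_minor = minor[sel])
  }
  p1 <- piece(ev, ev_start, ifelse(split, brk, ev_end), nt, nm)
  p2 <- piece(ev & split, brk + 1, ev_end, nt, nm)
  # neutral remainder on the centromeric side of a partial event
  rem_sel <- ev & ev_len < arm_len
  rem_s <- ifelse(grid$arm == "p", ev_end + 1, grid$start)
  rem_e <- ifelse(grid$arm == "p", grid$end, ev_start - 1)
  p3 <- piece(rem_sel, rem_s, rem_e, rep(2L, n), rep(1L, n))
  p4 <- piece(!ev, grid$start, grid$end, nt, nm)
  dplyr::bind_rows(p1, p2, p3, p4) |>
    dplyr::arrange(.data$sample, match(.data$chrom,
                                       hg19_chrom_info()$chrom),
                   .data$start)
}

#' Generate a synthetic three-cohort study
#'
#' Draws a full synthetic whole-exome downstream dataset from a
#' [cohort_spec()]: clinical metadata, per-sample variant calls from two
#' pseudo-callers (true somatic variants plus a contamination class the
#' consensus filter removes), arm-tiled allele-specific copy-number
#' segments with telomere-anchored UPD/loss/gain events, and 96-context
#' mutation spectra consistent with the per-cohort signature mixes. All
#' randomness flows from `spec$seed`; the same spec reproduces the same
#' cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param sigs Signature matrix used to draw trinucleotide contexts;
#'   defaults to the bundled demonstration matrix. Every signature named in
#'   `spec$signature_mix` must be a column.
#' @param genes Gene model used to place planted driver mutations.
#' @return A list of class `sclc_cohort` with tibbles `clinical` (`sample`,
#'   `cohort`, `sex`, `age`, `smoker`), `variants` (per-caller call records,
#'   `caller` in `"A"`/`"B"`), `segments`, `spectra` (long 96-context
#'   counts), and the originating `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort$clinical, cohort)
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            sigs = toy_signature_matrix(),
                            genes = demo_genes()) {
  validate_cohort_spec(spec)
  for (g in cohort_levels) {
    missing <- setdiff(names(spec$signature_mix[[g]]), colnames(sigs))
    if (length(missing) > 0) {
      abort(paste0("signature_mix names not in the signature matrix: ",
                   paste(missing, collapse = ", ")))
    }
  }
  set.seed(spec$seed)
  clinical <- tibble::tibble(
    sample = c(sprintf("LUAD%02d", seq_len(spec$n_primary_luad)),
               sprintf("TRSCLC%02d", seq_len(spec$n_transformed)),
               sprintf("DNSCLC%02d", seq_len(spec$n_denovo))),
    cohort = rep(cohort_levels,
                 c(spec$n_primary_luad, spec$n_transformed, spec$n_denovo))
  )
  n <- nrow(clinical)
  p_female <- c(primary_luad = 0.8, transformed = 0.8, denovo = 0.15)
  p_smoker <- c(primary_luad = 0.17, transformed = 0.17, denovo = 0.85)
  clinical$sex <- ifelse(runif(n) < unname(p_female[clinical$cohort]),
                         "female", "male")
  clinical$age <- as.integer(round(rnorm(n, mean = 62, sd = 8)))
  clinical$smoker <- runif(n) < unname(p_smoker[clinical$cohort])

  true_v <- add_evidence(draw_true_variants(clinical, spec, sigs, genes),
                         spec)
  cont_v <- draw_contamination(clinical, spec)
  all_v <- dplyr::bind_rows(
    dplyr::mutate(true_v, true_somatic = TRUE),
    dplyr::mutate(cont_v, true_somatic = FALSE)
  )
  in_a <- all_v$caller_set %in% c("both", "A")
  in_b <- all_v$caller_set %in% c("both", "B")
  variants <- dplyr::bind_rows(
    dplyr::mutate(all_v[in_a, ], caller = "A"),
    dplyr::mutate(all_v[in_b, ], caller = "B")
  ) |>
    dplyr::select(dplyr::all_of(variant_columns), "true_somatic") |>
    dplyr::arrange(.data$sample, .data$caller, .data$chrom, .data$pos,
                   .data$alt)
  spectra <- build_spectra(
    true_v |> dplyr::filter(.data$class == "SNV")
  )
  spectra <- tidyr::complete(
    spectra, sample = clinical$sample, context = sbs_contexts(),
    fill = list(count = 0L)
  ) |>
    dplyr::arrange(match(.data$sample, clinical$sample),
                   match(.data$context, sbs_contexts()))
  segments <- generate_segments(clinical, spec)
  structure(
    list(clinical = clinical, variants = variants, segments = segments,
         spectra = spectra, spec = spec),
    class = "sclc_cohort"
  )
}

#' @export
print.sclc_cohort <- function(x, ...) {
  sizes <- dplyr::count(x$clinical, .data$cohort)
  cat("Synthetic SCLC study cohort:",
      paste(sizes$n, sizes$cohort, collapse = ", "), "\n")
  cat(" ", nrow(x$variants), "caller variant records,",
      nrow(x$segments), "segments, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Write / read a cohort fixture on disk
#'
#' `write_fixture()` serialises a generated cohort to plain-text files that
#' round-trip losslessly through the package readers: per-sample per-caller
#' VCFs (or caller TSVs), a SEG-like segment table, a long spectra TSV and
#' a clinical TSV. `read_fixture()` reads them back.
#'
#' @param cohort An `sclc_cohort` from [generate_cohort()].
#' @param out_dir Output directory, created if needed.
#' @param format `"vcf"` (default) or `"tsv"` for the variant files.
#' @return `write_fixture()` returns `out_dir` invisibly; `read_fixture()`
#'   returns a list with `clinical`, `variants`, `segments`, `spectra`.
#' @export
write_fixture <- function(cohort, out_dir, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!inherits(cohort, "sclc_cohort") || nrow(cohort$clinical) == 0) {
    abort("cohort must be a non-empty sclc_cohort")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  readr::write_tsv(cohort$clinical, file.path(out_dir, "clinical.tsv"),
                   progress = FALSE)
  write_seg(cohort$segments, file.path(out_dir, "segments.seg"))
  write_spectra(cohort$spectra, file.path(out_dir, "spectra.tsv"))
  for (id in cohort$clinical$sample) {
    for (cl in c("A", "B")) {
      v <- dplyr::filter(cohort$variants, .data$sample == id,
                         .data$caller == cl)
      path <- file.path(out_dir,
                        paste0(id, ".caller_", cl, ".", format))
      if (format == "vcf") write_caller_vcf(v, path)
      else write_caller_tsv(dplyr::select(v, -"true_somatic"), path)
    }
  }
  invisible(out_dir)
}

#' @rdname write_fixture
#' @param dir Directory written by [write_fixture()].
#' @export
read_fixture <- function(dir) {
  clinical <- readr::read_tsv(file.path(dir, "clinical.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  if ("age" %in% names(clinical)) clinical$age <- as.integer(clinical$age)
  segments <- read_seg(file.path(dir, "segments.seg"))
  spectra <- read_spectra(file.path(dir, "spectra.tsv"))
  variants <- purrr::map_dfr(clinical$sample, function(id) {
    purrr::map_dfr(c("A", "B"), function(cl) {
      stem <- file.path(dir, paste0(id, ".caller_", cl))
      path <- if (file.exists(paste0(stem, ".vcf"))) {
        paste0(stem, ".vcf")
      } else {
        paste0(stem, ".tsv")
      }
      read_caller_variants(path, cl, sample_id = id)
    })
  })
  list(clinical = clinical, variants = variants, segments = segments,
       spectra = spectra)
}
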