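# Event 1 / Event 2 integration and pathway CNV summaries.

genes <- demo_genes()
arms <- hg19_arms()

tp53 <- genes[genes$gene == "TP53", ]

test_that("gene-level Event 2 follows the overlap threshold with UPD priority", {
  genome <- neutral_genome()
  upd <- patch_genome(genome, "chr17", tp53$start - 1e6, tp53$end + 1e6,
                      2, 0)
  ev <- gene_event2(upd, genes)
  expect_equal(ev$event2[ev$gene == "TP53"], "upd")
  expect_equal(ev$event2[ev$gene == "BRCA1"], "none")

  neutral_ev <- gene_event2(genome, genes)
  expect_true(all(neutral_ev$event2 == "none"))

  # 70% loss / 30% neutral split calls loss
  cut <- tp53$start + floor(0.7 * (tp53$end - tp53$start + 1)) - 1
  split <- patch_genome(genome, "chr17", tp53$start - 1e6, cut, 1, 0)
  ev2 <- gene_event2(split, genes)
  expect_equal(ev2$event2[ev2$gene == "TP53"], "loss")
  # ... but not at a 0.8 threshold (monotone shrinkage)
  ev3 <- gene_event2(split, genes, min_overlap_fraction = 0.8)
  expect_equal(ev3$event2[ev3$gene == "TP53"], "none")
})

test_that("raising the overlap threshold never creates new events", {
  segs <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(random_profile(i + 40,
                                 chroms = c("chr13", "chr17", "chr7")),
                  sample = paste0("S", i))
  }))
  # only three chromosomes are covered; the coverage warning is expected
  loose <- suppressWarnings(gene_event2(segs, genes,
                                        min_overlap_fraction = 0.3))
  strict <- suppressWarnings(gene_event2(segs, genes,
                                         min_overlap_fraction = 0.7))
  merged <- dplyr::inner_join(loose, strict, by = c("sample", "gene"),
                              suffix = c("_loose", "_strict"))
  expect_true(all(merged$event2_strict == "none" |
                    merged$event2_loose != "none"))
})

test_that("double hits need both a mutation and a CN second hit", {
  genome <- neutral_genome()
  upd <- patch_genome(genome, "chr17", tp53$start - 1e6, tp53$end + 1e6,
                      2, 0)
  muts <- tibble::tibble(sample = "S1", gene = c("TP53", "BRCA2"),
                         effect = c("missense", "missense"))
  dh <- double_hit_table(muts, upd, genes)
  tp53_row <- dh[dh$gene == "TP53", ]
  expect_true(tp53_row$double_hit)
  expect_equal(tp53_row$event2, "upd")
  brca2_row <- dh[dh$gene == "BRCA2", ]
  expect_true(brca2_row$event1)
  expect_false(brca2_row$double_hit)
  # unknown symbols are skipped with a warning
  expect_warning(
    double_hit_table(dplyr::mutate(muts, gene = c("TP53", "NOSUCH")),
                     upd, genes),
    "NOSUCH"
  )
})

test_that("double-hit table equals a brute-force per-sample evaluation", {
  set.seed(77)
  n_samples <- 8
  segs <- dplyr::bind_rows(lapply(seq_len(n_samples), function(i) {
    dplyr::mutate(random_profile(i + 60,
                                 chroms = unique(genes$chrom)),
                  sample = sprintf("S%02d", i))
  }))
  muts <- tibble::tibble(
    sample = sprintf("S%02d", sample.int(n_samples, 30, replace = TRUE)),
    gene = sample(genes$gene, 30, replace = TRUE),
    effect = "missense"
  )
  got <- double_hit_table(muts, segs, genes)
  # naive loop
  cls <- function(nt, nm) {
    if (nt == 2 && nm == 0) "upd" else if (nt < 2) "loss"
    else if (nt > 2) "gain" else "neutral"
  }
  for (i in seq_len(nrow(got))) {
    row <- got[i, ]
    g <- genes[genes$gene == row$gene, ]
    s <- segs[segs$sample == row$sample & segs$chrom == g$chrom, ]
    bp <- c(upd = 0, loss = 0)
    for (j in seq_len(nrow(s))) {
      ov <- min(s$end[j], g$end) - max(s$start[j], g$start) + 1
      if (ov > 0) {
        st <- cls(s$n_total[j], s$n_minor[j])
        if (st %in% names(bp)) bp[st] <- bp[st] + ov
      }
    }
    frac <- bp / (g$end - g$start + 1)
    want_ev2 <- if (frac["upd"] >= 0.5) "upd" else if (frac["loss"] >= 0.5) {
      "loss"
    } else "none"
    want_ev1 <- any(muts$sample == row$sample & muts$gene == row$gene)
    expect_equal(row$event2, want_ev2,
                 info = paste(row$sample, row$gene))
    expect_equal(row$event1, want_ev1)
    expect_equal(row$double_hit, want_ev1 && want_ev2 != "none")
  }
})

test_that("double-hit tables ignore mutation input order", {
  segs <- dplyr::mutate(random_profile(91, chroms = unique(genes$chrom)),
                        sample = "S1")
  muts <- tibble::tibble(sample = "S1",
                         gene = c("TP53", "RB1", "EGFR", "BRCA1"),
                         effect = "missense")
  expect_equal(double_hit_table(muts, segs, genes),
               double_hit_table(muts[c(3, 1, 4, 2), ], segs, genes))
})

test_that("cohort double-hit rates divide by mutated samples only", {
  records <- tibble::tibble(
    sample = c("T1", "T2", "T3", "D1"),
    gene = "TP53",
    event1 = c(TRUE, TRUE, FALSE, FALSE),
    mutation_class = c("missense", "missense", NA, NA),
    event2 = c("upd", "none", "loss", "loss"),
    double_hit = c(TRUE, FALSE, FALSE, FALSE)
  )
  clinical <- tibble::tibble(sample = c("T1", "T2", "T3", "D1"),
                             cohort = c("transformed", "transformed",
                                        "transformed", "denovo"))
  rates <- cohort_double_hit_rate(records, "TP53", clinical)
  expect_equal(rates$rate[rates$cohort == "transformed"], 0.5)
  expect_equal(rates$n_mutated[rates$cohort == "denovo"], 0L)
  expect_true(is.na(rates$rate[rates$cohort == "denovo"]))
})

test_that("pathway counts partition the gene set", {
  genome <- neutral_genome()
  sets <- pathway_gene_sets()
  all_neutral <- pathway_cnv_summary(genome, genes, sets)
  neutral_counts <- all_neutral |>
    dplyr::filter(state == "neutral")
  expect_equal(neutral_counts$n_genes,
               unname(lengths(sets)[neutral_counts$pathway]))
  # an UPD arm containing HRR genes shifts them into the upd column
  q17 <- arms[arms$arm_id == "17q", ]
  upd <- patch_genome(genome, "chr17", q17$start, q17$end, 2, 0)
  upd_counts <- pathway_cnv_summary(upd, genes, sets)
  hrr_upd <- upd_counts |>
    dplyr::filter(pathway == "HRR", state == "upd")
  expect_equal(hrr_upd$n_genes, 1L) # BRCA1 sits on 17q
  totals <- upd_counts |>
    dplyr::group_by(pathway) |>
    dplyr::summarise(n = sum(n_genes))
  expect_equal(totals$n, unname(lengths(sets)[totals$pathway]))
  expect_error(pathway_cnv_summary(genome, genes, list(empty = character(0))),
               "non-empty")
})
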