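# Random-input builders shared across tests. All take an explicit seed so
# property-style loops are reproducible.

# Random caller variant tables whose fields straddle every filter threshold.
random_caller_pair <- function(n, seed) {
  set.seed(seed)
  base <- tibble::tibble(
    sample = "S1",
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    pos = sample.int(5e7, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("AA", "CC", "GG", "TT"), n, replace = TRUE),
    class = sample(c("SNV", "INDEL"), n, replace = TRUE, prob = c(0.8, 0.2)),
    somatic_p = round(runif(n, 0, 0.2), 4),
    tumor_vaf = round(runif(n, 0, 0.12), 4),
    normal_vaf = ifelse(runif(n) < 0.2, NA, round(runif(n, 0, 0.03), 4)),
    normal_alt_reads = ifelse(runif(n) < 0.2, NA,
                              sample(0:7, n, replace = TRUE)),
    af_1kg = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.03), 4)),
    af_exac = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.03), 4)),
    af_esp = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.03), 4)),
    af_gnomad = NA_real_,
    gene = paste0("G", seq_len(n)),
    effect = "missense",
    sift = NA_character_,
    polyphen = NA_character_,
    truncating = NA,
    context = NA_character_,
    membership = sample(c("both", "A", "B"), n, replace = TRUE,
                        prob = c(0.7, 0.15, 0.15))
  )
  # exact boundary values are planted on purpose
  boundary_rows <- sample.int(n, min(n, 20))
  base$somatic_p[boundary_rows] <-
    sample(c(0.05, 0.1), length(boundary_rows), replace = TRUE)
  base$tumor_vaf[boundary_rows] <-
    sample(c(0.02, 0.05), length(boundary_rows), replace = TRUE)
  a <- base[base$membership %in% c("both", "A"), ]
  b <- base[base$membership %in% c("both", "B"), ]
  # caller B carries slightly different evidence on shared variants
  b$somatic_p <- ifelse(runif(nrow(b)) < 0.5, b$somatic_p,
                        round(runif(nrow(b), 0, 0.2), 4))
  a$caller <- "A"
  b$caller <- "B"
  list(a = dplyr::select(a, -"membership"),
       b = dplyr::select(b, -"membership"))
}

random_repeats <- function(seed, n = 30) {
  set.seed(seed)
  tibble::tibble(
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    start = sample.int(5e7, n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + sample.int(2e6, n, replace = TRUE))
}

# Random segment profile on a few chromosomes: contiguous tilings with
# random allele-specific copy numbers (including UPD and LOH states).
random_profile <- function(seed, chroms = c("chr1", "chr5", "chr13", "chr17"),
                           max_segs = 6) {
  set.seed(seed)
  arms <- hg19_arms()
  rows <- lapply(chroms, function(ch) {
    len <- max(arms$end[arms$chrom == ch])
    k <- sample.int(max_segs, 1)
    cuts <- sort(sample.int(len - 1, k - 1))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    nt <- sample(0:4, k, replace = TRUE,
                 prob = c(0.05, 0.2, 0.4, 0.25, 0.1))
    nm <- vapply(nt, function(t) sample(0:(t %/% 2), 1), integer(1))
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   n_total = nt, n_minor = nm)
  })
  dplyr::bind_rows(rows)
}

# Split every segment longer than 1 bp into two adjacent same-state halves.
split_segments <- function(segs) {
  long <- segs[segs$end > segs$start, ]
  short <- segs[segs$end <= segs$start, ]
  mid <- (long$start + long$end) %/% 2
  dplyr::bind_rows(
    short,
    dplyr::mutate(long, end = mid),
    dplyr::mutate(long, start = mid + 1L)
  ) |>
    dplyr::arrange(chrom, start)
}

# A neutral diploid genome tiled over every arm, used as a background into
# which toy events are patched.
neutral_genome <- function(sample_id = "S1") {
  hg19_arms() |>
    dplyr::transmute(sample = sample_id, chrom = chrom,
                     start = start, end = end,
                     n_total = 2L, n_minor = 1L)
}

# Replace the part of a neutral genome overlapping [start, end] on chrom
# with the given state, keeping the tiling contiguous.
patch_genome <- function(genome, p_chrom, p_start, p_end, n_total, n_minor) {
  hit <- genome$chrom == p_chrom & genome$start <= p_end &
    genome$end >= p_start
  keep <- genome[!hit, ]
  pieces <- list()
  for (i in which(hit)) {
    g <- genome[i, ]
    if (g$start < p_start) {
      left <- g
      left$end <- as.integer(p_start - 1)
      pieces[[length(pieces) + 1]] <- left
    }
    mid <- g
    mid$start <- as.integer(max(g$start, p_start))
    mid$end <- as.integer(min(g$end, p_end))
    mid$n_total <- as.integer(n_total)
    mid$n_minor <- as.integer(n_minor)
    pieces[[length(pieces) + 1]] <- mid
    if (g$end > p_end) {
      right <- g
      right$start <- as.integer(p_end + 1)
      pieces[[length(pieces) + 1]] <- right
    }
  }
  dplyr::bind_rows(keep, dplyr::bind_rows(pieces)) |>
    dplyr::arrange(chrom, start)
}
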