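# Bundled hg19 genome model: chromosome-arm table, a compact gene panel and
# the pathway gene sets used for the DDR/Notch/stem-cell CNV summaries.

# UCSC hg19 chromosome lengths and acen (centromere) boundaries, autosomes only.
hg19_chrom_info <- function() {
  tibble::tribble(
    ~chrom, ~length,    ~cen_start, ~cen_end,
    "chr1",  249250621L, 121535434L, 124535434L,
    "chr2",  243199373L,  92326171L,  95326171L,
    "chr3",  198022430L,  90504854L,  93504854L,
    "chr4",  191154276L,  49660117L,  52660117L,
    "chr5",  180915260L,  46405641L,  49405641L,
    "chr6",  171115067L,  58830166L,  61830166L,
    "chr7",  159138663L,  58054331L,  61054331L,
    "chr8",  146364022L,  43838887L,  46838887L,
    "chr9",  141213431L,  47367679L,  50367679L,
    "chr10", 135534747L,  39254935L,  42254935L,
    "chr11", 135006516L,  51644205L,  54644205L,
    "chr12", 133851895L,  34856694L,  37856694L,
    "chr13", 115169878L,  16000000L,  19000000L,
    "chr14", 107349540L,  16000000L,  19000000L,
    "chr15", 102531392L,  17000000L,  20000000L,
    "chr16",  90354753L,  35335801L,  38335801L,
    "chr17",  81195210L,  22263006L,  25263006L,
    "chr18",  78077248L,  15460898L,  18460898L,
    "chr19",  59128983L,  24681782L,  27681782L,
    "chr20",  63025520L,  26369569L,  29369569L,
    "chr21",  48129895L,  11288129L,  14288129L,
    "chr22",  51304566L,  13000000L,  16000000L
  )
}

# Short (heterochromatic) p arms that carry no exome probes and are excluded
# from arm-level analysis, leaving 39 analysable autosomal arms.
acrocentric_chroms <- c("chr13", "chr14", "chr15", "chr21", "chr22")

#' Autosomal chromosome-arm table (hg19)
#'
#' Arm coordinates for the 22 autosomes, derived from the UCSC hg19 cytoband
#' centromere (acen) boundaries. The heterochromatic p arms of the acrocentric
#' chromosomes (13, 14, 15, 21, 22) are excluded, giving the 39 arms used for
#' arm-level copy-number analysis. Telomeric ends are the arm boundaries that
#' coincide with a chromosome end: `start` of a p arm and `end` of a q arm.
#'
#' @return A tibble with one row per arm: `chrom`, `arm` (`"p"`/`"q"`),
#'   `arm_id` (e.g. `"17p"`), `start`, `end` (1-based inclusive bp),
#'   `cen_start`, `cen_end` (centromere interval of the chromosome), and
#'   `chrom_length`.
#' @examples
#' hg19_arms()
#' @export
hg19_arms <- function() {
  info <- hg19_chrom_info()
  p <- info |>
    dplyr::filter(!.data$chrom %in% acrocentric_chroms) |>
    dplyr::mutate(arm = "p", start = 1L, end = .data$cen_start - 1L)
  q <- info |>
    dplyr::mutate(arm = "q", start = .data$cen_end + 1L, end = .data$length)
  dplyr::bind_rows(p, q) |>
    dplyr::mutate(
      arm_id = paste0(sub("^chr", "", .data$chrom), .data$arm),
      chrom_length = .data$length
    ) |>
    dplyr::select("chrom", "arm", "arm_id", "start", "end",
                  "cen_start", "cen_end", "chrom_length") |>
    dplyr::arrange(match(.data$chrom, info$chrom), .data$arm)
}

#' Compact hg19 gene panel for double-hit and pathway analysis
#'
#' Approximate hg19 coordinates for a small panel of lung-cancer drivers
#' (EGFR, TP53, RB1), recurrently second-hit genes in small cell
#' transformation (CLTCL1, LRIG3, PABPC1, PTCH1), DNA-damage-repair pathway
#' members, Notch pathway members and stem-cell/ADC targets. Intended for
#' demonstration and testing; supply your own gene BED for real analyses.
#'
#' @return A tibble with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
demo_genes <- function() {
  tibble::tribble(
    ~gene,     ~chrom,  ~start,      ~end,
    "EGFR",    "chr7",   55086725L,  55275031L,
    "TP53",    "chr17",   7571720L,   7590868L,
    "RB1",     "chr13",  48877883L,  49056122L,
    "CLTCL1",  "chr22",  19166986L,  19279239L,
    "LRIG3",   "chr12",  59266876L,  59314721L,
    "PABPC1",  "chr8",  101715992L, 101734925L,
    "PTCH1",   "chr9",   98205264L,  98279339L,
    "XRCC1",   "chr19",  44047192L,  44084625L,
    "ERCC2",   "chr19",  45854649L,  45873845L,
    "FANCA",   "chr16",  89803957L,  89883065L,
    "PALB2",   "chr16",  23614483L,  23652678L,
    "BRCA1",   "chr17",  41196312L,  41277500L,
    "BRCA2",   "chr13",  32889611L,  32973805L,
    "RAD51",   "chr15",  40987327L,  41024356L,
    "ATM",     "chr11", 108093559L, 108239826L,
    "PRKDC",   "chr8",   48685667L,  48872743L,
    "MLH1",    "chr3",   37034841L,  37092337L,
    "MSH2",    "chr2",   47630206L,  47710367L,
    "NOTCH1",  "chr9",  139388896L, 139440238L,
    "NOTCH2",  "chr1",  120454176L, 120612317L,
    "DLL3",    "chr19",  39989536L,  39999046L,
    "SOX2",    "chr3",  181429712L, 181432223L,
    "MYCL",    "chr1",   40361098L,  40367687L
  )
}

#' Pathway gene sets for CNV summaries
#'
#' Named gene sets for the six DNA-damage-repair pathways (base excision
#' repair, nucleotide excision repair, Fanconi anemia, homology-dependent
#' recombination repair, non-homologous end joining, mismatch repair) plus
#' Notch signalling and stem-cell/ADC-target genes, restricted to the bundled
#' demonstration panel. Every symbol resolves in [demo_genes()].
#'
#' @return A named list of character vectors of gene symbols.
#' @export
pathway_gene_sets <- function() {
  list(
    BER      = c("XRCC1"),
    NER      = c("ERCC2"),
    FA       = c("FANCA", "PALB2"),
    HRR      = c("BRCA1", "BRCA2", "RAD51", "ATM"),
    NHEJ     = c("PRKDC"),
    MMR      = c("MLH1", "MSH2"),
    Notch    = c("NOTCH1", "NOTCH2", "DLL3"),
    StemCell = c("SOX2", "MYCL", "DLL3")
  )
}

#' Read a BED file of genomic intervals
#'
#' Reads BED (0-based half-open) intervals and converts them to the package's
#' internal 1-based inclusive convention.
#'
#' @param path Path to a BED file (at least 3 columns; a 4th is kept as
#'   `name`).
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) abort("BED file must have at least 3 columns")
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}
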