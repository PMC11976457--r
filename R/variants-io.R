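# Reading and writing per-caller variant tables. Two interchange formats:
# VCF 4.2 with the evidence carried in INFO fields, and a flat caller TSV
# with the same columns. Internally a variant is always one row per ALT
# allele with 1-based coordinates.

variant_columns <- c(
  "sample", "caller", "chrom", "pos", "ref", "alt", "class",
  "somatic_p", "tumor_vaf", "normal_vaf", "normal_alt_reads",
  "af_1kg", "af_exac", "af_esp", "af_gnomad",
  "gene", "effect", "sift", "polyphen", "truncating", "context"
)

vcf_info_spec <- tibble::tribble(
  ~id,       ~column,            ~number, ~type,      ~desc,
  "SOMP",    "somatic_p",        "A",     "Float",    "Somatic p-value",
  "TVAF",    "tumor_vaf",        "A",     "Float",    "Tumor variant allele frequency",
  "NVAF",    "normal_vaf",       "A",     "Float",    "Normal variant allele frequency",
  "NAR",     "normal_alt_reads", "A",     "Integer",  "Normal alt-supporting reads",
  "AF1KG",   "af_1kg",           "A",     "Float",    "1000 Genomes allele frequency",
  "AFEXAC",  "af_exac",          "A",     "Float",    "ExAC allele frequency",
  "AFESP",   "af_esp",           "A",     "Float",    "ESP6500 allele frequency",
  "AFGNOM",  "af_gnomad",        "A",     "Float",    "gnomAD allele frequency",
  "GENE",    "gene",             "1",     "String",   "Gene symbol",
  "EFF",     "effect",           "1",     "String",   "Coding effect",
  "SIFT",    "sift",             "1",     "String",   "SIFT verdict",
  "PPH",     "polyphen",         "1",     "String",   "PolyPhen verdict",
  "TRUNC",   "truncating",       "1",     "String",   "Truncating mutation flag",
  "CTX",     "context",          "1",     "String",   "Pyrimidine-strand trinucleotide context",
  "CLASS",   "class",            "1",     "String",   "Variant class (SNV/INDEL)"
)

empty_variant_tbl <- function() {
  out <- tibble::tibble(
    sample = character(), caller = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    class = character(), somatic_p = double(), tumor_vaf = double(),
    normal_vaf = double(), normal_alt_reads = integer(),
    af_1kg = double(), af_exac = double(), af_esp = double(),
    af_gnomad = double(), gene = character(), effect = character(),
    sift = character(), polyphen = character(), truncating = logical(),
    context = character()
  )
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE,
                               drop0trailing = TRUE))
}
fmt_chr <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))

#' Write caller variants to a VCF 4.2 file
#'
#' Serialises a per-caller variant table for one sample to a plain-text VCF,
#' with the somatic evidence (somatic p-value, tumor/normal VAF, normal alt
#' reads), population frequencies and annotation carried in INFO fields.
#'
#' @param variants Variant tibble for a single sample and caller.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(variants, path) {
  if (length(unique(variants$sample)) > 1) {
    abort("write_caller_vcf() writes one sample per file")
  }
  info_lines <- sprintf(
    '##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
    vcf_info_spec$id, vcf_info_spec$number, vcf_info_spec$type,
    vcf_info_spec$desc
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sclcscars",
    info_lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$alt)
  info <- paste0(
    "SOMP=", fmt_num(v$somatic_p),
    ";TVAF=", fmt_num(v$tumor_vaf),
    ";NVAF=", fmt_num(v$normal_vaf),
    ";NAR=", fmt_num(v$normal_alt_reads),
    ";AF1KG=", fmt_num(v$af_1kg),
    ";AFEXAC=", fmt_num(v$af_exac),
    ";AFESP=", fmt_num(v$af_esp),
    ";AFGNOM=", fmt_num(v$af_gnomad),
    ";GENE=", fmt_chr(v$gene),
    ";EFF=", fmt_chr(v$effect),
    ";SIFT=", fmt_chr(v$sift),
    ";PPH=", fmt_chr(v$polyphen),
    ";TRUNC=", ifelse(is.na(v$truncating), ".",
                      ifelse(v$truncating, "1", "0")),
    ";CTX=", fmt_chr(v$context),
    ";CLASS=", fmt_chr(v$class)
  )
  body <- if (nrow(v) == 0) character(0) else {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

parse_vcf_variants <- function(path, caller_id, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    out <- empty_variant_tbl()
    return(out)
  }
  fix <- tibble::as_tibble(as.data.frame(vcf@fix,
                                         stringsAsFactors = FALSE))
  get_info <- function(id) as.character(vcfR::extract.info(vcf, element = id))
  for (i in seq_len(nrow(vcf_info_spec))) {
    fix[[vcf_info_spec$column[i]]] <- get_info(vcf_info_spec$id[i])
  }
  fix$row_id <- seq_len(nrow(fix))
  # split multi-allelic rows: per-ALT (Number=A) fields split positionally
  a_cols <- vcf_info_spec$column[vcf_info_spec$number == "A"]
  long <- fix |>
    dplyr::mutate(alt_list = strsplit(.data$ALT, ",", fixed = TRUE),
                  n_alt = lengths(.data$alt_list))
  bad <- long$n_alt == 0 | is.na(long$ALT)
  if (any(bad)) {
    abort(paste0("malformed VCF record (no ALT allele) in ", path,
                 " at data line ", which(bad)[1]))
  }
  for (col in a_cols) {
    parts <- stringr::str_split(long[[col]], stringr::fixed(","))
    ok <- lengths(parts) == long$n_alt | lengths(parts) == 1
    if (any(!ok)) {
      abort(paste0("malformed per-allele INFO field in ", path,
                   " at data line ", which(!ok)[1]))
    }
    long[[col]] <- purrr::map2(parts, long$n_alt,
                               function(p, n) rep_len(p, n))
  }
  long <- long |>
    tidyr::unnest(cols = dplyr::all_of(c("alt_list", a_cols))) |>
    dplyr::rename(alt = "alt_list")
  na_dot <- function(x) ifelse(x == "." | x == "", NA_character_, x)
  tibble::tibble(
    sample = sample_id,
    caller = caller_id,
    chrom = long$CHROM,
    pos = as.integer(long$POS),
    ref = long$REF,
    alt = long$alt,
    class = na_dot(long$class),
    somatic_p = as.numeric(na_dot(long$somatic_p)),
    tumor_vaf = as.numeric(na_dot(long$tumor_vaf)),
    normal_vaf = as.numeric(na_dot(long$normal_vaf)),
    normal_alt_reads = as.integer(na_dot(long$normal_alt_reads)),
    af_1kg = as.numeric(na_dot(long$af_1kg)),
    af_exac = as.numeric(na_dot(long$af_exac)),
    af_esp = as.numeric(na_dot(long$af_esp)),
    af_gnomad = as.numeric(na_dot(long$af_gnomad)),
    gene = na_dot(long$gene),
    effect = na_dot(long$effect),
    sift = na_dot(long$sift),
    polyphen = na_dot(long$polyphen),
    truncating = dplyr::case_when(
      long$truncating == "1" ~ TRUE,
      long$truncating == "0" ~ FALSE,
      TRUE ~ NA
    ),
    context = na_dot(long$context)
  )
}

#' Read a per-caller variant file
#'
#' Reads variant calls from one caller for one sample, from either a VCF 4.2
#' file (extension `.vcf`) or a caller TSV with the package's canonical
#' columns. Multi-allelic VCF rows are split into one record per ALT allele;
#' per-allele INFO fields are split positionally. Coordinates stay 1-based.
#'
#' @param path Input file.
#' @param caller_id Caller label, conventionally `"A"` (the MuTect2 role) or
#'   `"B"` (the VarScan2 role, which carries the solo-rescue rule).
#' @param sample_id Sample label; defaults to the file name stem.
#' @return A variant tibble, one row per ALT allele.
#' @export
read_caller_variants <- function(path, caller_id,
                                 sample_id = sub("\\.caller_[AB]$", "",
                                                 sub("\\.(vcf|tsv)$", "",
                                                     basename(path)))) {
  if (!file.exists(path)) abort(paste0("no such variant file: ", path))
  if (grepl("\\.vcf$", path)) {
    parse_vcf_variants(path, caller_id, sample_id)
  } else {
    v <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    v$caller <- caller_id
    if (!"sample" %in% names(v)) v$sample <- sample_id
    missing <- setdiff(variant_columns, names(v))
    for (m in missing) v[[m]] <- NA
    v |>
      dplyr::mutate(pos = as.integer(.data$pos),
                    normal_alt_reads = as.integer(.data$normal_alt_reads),
                    truncating = as.logical(.data$truncating)) |>
      dplyr::select(dplyr::all_of(variant_columns))
  }
}

#' @rdname read_caller_variants
#' @param variants Variant tibble to write as TSV.
#' @export
write_caller_tsv <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}
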