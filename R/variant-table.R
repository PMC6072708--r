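#' @keywords internal
"_PACKAGE"

## Region classes in precedence order (highest first). When a variant carries
## several transcript-level annotations the highest-precedence class wins.
REGION_CLASSES <- c("exonic", "splicing", "utr5", "utr3", "ncRNA",
                    "upstream", "downstream", "intronic", "intergenic")

EXONIC_CLASSES <- c("nonsynonymous_SNV", "synonymous_SNV", "stopgain",
                    "stoploss", "nonframeshift_insertion",
                    "nonframeshift_deletion", "frameshift", "unknown", "none")

GENOTYPE_CALLS <- c("hom_ref", "het", "hom_alt", "missing")

## The 12-predictor missense panel, in canonical column order.
TOOL_PANEL <- c("sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt",
                "mutation_taster", "mutation_assessor", "fathmm",
                "metasvm", "metalr", "vest3", "provean", "ri")

INTOLERANCE_COLS <- c("rvis_esp", "rvis_exac", "rvis_local", "pli", "z_mis")
CONSERVATION_COLS <- c("gerp", "phastcons", "phylop")

REGION_SET_LABELS <- c("enhancer", "promoter", "super_enhancer", "ucne",
                       "ultrasensitive", "repeat")

#' Construct a variant table
#'
#' One row per variant per alternate allele, with per-sample genotype
#' (`gt_<sample>`) and depth (`dp_<sample>`) columns plus any subset of the
#' annotation columns the funnel consumes (population frequencies as
#' `maf_<db>`, `cadd_phred`, the 12 predictor columns, conservation and
#' intolerance scores, `mirsvr`, `tfbs_change`, `targetscan_site`).
#' Missing annotations are `NA` and are treated as absent, never as zero.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `region_class`, `exonic_class`, `is_indel`.
#' @param samples character vector of sample ids; each needs a
#'   `gt_<sample>` column (depth columns are optional).
#' @return a `variant_table` (data.frame subclass) with a `samples` attribute.
#' @export
variant_table <- function(df, samples = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "qual", "region_class",
                "exonic_class", "is_indel")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- sub("^gt_", "", grep("^gt_", names(df), value = TRUE))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$qual <- as.numeric(df$qual)
  df$is_indel <- as.logical(df$is_indel)
  for (s in samples) {
    gt_col <- paste0("gt_", s)
    if (!gt_col %in% names(df)) {
      stop("no genotype column for sample '", s, "'", call. = FALSE)
    }
    df[[gt_col]] <- normalize_genotype(df[[gt_col]])
  }
  attr(df, "samples") <- samples
  class(df) <- c("variant_table", "data.frame")
  validate_variant_table(df)
  df
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x), "variant(s),",
      length(samples(x)), "sample(s)\n")
  NextMethod()
}

#' Sample ids carried by a variant table
#' @param x a `variant_table`
#' @export
samples <- function(x) attr(x, "samples")

#' @keywords internal
variant_id <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "_")

#' @keywords internal
maf_columns <- function(x) grep("^maf_", names(x), value = TRUE)

## Accept both canonical call tokens and VCF-style GT strings.
#' @keywords internal
normalize_genotype <- function(gt) {
  gt <- as.character(gt)
  out <- ifelse(is.na(gt) | gt %in% c(".", "./.", ".|."), "missing", gt)
  vcf_map <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
               "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
               "1/1" = "hom_alt", "1|1" = "hom_alt")
  hit <- out %in% names(vcf_map)
  out[hit] <- vcf_map[out[hit]]
  bad <- !out %in% GENOTYPE_CALLS
  if (any(bad)) {
    stop("unrecognized genotype call(s): ",
         paste(unique(out[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @keywords internal
validate_variant_table <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$pos)) || any(x$pos < 1)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  if (any(x$ref == x$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  bad_region <- !is.na(x$region_class) & !x$region_class %in% REGION_CLASSES
  if (any(bad_region)) {
    stop("unknown region_class value(s): ",
         paste(unique(x$region_class[bad_region]), collapse = ", "),
         call. = FALSE)
  }
  bad_ex <- !is.na(x$exonic_class) & !x$exonic_class %in% EXONIC_CLASSES
  if (any(bad_ex)) {
    stop("unknown exonic_class value(s): ",
         paste(unique(x$exonic_class[bad_ex]), collapse = ", "),
         call. = FALSE)
  }
  non_exonic <- !is.na(x$region_class) & x$region_class != "exonic"
  if (any(non_exonic & !is.na(x$exonic_class) & x$exonic_class != "none")) {
    stop("exonic_class must be 'none' for non-exonic variants", call. = FALSE)
  }
  for (m in maf_columns(x)) {
    v <- x[[m]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("allele frequencies in '", m, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if ("phastcons" %in% names(x)) {
    v <- x$phastcons
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("phastCons scores must lie in [0, 1]", call. = FALSE)
    }
  }
  if ("pli" %in% names(x)) {
    v <- x$pli
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("pLI scores must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(x)
}

## Collapse an ANNOVAR-style (possibly multi-valued) region annotation to one
## canonical class using the precedence order in REGION_CLASSES.
#' @keywords internal
normalize_region_class <- function(x) {
  map_one <- function(tok) {
    tok <- trimws(tok)
    low <- tolower(tok)
    if (low %in% c("exonic")) return("exonic")
    if (low %in% c("splicing", "exonic;splicing")) return("splicing")
    if (low %in% c("utr5", "5utr", "utr-5")) return("utr5")
    if (low %in% c("utr3", "3utr", "utr-3")) return("utr3")
    if (startsWith(low, "ncrna")) return("ncRNA")
    if (low %in% c("upstream")) return("upstream")
    if (low %in% c("downstream", "upstream;downstream")) return("downstream")
    if (low %in% c("intronic")) return("intronic")
    if (low %in% c("intergenic")) return("intergenic")
    NA_character_
  }
  vapply(as.character(x), function(raw) {
    if (is.na(raw) || raw == "") return(NA_character_)
    toks <- unlist(strsplit(raw, "[;,]"))
    classes <- vapply(toks, map_one, character(1))
    classes <- classes[!is.na(classes)]
    if (length(classes) == 0) return(NA_character_)
    REGION_CLASSES[min(match(classes, REGION_CLASSES))]
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
normalize_exonic_class <- function(x, region_class) {
  canon <- gsub("[ -]", "_", trimws(as.character(x)))
  canon[is.na(canon) | canon == ""] <- "none"
  syn <- c("nonsynonymous_SNV" = "nonsynonymous_SNV",
           "synonymous_SNV" = "synonymous_SNV",
           "stopgain" = "stopgain", "stoploss" = "stoploss",
           "nonframeshift_insertion" = "nonframeshift_insertion",
           "nonframeshift_deletion" = "nonframeshift_deletion",
           "frameshift_insertion" = "frameshift",
           "frameshift_deletion" = "frameshift",
           "frameshift" = "frameshift",
           "unknown" = "unknown", "none" = "none")
  out <- unname(syn[canon])
  if (any(is.na(out))) {
    stop("unknown exonic classification value(s): ",
         paste(unique(canon[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out[!is.na(region_class) & region_class != "exonic"] <- "none"
  out
}

## Parse a compact amino-acid change token like "G573R" into from/to residues.
#' @keywords internal
parse_aa_change <- function(aa_change) {
  aa_change <- as.character(aa_change)
  m <- regmatches(aa_change,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", aa_change))
  from <- vapply(m, function(g) if (length(g) == 4) toupper(g[2]) else
    NA_character_, character(1))
  to <- vapply(m, function(g) if (length(g) == 4) toupper(g[4]) else
    NA_character_, character(1))
  list(from = from, to = to)
}
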