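#' Read a pedigree file
#'
#' Reads a PED file (family, individual, father, mother, sex, phenotype) with
#' an optional 7th column overriding the role. Phenotype 2 maps to `case`,
#' 1 to `control`, 0 and -9 to `unknown`. The 7th-column token `exclude`
#' marks an `exclusion_case`: an affected individual whose carrier status
#' must be negative for a variant to segregate (e.g. an unrelated case in an
#' otherwise related family); tokens `case`, `control` and `unknown` are
#' also accepted as overrides.
#'
#' @param path path to a whitespace-separated PED file.
#' @return a `pedigree` data.frame with columns `family`, `id`, `father`,
#'   `mother`, `sex`, `role`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    stop("PED file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 6)) {
    stop("PED line ", which(n_col < 6)[1], " has fewer than 6 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  ped <- data.frame(family = get(1), id = get(2), father = get(3),
                    mother = get(4), sex = get(5),
                    phenotype = get(6), stringsAsFactors = FALSE)
  role <- c("0" = "unknown", "-9" = "unknown",
            "1" = "control", "2" = "case")[ped$phenotype]
  if (any(is.na(role))) {
    stop("unrecognized phenotype code(s): ",
         paste(unique(ped$phenotype[is.na(role)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(n_col >= 7)) {
    ov <- vapply(fields, function(f) if (length(f) >= 7) f[7] else
      NA_character_, character(1))
    ov <- tolower(ov)
    ov[!is.na(ov) & ov %in% c(".", "-", "na")] <- NA_character_
    known <- c("case", "control", "unknown", "exclude", "exclusion_case")
    if (any(!is.na(ov) & !ov %in% known)) {
      stop("unrecognized role override(s): ",
           paste(unique(ov[!is.na(ov) & !ov %in% known]), collapse = ", "),
           call. = FALSE)
    }
    ov[!is.na(ov) & ov == "exclude"] <- "exclusion_case"
    role[!is.na(ov)] <- ov[!is.na(ov)]
  }
  ped$role <- role
  ped$phenotype <- NULL
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("father", "mother")) {
    dangling <- !ped[[col]] %in% c("0", ped$id)
    if (any(dangling)) {
      stop("pedigree ", col, " id(s) not listed: ",
           paste(unique(ped[[col]][dangling]), collapse = ", "),
           call. = FALSE)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @keywords internal
pedigree_roles <- function(pedigree, roles) {
  pedigree$id[pedigree$role %in% roles]
}

#' Read a BED file into a region set
#'
#' Reads a BED3+ file (0-based half-open intervals). Intervals are kept
#' exactly as listed -- overlapping intervals are not merged.
#'
#' @param path path to a BED file.
#' @param label which region set this file represents; one of
#'   `enhancer`, `promoter`, `super_enhancer`, `ucne`, `ultrasensitive`,
#'   `repeat`.
#' @return a `region_set`: list with elements `label` and `ranges`
#'   (a [GenomicRanges::GRanges] holding the intervals, 1-based inclusive
#'   internally).
#' @export
read_bed <- function(path, label) {
  label <- match.arg(label, REGION_SET_LABELS)
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "")
  if (ncol(raw) < 3) {
    stop("BED file must have at least 3 columns: ", path, call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric BED coordinate on line ",
         which(is.na(start) | is.na(end))[1], call. = FALSE)
  }
  bad <- start >= end
  if (any(bad)) {
    stop("BED interval with start >= end on line ", which(bad)[1],
         call. = FALSE)
  }
  region_set(label, chrom = raw[[1]], start = start, end = end)
}

#' Build a region set from coordinates
#'
#' @param label region-set label (see [read_bed()]).
#' @param chrom,start,end interval coordinates, BED convention
#'   (0-based half-open).
#' @return a `region_set`.
#' @export
region_set <- function(label, chrom, start, end) {
  label <- match.arg(label, REGION_SET_LABELS)
  if (any(start >= end)) {
    stop("region intervals require start < end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)))
  structure(list(label = label, ranges = gr), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set '", x$label, "': ", length(x$ranges), " interval(s)\n",
      sep = "")
  invisible(x)
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads a plain-text VCF 4.x file. Multi-allelic sites are split into one
#' record per alternate allele, with each sample's call re-expressed relative
#' to the split allele (copies of that allele: 0 = hom_ref, 1 = het,
#' 2 = hom_alt). Per-sample depth is taken from the first genotype field
#' listed in `depth_field` that the file provides. Annotation columns can be
#' mapped from INFO keys via `info_map`.
#'
#' @param path path to a VCF file.
#' @param sample_ids samples to keep (default: all samples in the file);
#'   unknown ids are an error.
#' @param depth_field genotype keys tried, in order, for per-sample depth.
#' @param info_map named character vector mapping variant-table columns to
#'   INFO keys, e.g. `c(cadd_phred = "CADD", gene = "GENE")`; parsed
#'   numerically where the target column is numeric.
#' @return a `variant_table`; `region_class` is `NA` unless provided via
#'   `info_map` (VCFs carry no region annotation by themselves).
#' @export
read_vcf <- function(path, sample_ids = NULL, depth_field = c("DP", "NR"),
                     info_map = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    stop("malformed VCF '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  file_samples <- colnames(vcf@gt)
  file_samples <- file_samples[file_samples != "FORMAT"]
  if (is.null(sample_ids)) sample_ids <- file_samples
  unknown <- setdiff(sample_ids, file_samples)
  if (length(unknown) > 0) {
    stop("sample id(s) not in VCF: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fix) == 0) {
    return(empty_variant_table(sample_ids))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- NULL
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  for (df in depth_field) {
    if (df %in% fmt_keys) {
      dp_raw <- suppressWarnings(
        vcfR::extract.gt(vcf, element = df, as.numeric = TRUE))
      break
    }
  }
  info_vals <- list()
  if (!is.null(info_map)) {
    for (col in names(info_map)) {
      info_vals[[col]] <- vcfR::extract.info(vcf, element = info_map[[col]])
    }
  }

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- unlist(strsplit(fix$ALT[i], ","))
    alts <- alts[!is.na(alts) & alts != "."]
    for (k in seq_along(alts)) {
      rec <- list(chrom = fix$CHROM[i],
                  pos = as.integer(fix$POS[i]),
                  ref = fix$REF[i],
                  alt = alts[k],
                  qual = suppressWarnings(as.numeric(fix$QUAL[i])))
      for (s in sample_ids) {
        rec[[paste0("gt_", s)]] <- split_gt_call(gt_raw[i, s], k)
        rec[[paste0("dp_", s)]] <- if (is.null(dp_raw)) NA_integer_ else
          as.integer(dp_raw[i, s])
      }
      for (col in names(info_vals)) rec[[col]] <- info_vals[[col]][i]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if ("region_class" %in% names(df)) {
    df$region_class <- normalize_region_class(df$region_class)
  } else {
    df$region_class <- NA_character_
  }
  df$exonic_class <- if ("exonic_class" %in% names(df)) {
    normalize_exonic_class(df$exonic_class, df$region_class)
  } else {
    ifelse(is.na(df$region_class) | df$region_class != "exonic",
           "none", "unknown")
  }
  if ("cadd_phred" %in% names(df)) {
    df$cadd_phred <- suppressWarnings(as.numeric(df$cadd_phred))
  }
  df$gene <- if ("gene" %in% names(df)) as.character(df$gene) else
    NA_character_
  df$is_indel <- nchar(df$ref) != nchar(df$alt)
  variant_table(df, samples = sample_ids)
}

## Re-express a VCF GT string relative to split alternate allele k.
#' @keywords internal
split_gt_call <- function(gt, k) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- unlist(strsplit(gt, "[/|]"))
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(k))
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

#' @keywords internal
empty_variant_table <- function(sample_ids) {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   qual = numeric(0), region_class = character(0),
                   exonic_class = character(0), gene = character(0),
                   is_indel = logical(0), stringsAsFactors = FALSE)
  for (s in sample_ids) {
    df[[paste0("gt_", s)]] <- character(0)
    df[[paste0("dp_", s)]] <- integer(0)
  }
  variant_table(df, samples = sample_ids)
}

## Canonical annotated-table columns with their storage type.
#' @keywords internal
annotation_column_types <- function() {
  c(chrom = "character", pos = "integer", ref = "character",
    alt = "character", qual = "numeric", region_class = "character",
    exonic_class = "character", gene = "character",
    aa_change = "character", is_indel = "logical",
    cadd_phred = "numeric",
    stats::setNames(rep("numeric", length(TOOL_PANEL)), TOOL_PANEL)[
      c("sift", "polyphen2_hdiv", "polyphen2_hvar", "fathmm", "metasvm",
        "metalr", "vest3", "provean", "ri")],
    lrt = "character", mutation_taster = "character",
    mutation_assessor = "character",
    gerp = "numeric", phastcons = "numeric", phylop = "numeric",
    rvis_esp = "numeric", rvis_exac = "numeric", rvis_local = "numeric",
    pli = "numeric", z_mis = "numeric",
    mirsvr = "numeric", tfbs_change = "logical",
    targetscan_site = "logical")
}

#' Read a flat annotated variant table
#'
#' Reads a tab-separated table with one row per variant per alternate allele:
#' required columns `chrom`, `pos`, `ref`, `alt`, `qual` plus per-sample
#' `gt_<sample>`/`dp_<sample>` pairs, and any subset of the annotation
#' columns (`region_class`, `exonic_class`, `gene`, `aa_change`,
#' `cadd_phred`, the 12 predictor columns, `maf_<db>` frequencies,
#' conservation and intolerance scores, `mirsvr`, `tfbs_change`,
#' `targetscan_site`). Unparseable numeric cells become `NA` with a warning;
#' missing annotations stay `NA` (absent), never zero.
#'
#' @param path path to a TSV file.
#' @param column_map optional named character vector renaming file columns to
#'   canonical ones, e.g. `c(cadd_phred = "CADD_PHRED")`.
#' @return a `variant_table`.
#' @export
read_annotated_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column-map source '", src, "' not found in table",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotated table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  gt_cols <- grep("^gt_", names(df), value = TRUE)
  if (length(gt_cols) == 0) {
    stop("annotated table is missing required column(s): gt_<sample>",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(empty_variant_table(sub("^gt_", "", gt_cols)))
  }
  types <- annotation_column_types()
  parse_num <- function(col, to_int = FALSE) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(val)
    if (any(bad)) {
      warning("unparseable numeric value(s) in column '", col,
              "' set to NA: ", paste(unique(raw[bad]), collapse = ", "),
              call. = FALSE)
    }
    if (to_int) as.integer(val) else val
  }
  for (col in names(df)) {
    ty <- if (col %in% names(types)) types[[col]] else
      if (grepl("^maf_", col)) "numeric" else
      if (grepl("^dp_", col)) "integer" else "character"
    if (ty == "numeric") df[[col]] <- parse_num(col)
    if (ty == "integer") df[[col]] <- parse_num(col, to_int = TRUE)
    if (ty == "logical") {
      raw <- toupper(trimws(df[[col]]))
      val <- rep(NA, nrow(df))
      val[raw %in% c("TRUE", "T", "1", "YES")] <- TRUE
      val[raw %in% c("FALSE", "F", "0", "NO")] <- FALSE
      bad <- !is.na(raw) & is.na(val)
      if (any(bad)) {
        stop("non-boolean value(s) in column '", col, "': ",
             paste(unique(df[[col]][bad]), collapse = ", "), call. = FALSE)
      }
      df[[col]] <- val
    }
  }
  df$region_class <- if ("region_class" %in% names(df)) {
    normalize_region_class(df$region_class)
  } else NA_character_
  df$exonic_class <- if ("exonic_class" %in% names(df)) {
    normalize_exonic_class(df$exonic_class, df$region_class)
  } else ifelse(is.na(df$region_class) | df$region_class != "exonic",
                "none", "unknown")
  if (!"is_indel" %in% names(df) || all(is.na(df$is_indel))) {
    df$is_indel <- nchar(df$ref) != nchar(df$alt)
  }
  if ("aa_change" %in% names(df)) {
    aa <- parse_aa_change(df$aa_change)
    df$aa_from <- aa$from
    df$aa_to <- aa$to
  }
  variant_table(df, samples = sub("^gt_", "", gt_cols))
}

#' Write a variant table to TSV
#'
#' Writes the table in the dialect [read_annotated_table()] reads, so that a
#' write/read round trip preserves every field.
#'
#' @param x a `variant_table`.
#' @param path output path.
#' @export
write_annotated_table <- function(x, path) {
  out <- as.data.frame(x)
  out$aa_from <- NULL
  out$aa_to <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
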