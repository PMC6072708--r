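## Half-open genomic footprint of each variant: an SNV at 1-based position p
## covers [p-1, p); an indel spanning L reference bases covers [p-1, p-1+L).
## Internally represented as 1-based inclusive GRanges.
#' @keywords internal
variant_ranges <- function(variants, chr_prefix = "keep") {
  chrom <- normalize_chrom(variants$chrom, chr_prefix)
  len <- pmax(nchar(variants$ref), 1L)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = variants$pos,
                              end = variants$pos + len - 1L))
}

#' @keywords internal
normalize_chrom <- function(chrom, chr_prefix = "keep") {
  chrom <- as.character(chrom)
  switch(chr_prefix,
         keep = chrom,
         strip = sub("^chr", "", chrom),
         add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
}

#' Intersect variants with a region set
#'
#' A variant hits an interval iff its half-open genomic footprint overlaps
#' the interval by at least one base. Chromosome names on both sides are
#' normalized per `chr_prefix`; if the two sides still share no chromosome
#' a warning is emitted and the result is empty.
#'
#' @param variants a `variant_table`.
#' @param regions a `region_set` from [read_bed()] or [region_set()].
#' @param chr_prefix chromosome-name normalization: `keep`, `strip`, `add`.
#' @return data.frame of hits with `variant_idx`, `variant_id`,
#'   `interval_idx`, `chrom`, `start`, `end` (BED coordinates), ordered by
#'   `variant_idx` (input variant order).
#' @export
intersect_regions <- function(variants, regions,
                              chr_prefix = c("keep", "strip", "add")) {
  chr_prefix <- match.arg(chr_prefix)
  stopifnot(inherits(regions, "region_set"))
  empty <- data.frame(variant_idx = integer(0), variant_id = character(0),
                      interval_idx = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0 || length(regions$ranges) == 0) return(empty)
  vr <- variant_ranges(variants, chr_prefix)
  gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(
      as.character(GenomicRanges::seqnames(regions$ranges)), chr_prefix),
    ranges = IRanges::ranges(regions$ranges))
  v_chr <- unique(as.character(GenomicRanges::seqnames(vr)))
  r_chr <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(intersect(v_chr, r_chr)) == 0) {
    warning("no chromosome shared between variants and '", regions$label,
            "' regions (chr-prefix mismatch?); zero hits", call. = FALSE)
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(vr, gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ord <- order(qi, si)
  qi <- qi[ord]
  si <- si[ord]
  data.frame(variant_idx = qi,
             variant_id = variant_id(as.data.frame(variants))[qi],
             interval_idx = si,
             chrom = as.character(GenomicRanges::seqnames(gr))[si],
             start = GenomicRanges::start(gr)[si] - 1L,
             end = GenomicRanges::end(gr)[si],
             stringsAsFactors = FALSE)
}

#' Exclude indels falling in repetitive regions
#'
#' Indels whose footprint overlaps a repeat interval are unreliable calls
#' and are moved to the excluded set with a reason tag; SNVs are never
#' excluded here.
#'
#' @param variants a `variant_table`.
#' @param repeat_set a `region_set` with label `repeat`.
#' @param chr_prefix chromosome-name normalization (see
#'   [intersect_regions()]).
#' @return list with `kept` (a `variant_table`) and `excluded` (a
#'   `variant_table` with an `exclusion_reason` column); together they
#'   partition the input.
#' @export
exclude_repeat_indels <- function(variants, repeat_set,
                                  chr_prefix = "keep") {
  stopifnot(inherits(repeat_set, "region_set"))
  if (repeat_set$label != "repeat") {
    stop("repeat exclusion requires a region set labelled 'repeat'",
         call. = FALSE)
  }
  if (nrow(variants) == 0) {
    return(list(kept = variants,
                excluded = transform(variants,
                                     exclusion_reason = character(0))))
  }
  hits <- intersect_regions(variants, repeat_set, chr_prefix)
  in_repeat <- seq_len(nrow(variants)) %in% hits$variant_idx
  drop <- variants$is_indel & in_repeat
  excluded <- variants[drop, , drop = FALSE]
  excluded$exclusion_reason <- rep("indel_in_repeat", sum(drop))
  list(kept = restore_variant_table(variants[!drop, , drop = FALSE],
                                    samples(variants)),
       excluded = restore_variant_table(excluded, samples(variants)))
}

#' Flag 3' UTR variants with miRNA target-site evidence
#'
#' A 3' UTR variant is flagged when its mirSVR score is present and strictly
#' below `mirsvr_max` (a good predicted miRNA target site), or when an
#' upstream target-site scan marked the position (`targetscan_site`).
#'
#' @param variants a `variant_table` of `utr3` records.
#' @param config a [pipeline_config()].
#' @return logical vector, one flag per variant.
#' @export
assess_utr3 <- function(variants, config = pipeline_config()) {
  df <- as.data.frame(variants)
  n <- nrow(df)
  mirsvr <- if ("mirsvr" %in% names(df)) df$mirsvr else rep(NA_real_, n)
  ts <- if ("targetscan_site" %in% names(df)) df$targetscan_site else
    rep(NA, n)
  (!is.na(mirsvr) & mirsvr < config$mirsvr_max) | (!is.na(ts) & ts)
}

#' Flag 5' UTR variants with transcription-factor binding-site evidence
#'
#' Pass-through of the upstream TFBS-change annotation with validation: the
#' flag is the `tfbs_change` column; an absent value counts as no evidence.
#'
#' @param variants a `variant_table` of `utr5` records.
#' @return logical vector, one flag per variant.
#' @export
assess_utr5 <- function(variants) {
  df <- as.data.frame(variants)
  n <- nrow(df)
  tfbs <- if ("tfbs_change" %in% names(df)) df$tfbs_change else rep(NA, n)
  if (!is.logical(tfbs)) {
    stop("tfbs_change must be logical (TRUE/FALSE/NA)", call. = FALSE)
  }
  !is.na(tfbs) & tfbs
}

ROUTES <- c("coding_route", "utr5_route", "utr3_route", "noncoding_route")

#' Route variants by genomic location
#'
#' Partitions variants into the four assessment routes: exonic and splicing
#' records to the coding route (CADD-gated), 5' and 3' UTR records to their
#' regulatory routes (CADD-gated), and ncRNA/upstream/downstream/intronic/
#' intergenic records to the non-coding route, where the CADD gate is
#' bypassed by default because regulatory variants need not score highly.
#'
#' @param variants a `variant_table`; every record must have a known
#'   `region_class`.
#' @return factor of route labels, one per variant.
#' @export
route_variant <- function(variants) {
  rc <- variants$region_class
  if (any(is.na(rc))) {
    stop("cannot route variant(s) with missing region_class", call. = FALSE)
  }
  route <- rep(NA_character_, length(rc))
  route[rc %in% c("exonic", "splicing")] <- "coding_route"
  route[rc == "utr5"] <- "utr5_route"
  route[rc == "utr3"] <- "utr3_route"
  route[rc %in% c("ncRNA", "upstream", "downstream", "intronic",
                  "intergenic")] <- "noncoding_route"
  if (any(is.na(route))) {
    stop("unknown region_class value(s): ",
         paste(unique(rc[is.na(route)]), collapse = ", "), call. = FALSE)
  }
  factor(route, levels = ROUTES)
}

#' Collect regulatory-region evidence for variants
#'
#' Intersects variants with each supplied regulatory region set (enhancer,
#' promoter, super_enhancer, ucne, ultrasensitive) and counts, per variant,
#' the distinct region labels hit.
#'
#' @param variants a `variant_table`.
#' @param region_sets named list of `region_set`s (names are ignored; the
#'   sets' own labels are used). A `repeat` set, if present, is ignored
#'   here -- repeats are handled by [exclude_repeat_indels()].
#' @param chr_prefix chromosome-name normalization.
#' @return data.frame with one logical `hit_<label>` column per supplied
#'   regulatory set and an integer `n_regulatory` count.
#' @export
regulatory_hits <- function(variants, region_sets,
                            chr_prefix = "keep") {
  n <- nrow(variants)
  out <- data.frame(row.names = seq_len(max(n, 0)))
  labels <- character(0)
  for (rs in region_sets) {
    if (!inherits(rs, "region_set") || rs$label == "repeat") next
    hits <- intersect_regions(variants, rs, chr_prefix)
    col <- paste0("hit_", rs$label)
    out[[col]] <- seq_len(n) %in% hits$variant_idx
    labels <- c(labels, col)
  }
  out$n_regulatory <- if (length(labels) > 0) {
    as.integer(rowSums(as.matrix(out[, labels, drop = FALSE])))
  } else {
    integer(n)
  }
  out
}
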