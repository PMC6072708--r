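#' Site and sample quality filter
#'
#' Removes variants whose site quality does not exceed `min_qual` (strict:
#' QUAL must be greater than the threshold). Per-sample calls backed by
#' fewer than `min_depth` reads are masked to `missing` rather than removing
#' the whole variant, because segregation needs per-sample evidence; a call
#' with no depth value is left untouched. Variants for which every
#' pedigree-sample call ends up missing are removed.
#'
#' @param variants a `variant_table`.
#' @param config a [pipeline_config()].
#' @param pedigree a `pedigree` from [read_ped()]; every pedigree individual
#'   must have a genotype column.
#' @return the filtered `variant_table`.
#' @export
apply_quality_filter <- function(variants, config = pipeline_config(),
                                 pedigree) {
  ped_ids <- pedigree$id
  absent <- setdiff(ped_ids, samples(variants))
  if (length(absent) > 0) {
    stop("pedigree sample(s) absent from variant table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(variants$qual) & variants$qual > config$min_qual
  out <- variants[keep, , drop = FALSE]
  for (s in ped_ids) {
    dp <- out[[paste0("dp_", s)]]
    if (is.null(dp)) next
    low <- !is.na(dp) & dp < config$min_depth
    out[[paste0("gt_", s)]][low] <- "missing"
  }
  gt_mat <- as.matrix(out[, paste0("gt_", ped_ids), drop = FALSE])
  all_missing <- apply(gt_mat == "missing", 1, all)
  out <- out[!all_missing, , drop = FALSE]
  restore_variant_table(out, samples(variants))
}

#' Population-frequency filter
#'
#' A variant survives iff its frequency is below `max_maf` in every
#' population column (`maf_<db>`) where a value is present; an absent
#' frequency counts as passing (missing means not observed, hence rare).
#'
#' @inheritParams apply_quality_filter
#' @return the filtered `variant_table`.
#' @export
apply_frequency_filter <- function(variants, config = pipeline_config()) {
  cols <- maf_columns(variants)
  if (length(cols) == 0 || nrow(variants) == 0) return(variants)
  m <- as.matrix(variants[, cols, drop = FALSE])
  if (any(!is.na(m) & (m < 0 | m > 1))) {
    stop("allele frequency outside [0, 1]", call. = FALSE)
  }
  common <- rowSums(!is.na(m) & m >= config$max_maf) > 0
  restore_variant_table(variants[!common, , drop = FALSE], samples(variants))
}

#' Pairwise genotype concordance
#'
#' Sample-swap and relatedness QC: for every pair of samples, the fraction
#' of co-called sites (both calls non-missing) with identical genotype
#' calls. The matrix is symmetric with unit diagonal; a pair with no
#' co-called site gets `NA` with a warning.
#'
#' @param variants a `variant_table`.
#' @param sample_ids samples to compare (default: all; at least 2).
#' @return a symmetric numeric matrix of concordance fractions.
#' @export
pairwise_concordance <- function(variants, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- samples(variants)
  if (length(sample_ids) < 2) {
    stop("concordance needs at least two samples", call. = FALSE)
  }
  absent <- setdiff(sample_ids, samples(variants))
  if (length(absent) > 0) {
    stop("unknown sample id(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  gt <- as.matrix(
    as.data.frame(variants)[, paste0("gt_", sample_ids), drop = FALSE])
  n <- length(sample_ids)
  out <- diag(1, n)
  dimnames(out) <- list(sample_ids, sample_ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- gt[, i] != "missing" & gt[, j] != "missing"
      if (!any(ok)) {
        warning("no co-called sites for pair ", sample_ids[i], "/",
                sample_ids[j], "; concordance undefined", call. = FALSE)
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- mean(gt[ok, i] == gt[ok, j])
      }
    }
  }
  out
}

## Subsetting a classed data.frame with [ drops attributes in some paths;
## re-attach the variant_table contract after row filtering.
#' @keywords internal
restore_variant_table <- function(df, sample_ids) {
  df <- as.data.frame(df)
  rownames(df) <- NULL
  attr(df, "samples") <- sample_ids
  class(df) <- c("variant_table", "data.frame")
  df
}
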