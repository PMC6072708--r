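#' Funnel thresholds and switches
#'
#' Every tunable threshold of the prioritization cascade, with the defaults
#' used for familial cancer studies: site quality must exceed `min_qual`
#' (QUAL > 20), per-sample coverage must reach `min_depth` reads (>= 5, lower
#' coverage masks that sample's call), population frequency must stay below
#' `max_maf` (< 0.1%) in every database where a value is present, and the
#' CADD PHRED cutpoints 10/20/30 delimit the top 10% / 1% / 0.1% tiers of
#' predicted deleteriousness. The missense consensus requires at least
#' `consensus_fraction` (60%) of the available predictors to call a variant
#' damaging, with at least `min_tools_available` predictors scored.
#' Conservation flags use GERP > 2, phastCons > 0.3 and phyloP >= 3;
#' intolerance votes use RVIS < 0, pLI >= 0.9 and missense Z > 0. 3' UTR
#' variants are flagged as putative miRNA targets below `mirsvr_max` (-0.1).
#' Grantham distances are binned at 50/100/150 into conservative through
#' radical substitution categories.
#'
#' @param min_qual site QUAL; variants with `qual <= min_qual` are removed.
#' @param min_depth per-sample read depth; calls with fewer reads are masked.
#' @param max_maf frequency ceiling; a present MAF must be `< max_maf`.
#' @param cadd_gate,cadd_top1,cadd_top01 CADD PHRED tier cutpoints (strict >).
#' @param consensus_fraction fraction of available predictors that must vote
#'   damaging.
#' @param min_tools_available minimum scored predictors for a usable consensus.
#' @param gerp_min,phastcons_min,phylop_min conservation cutoffs (GERP and
#'   phastCons strict >, phyloP inclusive >=).
#' @param pli_intolerant,pli_tolerant pLI bands for intolerant/tolerant genes.
#' @param mirsvr_max mirSVR ceiling (strict <) for a good miRNA target site.
#' @param grantham_bins strictly increasing category boundaries.
#' @param max_noncarrier_cases,max_carrier_controls segregation tolerances.
#' @param conservation_is_hard_gate when `TRUE`, coding candidates must also
#'   show at least `conservation_min_flags` conservation flags.
#' @param conservation_min_flags flags required when conservation is gated.
#' @param depth_field candidate per-sample depth keys in VCF genotype fields,
#'   tried in order (Platypus uses NR, GATK-style callers DP).
#' @param chr_prefix chromosome-name normalization applied when intersecting
#'   variants with region sets: keep, strip or add a "chr" prefix.
#' @param vest3_cutoff VEST3 damaging cutoff (no published cutoff exists;
#'   higher scores are more deleterious).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_qual = 20, min_depth = 5, max_maf = 0.001,
                            cadd_gate = 10, cadd_top1 = 20, cadd_top01 = 30,
                            consensus_fraction = 0.6,
                            min_tools_available = 6,
                            gerp_min = 2.0, phastcons_min = 0.3,
                            phylop_min = 3.0,
                            pli_intolerant = 0.9, pli_tolerant = 0.1,
                            mirsvr_max = -0.1,
                            grantham_bins = c(50, 100, 150),
                            max_noncarrier_cases = 0,
                            max_carrier_controls = 0,
                            conservation_is_hard_gate = FALSE,
                            conservation_min_flags = 2,
                            depth_field = c("DP", "NR"),
                            chr_prefix = c("keep", "strip", "add"),
                            vest3_cutoff = 0.5) {
  chr_prefix <- match.arg(chr_prefix)
  cfg <- list(min_qual = as.numeric(min_qual),
              min_depth = as.integer(min_depth),
              max_maf = as.numeric(max_maf),
              cadd_gate = as.numeric(cadd_gate),
              cadd_top1 = as.numeric(cadd_top1),
              cadd_top01 = as.numeric(cadd_top01),
              consensus_fraction = as.numeric(consensus_fraction),
              min_tools_available = as.integer(min_tools_available),
              gerp_min = as.numeric(gerp_min),
              phastcons_min = as.numeric(phastcons_min),
              phylop_min = as.numeric(phylop_min),
              pli_intolerant = as.numeric(pli_intolerant),
              pli_tolerant = as.numeric(pli_tolerant),
              mirsvr_max = as.numeric(mirsvr_max),
              grantham_bins = as.numeric(grantham_bins),
              max_noncarrier_cases = as.integer(max_noncarrier_cases),
              max_carrier_controls = as.integer(max_carrier_controls),
              conservation_is_hard_gate = isTRUE(conservation_is_hard_gate),
              conservation_min_flags = as.integer(conservation_min_flags),
              depth_field = as.character(depth_field),
              chr_prefix = chr_prefix,
              vest3_cutoff = as.numeric(vest3_cutoff))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  if (!(cfg$max_maf > 0 && cfg$max_maf < 1)) {
    stop("max_maf must lie in (0, 1)", call. = FALSE)
  }
  if (!(cfg$consensus_fraction > 0 && cfg$consensus_fraction <= 1)) {
    stop("consensus_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (length(cfg$grantham_bins) != 3 ||
      any(diff(cfg$grantham_bins) <= 0)) {
    stop("grantham_bins must be three strictly increasing boundaries",
         call. = FALSE)
  }
  if (cfg$max_noncarrier_cases < 0 || cfg$max_carrier_controls < 0) {
    stop("segregation tolerances must be >= 0", call. = FALSE)
  }
  if (!(cfg$cadd_gate < cfg$cadd_top1 && cfg$cadd_top1 < cfg$cadd_top01)) {
    stop("CADD tier cutpoints must be strictly increasing", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON file whose keys mirror the [pipeline_config()]
#' arguments; unspecified keys keep their defaults, unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

## Half-up decimal rounding (R's round() is half-even); funnel percentages
## are reported half-up to one decimal.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
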