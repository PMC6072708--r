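#' A single predictor's voting rule
#'
#' @param name predictor label, unique within a panel.
#' @param mode `numeric_low_is_damaging` (damaging below the cutoff),
#'   `numeric_high_is_damaging` (damaging above it) or `categorical`
#'   (damaging iff the label is in `damaging_categories`).
#' @param cutoff numeric cutoff (numeric modes only).
#' @param cutoff_inclusive whether the cutoff itself counts as damaging.
#' @param damaging_categories labels that vote damaging (categorical mode).
#' @param vocabulary all labels the predictor can emit (categorical mode).
#' @param range published score range, used to validate simulated scores.
#' @return a `tool_rule`.
#' @export
tool_rule <- function(name, mode, cutoff = NULL, cutoff_inclusive = FALSE,
                      damaging_categories = NULL, vocabulary = NULL,
                      range = NULL) {
  mode <- match.arg(mode, c("numeric_low_is_damaging",
                            "numeric_high_is_damaging", "categorical"))
  if (mode == "categorical") {
    if (is.null(damaging_categories) || is.null(vocabulary) ||
        !is.null(cutoff)) {
      stop("categorical rule '", name,
           "' needs damaging_categories and vocabulary, and no cutoff",
           call. = FALSE)
    }
    if (!all(damaging_categories %in% vocabulary)) {
      stop("damaging categories of '", name,
           "' must be in its vocabulary", call. = FALSE)
    }
  } else {
    if (is.null(cutoff) || !is.null(damaging_categories)) {
      stop("numeric rule '", name,
           "' needs a cutoff and no damaging_categories", call. = FALSE)
    }
  }
  structure(list(name = name, mode = mode, cutoff = cutoff,
                 cutoff_inclusive = isTRUE(cutoff_inclusive),
                 damaging_categories = damaging_categories,
                 vocabulary = vocabulary, range = range),
            class = "tool_rule")
}

#' The default 12-predictor panel
#'
#' Loads the packaged versioned panel description (SIFT, PolyPhen-2 HDIV and
#' HVAR, LRT, MutationTaster, MutationAssessor, FATHMM, MetaSVM, MetaLR,
#' VEST3, PROVEAN, RI) and applies the configurable VEST3 cutoff.
#'
#' @param config a [pipeline_config()]; only `vest3_cutoff` is consulted.
#' @return named list of [tool_rule()]s in panel order.
#' @export
default_tool_rules <- function(config = pipeline_config()) {
  path <- system.file("extdata", "tool_rules.yaml", package = "varfunnel",
                      mustWork = TRUE)
  spec <- yaml::read_yaml(path)$tools
  rules <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    tool_rule(name = nm, mode = s$mode, cutoff = s$cutoff,
              cutoff_inclusive = isTRUE(s$cutoff_inclusive),
              damaging_categories = s$damaging_categories,
              vocabulary = s$vocabulary,
              range = if (!is.null(s$range)) as.numeric(s$range))
  })
  names(rules) <- names(spec)
  rules$vest3$cutoff <- config$vest3_cutoff
  rules
}

#' CADD deleteriousness tier
#'
#' Bins a scaled CADD PHRED score into the tiers of predicted human-genome
#' deleteriousness: above 10 the top 10% (`top10`), above 20 the top 1%
#' (`top1`), above 30 the top 0.1% (`top01`); all thresholds strict. An
#' absent score is `unscored`, anything else `below`.
#'
#' @param score numeric CADD PHRED score(s); `NA` allowed.
#' @param config a [pipeline_config()] supplying the cutpoints.
#' @return ordered factor with levels
#'   `unscored < below < top10 < top1 < top01`.
#' @export
cadd_tier <- function(score, config = pipeline_config()) {
  levels <- c("unscored", "below", "top10", "top1", "top01")
  tier <- rep("below", length(score))
  tier[!is.na(score) & score > config$cadd_gate] <- "top10"
  tier[!is.na(score) & score > config$cadd_top1] <- "top1"
  tier[!is.na(score) & score > config$cadd_top01] <- "top01"
  tier[is.na(score)] <- "unscored"
  factor(tier, levels = levels, ordered = TRUE)
}

#' Classify one predictor's output
#'
#' @param rule a [tool_rule()].
#' @param value the predictor's raw score (numeric modes) or label
#'   (categorical mode); `NA` means the predictor did not score the variant.
#'   Vectorized.
#' @return character vector in `damaging` / `tolerated` / `unavailable`.
#' @export
classify_tool <- function(rule, value) {
  stopifnot(inherits(rule, "tool_rule"))
  n <- length(value)
  out <- rep("unavailable", n)
  present <- !is.na(value)
  if (!any(present)) return(out)
  if (rule$mode == "categorical") {
    lab <- as.character(value[present])
    unknown <- !lab %in% rule$vocabulary
    if (any(unknown)) {
      stop("label(s) outside the vocabulary of '", rule$name, "': ",
           paste(unique(lab[unknown]), collapse = ", "), call. = FALSE)
    }
    out[present] <- ifelse(lab %in% rule$damaging_categories,
                           "damaging", "tolerated")
  } else {
    v <- suppressWarnings(as.numeric(value[present]))
    if (any(is.na(v))) {
      stop("non-numeric score for numeric rule '", rule$name, "'",
           call. = FALSE)
    }
    hit <- if (rule$mode == "numeric_low_is_damaging") {
      if (rule$cutoff_inclusive) v <= rule$cutoff else v < rule$cutoff
    } else {
      if (rule$cutoff_inclusive) v >= rule$cutoff else v > rule$cutoff
    }
    out[present] <- ifelse(hit, "damaging", "tolerated")
  }
  out
}

#' Deleteriousness consensus over the predictor panel
#'
#' Counts damaging votes over the predictors that scored the variant
#' (`unavailable` verdicts are excluded from the denominator). The verdict
#' is `deleterious` when the damaging fraction reaches
#' `consensus_fraction` with at least `min_tools_available` predictors
#' scored, `insufficient` when too few predictors scored, else `tolerated`.
#'
#' @param verdicts named character vector of per-predictor verdicts
#'   (`damaging` / `tolerated` / `unavailable`), one per panel member;
#'   duplicate names are an error.
#' @param config a [pipeline_config()].
#' @return list with `n_damaging`, `n_available`, `fraction`, `verdict`.
#' @export
consensus <- function(verdicts, config = pipeline_config()) {
  if (!is.null(names(verdicts)) && anyDuplicated(names(verdicts))) {
    stop("duplicate predictor name(s) in verdict vector", call. = FALSE)
  }
  bad <- !verdicts %in% c("damaging", "tolerated", "unavailable")
  if (any(bad)) {
    stop("unrecognized verdict(s): ",
         paste(unique(verdicts[bad]), collapse = ", "), call. = FALSE)
  }
  n_available <- sum(verdicts != "unavailable")
  n_damaging <- sum(verdicts == "damaging")
  fraction <- if (n_available > 0) n_damaging / n_available else NA_real_
  verdict <- if (n_available < config$min_tools_available) {
    "insufficient"
  } else if (fraction >= config$consensus_fraction) {
    "deleterious"
  } else {
    "tolerated"
  }
  list(n_damaging = n_damaging, n_available = n_available,
       fraction = fraction, verdict = verdict)
}

#' Conservation flags
#'
#' Three independent evolutionary-conservation flags: GERP strictly above
#' `gerp_min`, phastCons strictly above `phastcons_min`, phyloP at or above
#' `phylop_min`. An absent score yields an absent (`NA`) flag, never a
#' failing one; `n_conserved` counts the flags that are present and true.
#'
#' @param gerp,phastcons,phylop numeric scores (vectorized, `NA` allowed).
#' @param config a [pipeline_config()].
#' @return data.frame with `gerp_flag`, `phastcons_flag`, `phylop_flag`
#'   (logical, `NA` = absent) and integer `n_conserved`.
#' @export
conservation_flags <- function(gerp = NA, phastcons = NA, phylop = NA,
                               config = pipeline_config()) {
  if (any(!is.na(phastcons) & (phastcons < 0 | phastcons > 1))) {
    stop("phastCons scores must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(gerp), length(phastcons), length(phylop))
  gerp <- rep_len(gerp, n)
  phastcons <- rep_len(phastcons, n)
  phylop <- rep_len(phylop, n)
  gerp_flag <- ifelse(is.na(gerp), NA, gerp > config$gerp_min)
  phastcons_flag <- ifelse(is.na(phastcons), NA,
                           phastcons > config$phastcons_min)
  phylop_flag <- ifelse(is.na(phylop), NA, phylop >= config$phylop_min)
  flags <- cbind(gerp_flag, phastcons_flag, phylop_flag)
  data.frame(gerp_flag = as.logical(gerp_flag),
             phastcons_flag = as.logical(phastcons_flag),
             phylop_flag = as.logical(phylop_flag),
             n_conserved = as.integer(rowSums(flags, na.rm = TRUE)))
}

#' Gene intolerance votes
#'
#' Five per-gene intolerance calls: each of the three RVIS flavours
#' (ESP6500-, ExAC- and local-cohort-based) votes intolerant when negative,
#' pLI votes intolerant at or above `pli_intolerant`, and the missense
#' Z-score votes intolerant when positive (fewer variants observed than
#' expected). Absent scores cast no vote; `n_intolerant` counts intolerant
#' votes among present scores.
#'
#' @param rvis_esp,rvis_exac,rvis_local,pli,z_mis numeric scores
#'   (vectorized, `NA` allowed); `pli` must lie in \[0, 1\].
#' @param config a [pipeline_config()].
#' @return data.frame of the five logical votes (`NA` = absent), plus
#'   integer `n_intolerant` and `n_scores_present`.
#' @export
intolerance_votes <- function(rvis_esp = NA, rvis_exac = NA,
                              rvis_local = NA, pli = NA, z_mis = NA,
                              config = pipeline_config()) {
  if (any(!is.na(pli) & (pli < 0 | pli > 1))) {
    stop("pLI scores must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(rvis_esp), length(rvis_exac), length(rvis_local),
           length(pli), length(z_mis))
  votes <- cbind(rvis_esp_vote = rep_len(rvis_esp, n) < 0,
                 rvis_exac_vote = rep_len(rvis_exac, n) < 0,
                 rvis_local_vote = rep_len(rvis_local, n) < 0,
                 pli_vote = rep_len(pli, n) >= config$pli_intolerant,
                 z_mis_vote = rep_len(z_mis, n) > 0)
  out <- as.data.frame(votes)
  out$n_intolerant <- as.integer(rowSums(votes, na.rm = TRUE))
  out$n_scores_present <- as.integer(rowSums(!is.na(votes)))
  out
}

## Vectorized panel classification over a variant table's score columns.
#' @keywords internal
classify_panel_matrix <- function(variants, rules) {
  df <- as.data.frame(variants)
  m <- matrix("unavailable", nrow = nrow(df), ncol = length(rules),
              dimnames = list(NULL, names(rules)))
  for (nm in names(rules)) {
    if (nm %in% names(df)) {
      m[, nm] <- classify_tool(rules[[nm]], df[[nm]])
    }
  }
  m
}

#' Assess coding variants
#'
#' Runs the full coding-side evidence battery on each variant of a table:
#' CADD tier, predictor-panel consensus, conservation flags, gene
#' intolerance votes, and Grantham scoring of the amino-acid change. A
#' variant passes iff it is a nonsynonymous (missense) SNV in at least the
#' top-10% CADD tier whose consensus verdict is deleterious and whose gene
#' draws at least one intolerance vote; when
#' `conservation_is_hard_gate` is set, at least `conservation_min_flags`
#' conservation flags are additionally required. Exonic variants of other
#' classes receive an assessment with `passes = FALSE` and an explanatory
#' note. `gate_failed` names the first failing gate (in the order
#' coding_class, cadd, consensus, intolerance, conservation) for funnel
#' attribution.
#'
#' @param variants a `variant_table` restricted to exonic records, carrying
#'   the predictor, conservation and intolerance columns it has available.
#' @param config a [pipeline_config()].
#' @param rules predictor panel (default [default_tool_rules()]).
#' @return data.frame, one row per variant, with tier, consensus,
#'   conservation, intolerance and Grantham columns plus `passes`,
#'   `gate_failed` and `evidence_notes`.
#' @export
assess_coding <- function(variants, config = pipeline_config(),
                          rules = default_tool_rules(config)) {
  df <- as.data.frame(variants)
  n <- nrow(df)
  get_col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, n)
  tier <- cadd_tier(get_col("cadd_phred"), config)
  verdict_mat <- classify_panel_matrix(variants, rules)
  n_available <- rowSums(verdict_mat != "unavailable")
  n_damaging <- rowSums(verdict_mat == "damaging")
  fraction <- ifelse(n_available > 0, n_damaging / n_available, NA_real_)
  cons_verdict <- ifelse(n_available < config$min_tools_available,
                         "insufficient",
                         ifelse(fraction >= config$consensus_fraction,
                                "deleterious", "tolerated"))
  cons <- conservation_flags(get_col("gerp"), get_col("phastcons"),
                             get_col("phylop"), config)
  intol <- intolerance_votes(get_col("rvis_esp"), get_col("rvis_exac"),
                             get_col("rvis_local"), get_col("pli"),
                             get_col("z_mis"), config)
  aa_from <- get_col("aa_from")
  aa_to <- get_col("aa_to")
  if (all(is.na(aa_from)) && "aa_change" %in% names(df)) {
    aa <- parse_aa_change(df$aa_change)
    aa_from <- aa$from
    aa_to <- aa$to
  }
  gr_dist <- rep(NA_integer_, n)
  gr_cat <- rep(NA_character_, n)
  has_aa <- !is.na(aa_from) & !is.na(aa_to)
  if (any(has_aa)) {
    g <- grantham(aa_from[has_aa], aa_to[has_aa], config$grantham_bins)
    gr_dist[has_aa] <- g$distance
    gr_cat[has_aa] <- as.character(g$category)
  }

  is_missense <- !is.na(df$exonic_class) &
    df$exonic_class == "nonsynonymous_SNV"
  gate_failed <- rep(NA_character_, n)
  gate_failed[!is_missense] <- "coding_class"
  cadd_ok <- tier >= "top10" & tier != "unscored"
  gate_failed[is.na(gate_failed) & !cadd_ok] <- "cadd"
  consensus_ok <- cons_verdict == "deleterious"
  gate_failed[is.na(gate_failed) & !consensus_ok] <- "consensus"
  intol_ok <- intol$n_intolerant >= 1
  gate_failed[is.na(gate_failed) & !intol_ok] <- "intolerance"
  if (config$conservation_is_hard_gate) {
    conserv_ok <- cons$n_conserved >= config$conservation_min_flags
    gate_failed[is.na(gate_failed) & !conserv_ok] <- "conservation"
  }
  passes <- is.na(gate_failed)

  notes <- paste0(
    "cadd=", as.character(tier),
    "; consensus=", cons_verdict, " (", n_damaging, "/", n_available, ")",
    "; intolerant_votes=", intol$n_intolerant, "/", intol$n_scores_present,
    "; conserved_flags=", cons$n_conserved,
    ifelse(is.na(gr_dist), "",
           paste0("; grantham=", gr_dist, " (", gr_cat, ")")))
  notes[!is_missense] <- paste0("not a missense SNV (",
                                df$exonic_class[!is_missense], ")")

  out <- data.frame(variant_id = variant_id(df),
                    gene = get_col("gene"),
                    cadd_phred = as.numeric(get_col("cadd_phred")),
                    cadd_tier = as.character(tier),
                    consensus_n_damaging = as.integer(n_damaging),
                    consensus_n_available = as.integer(n_available),
                    consensus_fraction = fraction,
                    consensus_verdict = cons_verdict,
                    stringsAsFactors = FALSE)
  out <- cbind(out, cons, intol)
  out$grantham_distance <- gr_dist
  out$grantham_category <- gr_cat
  out$passes <- passes
  out$gate_failed <- gate_failed
  out$evidence_notes <- notes
  out
}
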