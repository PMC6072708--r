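#' Run the full prioritization funnel
#'
#' Executes the cascade in fixed order: site/sample quality filter,
#' population-frequency filter, pedigree segregation, location routing,
#' repeat-indel exclusion, per-route assessment (CADD gate, predictor
#' consensus, intolerance and optional conservation gate on the coding
#' route; miRNA-site / TFBS evidence on the UTR routes; regulatory-region
#' evidence on the non-coding route) and ranking. Every dropped variant is
#' attributed to exactly one stage; given identical inputs and
#' configuration the result is deterministic.
#'
#' @param variants a `variant_table` (from [read_vcf()],
#'   [read_annotated_table()] or built in code).
#' @param pedigree a `pedigree` from [read_ped()].
#' @param region_sets named list of `region_set`s; a set labelled `repeat`
#'   drives repeat-indel exclusion, the regulatory labels feed the
#'   non-coding route. May be empty.
#' @param config a [pipeline_config()].
#' @param rule a [segregation_rule()]; defaults to the strict rule with the
#'   config's tolerances.
#' @return a `funnel_run`: list with `candidates` (ranked data.frame of
#'   surviving variants with their assessments), `funnel` (stage/count/
#'   percent table), `routes` (per-route counts after segregation),
#'   `fates` (data.frame attributing every input variant to `pass` or its
#'   dropping stage) and `config`.
#' @export
run_pipeline <- function(variants, pedigree, region_sets = list(),
                         config = pipeline_config(), rule = NULL) {
  if (is.null(rule)) {
    rule <- segregation_rule(
      max_noncarrier_cases = config$max_noncarrier_cases,
      max_carrier_controls = config$max_carrier_controls)
  }
  ids <- variant_id(as.data.frame(variants))
  if (anyDuplicated(ids)) {
    stop("duplicate variant record(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  fate <- stats::setNames(rep(NA_character_, length(ids)), ids)
  mark <- function(surviving_ids, stage) {
    gone <- is.na(fate) & !names(fate) %in% surviving_ids
    fate[gone] <<- stage
  }
  stage_counts <- c(input = nrow(variants))

  q <- with_stage("quality", apply_quality_filter(variants, config,
                                                  pedigree))
  mark(variant_id(as.data.frame(q)), "quality")
  stage_counts["quality"] <- nrow(q)
  message("stage quality: ", nrow(q), "/", nrow(variants), " survive")

  f <- with_stage("frequency", apply_frequency_filter(q, config))
  mark(variant_id(as.data.frame(f)), "frequency")
  stage_counts["frequency"] <- nrow(f)
  message("stage frequency: ", nrow(f), "/", nrow(q), " survive")

  s <- with_stage("segregation", segregate(f, pedigree, rule))
  mark(variant_id(as.data.frame(s)), "segregation")
  stage_counts["segregation"] <- nrow(s)
  message("stage segregation: ", nrow(s), "/", nrow(f), " survive")

  route <- if (nrow(s) > 0) route_variant(s) else
    factor(character(0), levels = ROUTES)
  routes <- table(route)

  repeat_set <- Filter(function(r) inherits(r, "region_set") &&
                         r$label == "repeat", region_sets)
  if (length(repeat_set) > 0) {
    split <- exclude_repeat_indels(s, repeat_set[[1]],
                                   chr_prefix = config$chr_prefix)
    mark(variant_id(as.data.frame(split$kept)), "repeat_indel")
    route <- route[!variant_id(as.data.frame(s)) %in%
                     variant_id(as.data.frame(split$excluded))]
    s <- split$kept
  }
  stage_counts["repeat_indel"] <- nrow(s)

  s_df <- as.data.frame(s)
  candidates <- list()

  ## coding route: CADD tier gate, then consensus / intolerance /
  ## (optionally) conservation, via the full coding assessment
  coding <- s[route == "coding_route", , drop = FALSE]
  coding <- restore_variant_table(coding, samples(s))
  n_cadd <- n_consensus <- n_intol <- 0L
  if (nrow(coding) > 0) {
    assess <- assess_coding(coding, config)
    for (i in seq_len(nrow(assess))) {
      if (!assess$passes[i]) fate[assess$variant_id[i]] <- assess$gate_failed[i]
    }
    n_cadd <- sum(!assess$gate_failed %in% c("coding_class", "cadd"))
    n_consensus <- sum(!assess$gate_failed %in%
                         c("coding_class", "cadd", "consensus"))
    n_intol <- sum(!assess$gate_failed %in%
                     c("coding_class", "cadd", "consensus", "intolerance"))
    keep <- assess$passes
    if (any(keep)) {
      cd <- cbind(coding_key_columns(as.data.frame(coding)[keep, ]),
                  route = "coding_route",
                  assess[keep, setdiff(names(assess),
                                       c("variant_id", "gene",
                                         "cadd_phred"))])
      candidates[[length(candidates) + 1L]] <- cd
    }
  }
  stage_counts["coding_cadd"] <- n_cadd
  stage_counts["coding_consensus"] <- n_consensus
  stage_counts["coding_intolerance"] <- n_intol

  ## UTR routes: CADD gate applies, then route-specific evidence
  for (rt in c("utr5_route", "utr3_route")) {
    sub <- restore_variant_table(s[route == rt, , drop = FALSE],
                                 samples(s))
    if (nrow(sub) == 0) next
    sub_ids <- variant_id(as.data.frame(sub))
    tier <- cadd_tier(if ("cadd_phred" %in% names(sub)) sub$cadd_phred
                      else rep(NA_real_, nrow(sub)), config)
    cadd_ok <- tier >= "top10"
    fate[sub_ids[!cadd_ok]] <- "cadd"
    flag <- if (rt == "utr3_route") assess_utr3(sub, config) else
      assess_utr5(sub)
    fate[sub_ids[cadd_ok & !flag]] <- "regulatory_evidence"
    keep <- cadd_ok & flag
    if (any(keep)) {
      cd <- cbind(coding_key_columns(as.data.frame(sub)[keep, ]),
                  route = rt, cadd_tier = as.character(tier)[keep],
                  passes = TRUE)
      candidates[[length(candidates) + 1L]] <- cd
    }
  }

  ## non-coding route: regulatory-region evidence, no CADD gate
  nc <- restore_variant_table(s[route == "noncoding_route", , drop = FALSE],
                              samples(s))
  if (nrow(nc) > 0) {
    nc_ids <- variant_id(as.data.frame(nc))
    hits <- regulatory_hits(nc, region_sets, chr_prefix = config$chr_prefix)
    keep <- hits$n_regulatory >= 1
    fate[nc_ids[!keep]] <- "regulatory_evidence"
    if (any(keep)) {
      cd <- cbind(coding_key_columns(as.data.frame(nc)[keep, ]),
                  route = "noncoding_route",
                  hits[keep, , drop = FALSE], passes = TRUE)
      candidates[[length(candidates) + 1L]] <- cd
    }
  }

  cand <- if (length(candidates) > 0) {
    rank_variants(do.call(rbind_fill, candidates))
  } else {
    data.frame()
  }
  if (nrow(cand) > 0) fate[cand$variant_id] <- "pass"
  stage_counts["final"] <- nrow(cand)
  message("final candidates: ", nrow(cand))

  funnel <- build_funnel(stage_counts)
  fates <- data.frame(variant_id = names(fate), fate = unname(fate),
                      stringsAsFactors = FALSE)
  structure(list(candidates = cand, funnel = funnel,
                 routes = as.integer(routes)[match(ROUTES, names(routes))],
                 fates = fates, config = config),
            class = "funnel_run")
}

#' @keywords internal
coding_key_columns <- function(df) {
  data.frame(variant_id = variant_id(df), chrom = df$chrom, pos = df$pos,
             ref = df$ref, alt = df$alt,
             gene = if ("gene" %in% names(df)) df$gene else NA_character_,
             region_class = df$region_class,
             exonic_class = df$exonic_class,
             cadd_phred = if ("cadd_phred" %in% names(df)) df$cadd_phred
             else NA_real_,
             n_cases_carrying = df$n_cases_carrying,
             n_unknown_carrying = df$n_unknown_carrying,
             stringsAsFactors = FALSE)
}

## rbind data.frames with differing columns, filling with NA.
#' @keywords internal
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  filled <- lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, filled)
}

#' @keywords internal
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Rank assessed variants
#'
#' Deterministic ordering of assessed variants: passing records first, then
#' descending CADD PHRED, consensus fraction, intolerance-vote count and
#' Grantham distance (absent values sort last), with a final ascending
#' (chrom, pos, alt) tie-break so that reruns and input permutations give
#' identical output.
#'
#' @param assessed data.frame with at least `chrom`, `pos`, `alt`; uses
#'   `passes`, `cadd_phred`, `consensus_fraction`, `n_intolerant`,
#'   `grantham_distance` when present.
#' @return the same data.frame ordered, with a contiguous `rank` column.
#' @export
rank_variants <- function(assessed) {
  if (nrow(assessed) == 0) {
    assessed$rank <- integer(0)
    return(assessed)
  }
  pull <- function(nm, default) {
    v <- if (nm %in% names(assessed)) assessed[[nm]] else
      rep(default, nrow(assessed))
    v[is.na(v)] <- default
    v
  }
  passes <- as.logical(pull("passes", FALSE))
  ord <- order(-passes,
               -pull("cadd_phred", -Inf),
               -pull("consensus_fraction", -Inf),
               -pull("n_intolerant", -Inf),
               -pull("grantham_distance", -Inf),
               chrom_rank(assessed$chrom),
               assessed$pos,
               assessed$alt)
  out <- assessed[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## Natural chromosome order: 1..22, X, Y, MT, then anything else lexically.
#' @keywords internal
chrom_rank <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  canonical <- c(as.character(1:22), "X", "Y", "MT", "M")
  r <- match(chrom, canonical)
  r[is.na(r)] <- length(canonical) + xtfrm(chrom[is.na(r)])
  r
}

#' @keywords internal
build_funnel <- function(counts) {
  stages <- names(counts)
  pct <- rep(NA_real_, length(counts))
  for (i in seq_along(counts)[-1]) {
    pct[i] <- if (counts[i - 1] > 0) {
      funnel_fraction(counts[i - 1], counts[i])
    } else {
      NA_real_
    }
  }
  data.frame(stage = stages, count = as.integer(counts),
             pct_of_previous = pct, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Check the route partition of segregation survivors
#'
#' Conservation of counts: the per-route counts must sum exactly to the
#' number of segregation survivors they partition.
#'
#' @param route_counts integer vector of per-route counts.
#' @param n_segregated expected total.
#' @return `n_segregated`, invisibly, if the partition balances; error
#'   otherwise.
#' @export
check_route_partition <- function(route_counts, n_segregated) {
  total <- sum(route_counts)
  if (total != n_segregated) {
    stop("route counts sum to ", total, " but ", n_segregated,
         " variants survived segregation", call. = FALSE)
  }
  invisible(n_segregated)
}

#' @export
print.funnel_run <- function(x, ...) {
  cat("funnel_run:", nrow(x$candidates), "candidate(s)\n\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

#' Write the funnel report
#'
#' Writes the stage/count/percentage table both as a human-readable TSV
#' (`<path>.tsv`) and a machine-readable JSON (`<path>.json`). The JSON
#' also carries the per-route counts and validates their partition against
#' the segregation-survivor count before writing.
#'
#' @param run a `funnel_run` from [run_pipeline()], or a funnel data.frame
#'   with columns `stage`, `count`, `pct_of_previous`.
#' @param path output path prefix (without extension).
#' @return invisibly, the two paths written.
#' @export
write_funnel <- function(run, path) {
  if (inherits(run, "funnel_run")) {
    funnel <- run$funnel
    routes <- stats::setNames(as.list(run$routes), ROUTES)
    n_seg <- funnel$count[funnel$stage == "segregation"]
    check_route_partition(unlist(routes), n_seg)
  } else {
    funnel <- run
    routes <- NULL
  }
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(funnel, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  payload <- list(stages = funnel)
  if (!is.null(routes)) payload$routes <- routes
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
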