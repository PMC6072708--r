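#' Simulation parameters for a synthetic cohort
#'
#' Describes a synthetic annotated cohort with planted ground truth: a
#' family of `n_cases` sequenced cases, `n_controls` unaffected controls
#' and `n_exclusion_cases` unrelated cases, `n_planted` variants built to
#' pass every gate of the funnel, and one decoy class per named gate, each
#' decoy built to fail exactly that gate and no other. Decoys are drawn
#' adversarially close to their gate (CADD just at or below 10, frequencies
#' just at or above 0.1%, consensus 7/12) to exercise the strict/inclusive
#' boundary semantics. Scores are sampled inside each predictor's published
#' range; CADD for passing profiles comes from the upper tail of its
#' right-skewed scale and frequencies of rare variants concentrate below
#' 0.1%.
#'
#' @param n_planted number of full-pass planted variants.
#' @param decoys named integer vector of per-class decoy counts; classes
#'   are `quality`, `frequency`, `segregation`, `cadd`, `consensus`,
#'   `intolerance`, `repeat_indel`.
#' @param n_cases,n_controls,n_exclusion_cases family design.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_planted = 1,
                       decoys = c(quality = 800, frequency = 800,
                                  segregation = 900, cadd = 800,
                                  consensus = 800, intolerance = 600,
                                  repeat_indel = 300),
                       n_cases = 2, n_controls = 1, n_exclusion_cases = 1,
                       seed = 1) {
  known <- c("quality", "frequency", "segregation", "cadd", "consensus",
             "intolerance", "repeat_indel")
  unknown <- setdiff(names(decoys), known)
  if (length(unknown) > 0) {
    stop("unknown decoy class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (n_planted < 0 || any(decoys < 0)) {
    stop("variant counts must be >= 0", call. = FALSE)
  }
  if (n_cases < 1) {
    stop("the family design needs at least one case", call. = FALSE)
  }
  structure(list(n_planted = as.integer(n_planted),
                 decoys = stats::setNames(as.integer(decoys), names(decoys)),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_exclusion_cases = as.integer(n_exclusion_cases),
                 seed = as.integer(seed)),
            class = "sim_params")
}

## Run expr under a fixed seed without disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic annotated cohort with planted ground truth
#'
#' Builds an annotated variant table, matching pedigree, a synthetic
#' repeat-region set and a truth table listing every variant's intended
#' fate. Planted variants satisfy every gate; each decoy fails exactly its
#' named gate, so a faithful funnel must recover the planted set exactly
#' and attribute every decoy's drop to its intended stage.
#'
#' @param params a [sim_params()].
#' @param config the [pipeline_config()] the cohort is built against
#'   (profiles are constructed relative to its thresholds).
#' @return a `synthetic_cohort`: list with `variants` (a `variant_table`),
#'   `pedigree`, `region_sets` (named list holding the synthetic `repeat`
#'   set), `truth` (data.frame `variant_id`, `class`, `expected_fate`) and
#'   `params`.
#' @export
generate_cohort <- function(params = sim_params(),
                            config = pipeline_config()) {
  stopifnot(inherits(params, "sim_params"))
  n_tools_planted <- length(TOOL_PANEL)
  if (n_tools_planted < config$min_tools_available) {
    stop("planted consensus profile unsatisfiable: panel smaller than ",
         "min_tools_available", call. = FALSE)
  }
  with_seed(params$seed, build_cohort(params, config))
}

#' @keywords internal
build_cohort <- function(params, config) {
  case_ids <- sprintf("CASE%d", seq_len(params$n_cases))
  control_ids <- if (params$n_controls > 0) {
    sprintf("CTRL%d", seq_len(params$n_controls))
  } else character(0)
  excl_ids <- if (params$n_exclusion_cases > 0) {
    sprintf("EXCL%d", seq_len(params$n_exclusion_cases))
  } else character(0)
  all_ids <- c(case_ids, control_ids, excl_ids)
  pedigree <- data.frame(
    family = "FAM1", id = all_ids, father = "0", mother = "0",
    sex = rep("0", length(all_ids)),
    role = c(rep("case", length(case_ids)),
             rep("control", length(control_ids)),
             rep("exclusion_case", length(excl_ids))),
    stringsAsFactors = FALSE)
  class(pedigree) <- c("pedigree", "data.frame")

  classes <- c(rep("planted", params$n_planted),
               rep(names(params$decoys), params$decoys))
  n <- length(classes)
  if (n == 0) stop("cohort has zero variants", call. = FALSE)

  rules <- default_tool_rules(config)
  bases <- c("A", "C", "G", "T")

  ## positions: repeat-indel decoys live on chromosome 2 so their synthetic
  ## repeat intervals can never touch the other classes
  is_repeat <- classes == "repeat_indel"
  chrom <- ifelse(is_repeat, "2",
                  as.character(sample(c(1:22), n, replace = TRUE)))
  chrom[is_repeat] <- "2"
  pos <- integer(n)
  pos[!is_repeat] <- sample.int(2e8, sum(!is_repeat))
  pos[is_repeat] <- 10000000L + seq_len(sum(is_repeat)) * 1000L

  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ## repeat decoys are deletions spanning 4 reference bases
  ref[is_repeat] <- paste0(alt[is_repeat],
                           vapply(seq_len(sum(is_repeat)), function(i)
                             paste(sample(bases, 3, replace = TRUE),
                                   collapse = ""), character(1)))

  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  df$qual <- stats::runif(n, 50, 1000)
  df$region_class <- "exonic"
  df$exonic_class <- "nonsynonymous_SNV"
  df$gene <- sprintf("GENE%05d", seq_len(n))
  df$is_indel <- nchar(df$ref) != nchar(df$alt)
  aa <- t(vapply(seq_len(n), function(i)
    sample(GRANTHAM_ORDER, 2, replace = FALSE), character(2)))
  df$aa_change <- paste0(aa[, 1], sample(50:900, n, replace = TRUE),
                         aa[, 2])
  df$aa_from <- aa[, 1]
  df$aa_to <- aa[, 2]
  df$cadd_phred <- stats::runif(n, config$cadd_top1 + 2,
                                config$cadd_top01 + 10)
  df$maf_exac <- ifelse(stats::runif(n) < 0.5, NA,
                        stats::runif(n, 0, config$max_maf * 0.5))
  df$maf_1kg <- ifelse(stats::runif(n) < 0.5, NA,
                       stats::runif(n, 0, config$max_maf * 0.5))
  ## conservation: high for every profile (conservation is evidence, not a
  ## default gate); phyloP sits at or above its inclusive cutoff
  df$gerp <- stats::runif(n, config$gerp_min + 0.5, 6.17)
  df$phastcons <- stats::runif(n, config$phastcons_min + 0.1, 1)
  df$phylop <- stats::runif(n, config$phylop_min, 6)

  ## intolerance: one guaranteed vote (pLI) plus random leanings
  df$pli <- stats::runif(n, config$pli_intolerant, 1)
  df$rvis_esp <- stats::runif(n, -3, 1)
  df$rvis_exac <- stats::runif(n, -3, 1)
  df$rvis_local <- stats::runif(n, -3, 1)
  df$z_mis <- stats::runif(n, -2, 4)

  ## predictor panel: start everything at a passing consensus (>= 60% of 12)
  n_damaging <- sample(8:12, n, replace = TRUE)
  tool_scores <- sample_panel_scores(n_damaging, rep(12L, n), rules)
  for (nm in TOOL_PANEL) df[[nm]] <- tool_scores[[nm]]

  ## genotypes: segregating pattern (all cases carry, nobody else)
  for (s in pedigree$id) {
    carrier <- pedigree$role[pedigree$id == s] == "case"
    df[[paste0("gt_", s)]] <- rep(if (carrier) "het" else "hom_ref", n)
    df[[paste0("dp_", s)]] <- sample(20:60, n, replace = TRUE)
  }

  ## now break exactly one gate per decoy class
  idx <- function(cl) which(classes == cl)

  i <- idx("quality")
  if (length(i) > 0) {
    ## mostly sub-threshold QUAL, some exactly at the boundary, and a few
    ## well-covered sites whose pedigree calls are all masked by low depth
    df$qual[i] <- stats::runif(length(i), 1, config$min_qual)
    at_boundary <- i[seq_along(i) %% 5 == 0]
    df$qual[at_boundary] <- config$min_qual
    all_masked <- i[seq_along(i) %% 7 == 0]
    if (length(all_masked) > 0) {
      df$qual[all_masked] <- stats::runif(length(all_masked), 50, 1000)
      for (s in pedigree$id) {
        df[[paste0("dp_", s)]][all_masked] <-
          sample(0:(config$min_depth - 1), length(all_masked),
                 replace = TRUE)
      }
    }
  }

  i <- idx("frequency")
  if (length(i) > 0) {
    df$maf_exac[i] <- stats::runif(length(i), config$max_maf * 1.1,
                                   config$max_maf * 50)
    at_boundary <- i[seq_along(i) %% 5 == 0]
    df$maf_exac[at_boundary] <- config$max_maf
  }

  i <- idx("segregation")
  if (length(i) > 0) {
    ## alternate between a non-carrying case and a carrying forbidden-role
    ## sample (or a second non-carrying case if the family has no controls)
    half <- i[seq_along(i) %% 2 == 0]
    rest <- setdiff(i, half)
    df[[paste0("gt_", case_ids[1])]][half] <- "hom_ref"
    forb <- c(control_ids, excl_ids)
    if (length(forb) > 0) {
      df[[paste0("gt_", forb[1])]][rest] <- "het"
    } else {
      df[[paste0("gt_", case_ids[1])]][rest] <- "hom_ref"
    }
  }

  i <- idx("cadd")
  if (length(i) > 0) {
    df$cadd_phred[i] <- stats::runif(length(i), 0, config$cadd_gate)
    at_boundary <- i[seq_along(i) %% 5 == 0]
    df$cadd_phred[at_boundary] <- config$cadd_gate
  }

  i <- idx("consensus")
  if (length(i) > 0) {
    ## adversarial: 7/12 = 0.583 just misses the 60% consensus; a slice of
    ## the class instead has too few predictors scored (insufficient)
    low <- sample(0:7, length(i), replace = TRUE)
    low[seq_along(i) %% 4 == 0] <- 7L
    avail <- rep(12L, length(i))
    insufficient <- seq_along(i) %% 6 == 0
    avail[insufficient] <- sample(0:(config$min_tools_available - 1),
                                  sum(insufficient), replace = TRUE)
    low[insufficient] <- pmin(low[insufficient], avail[insufficient])
    sc <- sample_panel_scores(low, avail, rules)
    for (nm in TOOL_PANEL) df[[nm]][i] <- sc[[nm]]
  }

  i <- idx("intolerance")
  if (length(i) > 0) {
    ## every present score leans tolerant; some scores absent entirely
    df$pli[i] <- stats::runif(length(i), 0, config$pli_tolerant)
    df$rvis_esp[i] <- stats::runif(length(i), 0.1, 3)
    df$rvis_exac[i] <- stats::runif(length(i), 0.1, 3)
    df$rvis_local[i] <- stats::runif(length(i), 0.1, 3)
    df$z_mis[i] <- stats::runif(length(i), -4, -0.1)
    drop_some <- i[seq_along(i) %% 3 == 0]
    df$rvis_local[drop_some] <- NA
    df$z_mis[drop_some] <- NA
  }

  i <- idx("repeat_indel")
  repeat_regions <- NULL
  if (length(i) > 0) {
    ## indels already placed on chromosome 2; cover each with an interval
    df$region_class[i] <- rep(c("exonic", "ncRNA", "utr3"),
                              length.out = length(i))
    df$exonic_class[i] <- ifelse(df$region_class[i] == "exonic",
                                 "nonframeshift_deletion", "none")
    df$aa_change[i] <- NA
    df$aa_from[i] <- NA
    df$aa_to[i] <- NA
    repeat_regions <- region_set("repeat", chrom = "2",
                                 start = df$pos[i] - 5L,
                                 end = df$pos[i] + nchar(df$ref[i]) + 5L)
  }

  variants <- variant_table(df, samples = pedigree$id)
  truth <- data.frame(
    variant_id = variant_id(as.data.frame(variants)),
    class = classes,
    expected_fate = ifelse(classes == "planted", "pass", classes),
    stringsAsFactors = FALSE)
  region_sets <- if (is.null(repeat_regions)) list() else
    list(repeat_set = repeat_regions)
  structure(list(variants = variants, pedigree = pedigree,
                 region_sets = region_sets,
                 truth = truth, params = params),
            class = "synthetic_cohort")
}

## Sample predictor scores realizing, per variant, n_damaging damaging
## verdicts among n_available scored predictors (panel order shuffled per
## variant; unscored predictors are NA). Scores stay inside each
## predictor's published range, strictly on the intended side of its cutoff.
#' @keywords internal
sample_panel_scores <- function(n_damaging, n_available, rules) {
  n <- length(n_damaging)
  stopifnot(length(n_available) == n, all(n_damaging <= n_available))
  cols <- stats::setNames(
    lapply(TOOL_PANEL, function(nm)
      if (rules[[nm]]$mode == "categorical") rep(NA_character_, n)
      else rep(NA_real_, n)),
    TOOL_PANEL)
  for (v in seq_len(n)) {
    scored <- sample(TOOL_PANEL, n_available[v])
    damaging_tools <- if (n_damaging[v] > 0) {
      scored[seq_len(n_damaging[v])]
    } else character(0)
    for (nm in scored) {
      cols[[nm]][v] <- sample_tool_score(rules[[nm]],
                                         nm %in% damaging_tools)
    }
  }
  cols
}

#' @keywords internal
sample_tool_score <- function(rule, damaging) {
  if (rule$mode == "categorical") {
    pool <- if (damaging) rule$damaging_categories else
      setdiff(rule$vocabulary, rule$damaging_categories)
    return(sample(pool, 1))
  }
  lo <- rule$range[1]
  hi <- rule$range[2]
  eps <- (hi - lo) * 1e-3
  if (rule$mode == "numeric_low_is_damaging") {
    if (damaging) {
      stats::runif(1, lo, rule$cutoff - if (rule$cutoff_inclusive) 0 else eps)
    } else {
      stats::runif(1, rule$cutoff + eps, hi)
    }
  } else {
    if (damaging) {
      stats::runif(1, rule$cutoff + if (rule$cutoff_inclusive) 0 else eps, hi)
    } else {
      stats::runif(1, lo, rule$cutoff - eps)
    }
  }
}

#' Write a synthetic cohort to files
#'
#' Writes the cohort in the dialects the readers consume: the annotated
#' table as TSV, the pedigree as 7-column PED (role overrides in column 7),
#' the synthetic repeat set as BED and the truth table as TSV.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             ped = file.path(dir, "family.ped"),
             truth = file.path(dir, "truth.tsv"))
  if (!is.null(cohort$region_sets$repeat_set)) {
    paths["repeats"] <- file.path(dir, "repeats.bed")
  }
  write_annotated_table(cohort$variants, paths["variants"])
  ped <- cohort$pedigree
  phenotype <- c(case = "2", control = "1", exclusion_case = "2",
                 unknown = "0")[ped$role]
  role7 <- ifelse(ped$role == "exclusion_case", "exclude", ped$role)
  utils::write.table(
    data.frame(ped$family, ped$id, ped$father, ped$mother, ped$sex,
               phenotype, role7),
    paths["ped"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  if ("repeats" %in% names(paths)) {
    gr <- cohort$region_sets$repeat_set$ranges
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
      paths["repeats"], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' The packaged family fixture
#'
#' Loads the packaged seven-variant family table: the top-ranked germline
#' variants of a three-sample thyroid-cancer family (two distantly related
#' cases plus one unrelated case) with their printed loci, region
#' annotations, exonic classifications, CADD PHRED scores and carrier
#' counts (every variant carried by the 2 related cases and absent from the
#' unrelated one). Printed fields are reproduced as published; QUAL, depths,
#' genotype calls, predictor scores and intolerance scores are synthetic
#' reconstructions consistent with the reported evidence counts (9/12
#' damaging and 4/5 intolerant for the CPXM1 missense candidate; 3/12 for
#' ZBTB41; all-tolerant intolerance profiles for C1orf27 and FAM129A), and
#' the repeat region set is a synthetic stand-in covering the three indel
#' loci reported to lie in repetitive regions.
#'
#' @return list with `variants` (a `variant_table`), `pedigree` and
#'   `region_sets` (holding the synthetic `repeat` set).
#' @export
table3_fixture <- function() {
  base <- system.file("extdata", package = "varfunnel", mustWork = TRUE)
  list(variants = read_annotated_table(
         file.path(base, "ptc_family_variants.tsv")),
       pedigree = read_ped(file.path(base, "ptc_family.ped")),
       region_sets = list(
         repeat_set = read_bed(
           file.path(base, "ptc_family_repeats_synthetic.bed"), "repeat")))
}
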