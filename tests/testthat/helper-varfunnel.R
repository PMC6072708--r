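## Shared fixture builders for the test suite. Everything is generated in
## code; no binary fixtures.

trio_pedigree <- function() {
  ped <- data.frame(
    family = "FAM1",
    id = c("EX1", "C1", "C2"),
    father = "0", mother = "0", sex = "0",
    role = c("exclusion_case", "case", "case"),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## Minimal variant-table builder: one row per element of the argument
## vectors, trio genotype columns defaulting to the segregating pattern.
make_variants <- function(n = 1, chrom = "1", pos = seq_len(n) * 100,
                          ref = "A", alt = "T", qual = 100,
                          region_class = "exonic",
                          exonic_class = NULL,
                          gt_EX1 = "hom_ref", gt_C1 = "het",
                          gt_C2 = "het",
                          dp_EX1 = 30L, dp_C1 = 30L, dp_C2 = 30L, ...) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   qual = qual, region_class = region_class,
                   stringsAsFactors = FALSE)
  df <- df[rep(seq_len(nrow(df)), length.out = n), , drop = FALSE]
  df$pos <- rep_len(pos, n)
  df$exonic_class <- if (is.null(exonic_class)) {
    ifelse(df$region_class == "exonic", "nonsynonymous_SNV", "none")
  } else {
    rep_len(exonic_class, n)
  }
  df$is_indel <- nchar(df$ref) != nchar(df$alt)
  df$gt_EX1 <- rep_len(gt_EX1, n)
  df$gt_C1 <- rep_len(gt_C1, n)
  df$gt_C2 <- rep_len(gt_C2, n)
  df$dp_EX1 <- rep_len(dp_EX1, n)
  df$dp_C1 <- rep_len(dp_C1, n)
  df$dp_C2 <- rep_len(dp_C2, n)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  variant_table(df, samples = c("EX1", "C1", "C2"))
}

## Random genotype table over the trio for property tests.
random_genotype_table <- function(n, seed) {
  set.seed(seed)
  calls <- c("hom_ref", "het", "hom_alt", "missing")
  make_variants(n,
                pos = sample.int(1e6, n),
                qual = runif(n, 1, 300),
                gt_EX1 = sample(calls, n, replace = TRUE),
                gt_C1 = sample(calls, n, replace = TRUE),
                gt_C2 = sample(calls, n, replace = TRUE),
                dp_C1 = sample(0:40, n, replace = TRUE),
                maf_exac = ifelse(runif(n) < 0.3, NA,
                                  runif(n, 0, 0.01)))
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
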