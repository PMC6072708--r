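cfg <- pipeline_config()

test_that("interval intersection honors the half-open footprint", {
  rs <- region_set("enhancer", "1", 100, 200)
  hit <- intersect_regions(make_variants(1, pos = 150), rs)
  expect_equal(nrow(hit), 1)
  ## 1-based position 200 is half-open [199, 200): still inside [100, 200)
  expect_equal(nrow(intersect_regions(make_variants(1, pos = 200), rs)), 1)
  expect_equal(nrow(intersect_regions(make_variants(1, pos = 201), rs)), 0)
  ## 1-based position 100 is [99, 100): one base before the interval? no --
  ## BED start 100 means the interval covers 0-based 100..199, so 1-based
  ## position 101 is its first base and 100 misses
  expect_equal(nrow(intersect_regions(make_variants(1, pos = 101), rs)), 1)
  expect_equal(nrow(intersect_regions(make_variants(1, pos = 100), rs)), 0)
  ## an indel footprint spans its reference length
  del <- make_variants(1, pos = 95, ref = "AACCGGTT", alt = "A")
  expect_equal(nrow(intersect_regions(del, rs)), 1)
})

test_that("sweep intersection equals the brute-force all-pairs oracle", {
  brute <- function(variants, rs) {
    df <- as.data.frame(variants)
    gr <- rs$ranges
    hits <- list()
    for (i in seq_len(nrow(df))) {
      v_start <- df$pos[i] - 1            # 0-based half-open
      v_end <- df$pos[i] - 1 + max(nchar(df$ref[i]), 1)
      for (j in seq_along(gr)) {
        if (as.character(GenomicRanges::seqnames(gr))[j] != df$chrom[i]) next
        r_start <- GenomicRanges::start(gr)[j] - 1
        r_end <- GenomicRanges::end(gr)[j]
        if (v_start < r_end && r_start < v_end) {
          hits[[length(hits) + 1]] <- c(i, j)
        }
      }
    }
    if (length(hits) == 0) return(matrix(numeric(0), ncol = 2))
    m <- do.call(rbind, hits)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  for (seed in 1:100) {
    set.seed(seed)
    n_v <- sample(10:50, 1)
    n_r <- sample(5:20, 1)
    v <- make_variants(n_v, chrom = sample(c("1", "2"), n_v, replace = TRUE),
                       pos = sample.int(2000, n_v),
                       ref = sample(c("A", "AGGTC"), n_v, replace = TRUE),
                       alt = "T", region_class = "intronic")
    start <- sample.int(2000, n_r)
    rs <- region_set("promoter",
                     chrom = sample(c("1", "2"), n_r, replace = TRUE),
                     start = start, end = start + sample.int(50, n_r))
    got <- intersect_regions(v, rs)
    want <- brute(v, rs)
    expect_equal(unname(cbind(got$variant_idx, got$interval_idx)),
                 unname(want))
  }
  ## one larger instance
  set.seed(424)
  v <- make_variants(500, pos = sample.int(5e4, 500),
                     region_class = "intergenic")
  start <- sample.int(5e4, 200)
  rs <- region_set("enhancer", "1", start, start + sample.int(300, 200))
  got <- intersect_regions(v, rs)
  want <- brute(v, rs)
  expect_equal(unname(cbind(got$variant_idx, got$interval_idx)),
               unname(want))
})

test_that("chromosome-name mismatches warn and can be normalized", {
  v <- make_variants(1, chrom = "1", pos = 150, region_class = "intronic")
  rs <- region_set("enhancer", "chr1", 100, 200)
  expect_warning(none <- intersect_regions(v, rs), "chr-prefix")
  expect_equal(nrow(none), 0)
  expect_equal(nrow(intersect_regions(v, rs, chr_prefix = "strip")), 1)
  expect_equal(nrow(intersect_regions(v, rs, chr_prefix = "add")), 1)
})

test_that("repeat exclusion removes only indels inside repeats", {
  rep_set <- region_set("repeat", "1", 100, 200)
  del_in <- make_variants(1, pos = 150, ref = "ACGTA", alt = "A",
                          region_class = "intronic")
  out <- exclude_repeat_indels(del_in, rep_set)
  expect_equal(nrow(out$kept), 0)
  expect_equal(nrow(out$excluded), 1)
  expect_equal(out$excluded$exclusion_reason, "indel_in_repeat")

  snv_in <- make_variants(1, pos = 150, region_class = "intronic")
  expect_equal(nrow(exclude_repeat_indels(snv_in, rep_set)$kept), 1)

  del_out <- make_variants(1, pos = 500, ref = "ACGTA", alt = "A",
                           region_class = "intronic")
  expect_equal(nrow(exclude_repeat_indels(del_out, rep_set)$kept), 1)

  ## kept and excluded partition the input
  set.seed(8)
  mix <- make_variants(100, pos = sample.int(1000, 100),
                       ref = sample(c("A", "ACGT"), 100, replace = TRUE),
                       region_class = "intronic")
  parts <- exclude_repeat_indels(mix, rep_set)
  expect_equal(nrow(parts$kept) + nrow(parts$excluded), 100)
  expect_length(intersect(variant_id(as.data.frame(parts$kept)),
                          variant_id(as.data.frame(parts$excluded))), 0)
  expect_error(exclude_repeat_indels(mix, region_set("ucne", "1", 1, 2)),
               "repeat")
})

test_that("UTR evidence flags follow the mirSVR and TFBS rules", {
  u3 <- function(...) make_variants(1, region_class = "utr3", ...)
  expect_true(assess_utr3(u3(mirsvr = -0.5), cfg))
  expect_false(assess_utr3(u3(mirsvr = -0.1), cfg))   # strict "lower than"
  expect_false(assess_utr3(u3(mirsvr = NA_real_), cfg))
  expect_true(assess_utr3(u3(mirsvr = NA_real_, targetscan_site = TRUE),
                          cfg))

  u5 <- function(...) make_variants(1, region_class = "utr5", ...)
  expect_true(assess_utr5(u5(tfbs_change = TRUE)))
  expect_false(assess_utr5(u5(tfbs_change = FALSE)))
  expect_false(assess_utr5(u5(tfbs_change = NA)))
  expect_error(assess_utr5(u5(tfbs_change = "yes")), "logical")
})

test_that("routing partitions every variant into exactly one route", {
  classes <- c("exonic", "splicing", "utr5", "utr3", "ncRNA", "upstream",
               "downstream", "intronic", "intergenic")
  v <- make_variants(9, region_class = classes)
  r <- route_variant(v)
  expect_equal(as.character(r),
               c("coding_route", "coding_route", "utr5_route", "utr3_route",
                 rep("noncoding_route", 5)))
  expect_equal(sum(table(r)), 9)
  bad <- make_variants(1)
  bad$region_class <- NA_character_
  expect_error(route_variant(bad), "region_class")

  ## random tables: route counts always sum to the input count
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:80, 1)
    v <- make_variants(n, pos = sample.int(1e5, n),
                       region_class = sample(classes, n, replace = TRUE))
    expect_equal(sum(table(route_variant(v))), n)
  }
})

test_that("regulatory hits accumulate across region sets", {
  v <- make_variants(2, pos = c(150, 5000), region_class = "intergenic")
  sets <- list(region_set("enhancer", "1", 100, 200),
               region_set("promoter", "1", 120, 180),
               region_set("ucne", "1", 4000, 4500))
  h <- regulatory_hits(v, sets)
  expect_equal(h$n_regulatory, c(2L, 0L))
  expect_true(h$hit_enhancer[1] && h$hit_promoter[1])
  expect_false(h$hit_ucne[1])
})
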