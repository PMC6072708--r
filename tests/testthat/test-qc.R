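cfg <- pipeline_config()
ped <- trio_pedigree()

test_that("quality filter drops low-QUAL sites and masks low-depth calls", {
  v <- make_variants(1, qual = 120)
  expect_equal(nrow(apply_quality_filter(v, cfg, ped)), 1)

  ## QUAL threshold is strict: exactly 20 is removed
  v20 <- make_variants(1, qual = 20)
  expect_equal(nrow(apply_quality_filter(v20, cfg, ped)), 0)

  ## low depth masks that sample's call, keeping the variant
  vlow <- make_variants(1, qual = 50, dp_C1 = 3L)
  out <- apply_quality_filter(vlow, cfg, ped)
  expect_equal(nrow(out), 1)
  expect_equal(out$gt_C1, "missing")
  expect_equal(out$gt_C2, "het")

  ## depth 5 is "minimum 5 reads": kept unmasked
  v5 <- make_variants(1, qual = 50, dp_C1 = 5L)
  expect_equal(apply_quality_filter(v5, cfg, ped)$gt_C1, "het")

  ## a variant whose every pedigree call ends up missing is removed
  vall <- make_variants(1, qual = 50, dp_EX1 = 1L, dp_C1 = 1L, dp_C2 = 1L)
  expect_equal(nrow(apply_quality_filter(vall, cfg, ped)), 0)

  ped_extra <- rbind(ped, data.frame(family = "FAM1", id = "GHOST",
                                     father = "0", mother = "0", sex = "0",
                                     role = "control"))
  expect_error(apply_quality_filter(v, cfg, ped_extra), "GHOST")
})

test_that("frequency filter requires rarity in every database with a value", {
  keep <- make_variants(1, maf_exac = 0.0004)
  expect_equal(nrow(apply_frequency_filter(keep, cfg)), 1)

  ## one common database is enough to remove
  mixed <- make_variants(1, maf_exac = 0.00005, maf_1kg = 0.002)
  expect_equal(nrow(apply_frequency_filter(mixed, cfg)), 0)

  ## absent everywhere counts as rare
  absent <- make_variants(1, maf_exac = NA_real_, maf_1kg = NA_real_)
  expect_equal(nrow(apply_frequency_filter(absent, cfg)), 1)

  ## boundary: exactly 0.1% is not below 0.1%
  boundary <- make_variants(1, maf_exac = 0.001)
  expect_equal(nrow(apply_frequency_filter(boundary, cfg)), 0)

  bad <- make_variants(1, maf_exac = 0.5)
  bad$maf_exac <- 2  # bypass constructor check
  expect_error(apply_frequency_filter(bad, cfg), "\\[0, 1\\]")
})

test_that("quality and frequency filters commute and are idempotent", {
  for (seed in 1:5) {
    v <- random_genotype_table(120, seed)
    qf <- apply_frequency_filter(apply_quality_filter(v, cfg, ped), cfg)
    fq <- apply_quality_filter(apply_frequency_filter(v, cfg), cfg, ped)
    expect_equal(as.data.frame(qf), as.data.frame(fq))
    expect_equal(as.data.frame(apply_quality_filter(qf, cfg, ped)),
                 as.data.frame(qf))
    expect_equal(as.data.frame(apply_frequency_filter(qf, cfg)),
                 as.data.frame(qf))
  }
})

test_that("tightening thresholds never enlarges the surviving set", {
  v <- random_genotype_table(200, 42)
  ids <- function(x) paste(x$chrom, x$pos, sep = "_")
  loose <- pipeline_config(min_qual = 10, max_maf = 0.01)
  tight <- pipeline_config(min_qual = 100, max_maf = 0.0001)
  expect_true(all(ids(apply_quality_filter(v, tight, ped)) %in%
                    ids(apply_quality_filter(v, loose, ped))))
  expect_true(all(ids(apply_frequency_filter(v, tight)) %in%
                    ids(apply_frequency_filter(v, loose))))
})

test_that("pairwise concordance matches a brute-force per-site count", {
  v <- random_genotype_table(200, 11)
  m <- pairwise_concordance(v)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  ## naive double loop oracle
  gt <- as.data.frame(v)[, c("gt_EX1", "gt_C1", "gt_C2")]
  for (i in 1:2) for (j in (i + 1):3) {
    same <- 0; called <- 0
    for (k in seq_len(nrow(gt))) {
      if (gt[k, i] != "missing" && gt[k, j] != "missing") {
        called <- called + 1
        if (gt[k, i] == gt[k, j]) same <- same + 1
      }
    }
    expect_equal(m[i, j], same / called)
  }
})

test_that("concordance hits its identity and disjoint extremes", {
  dup <- make_variants(50, pos = 1:50, gt_C1 = "het", gt_C2 = "het")
  m <- pairwise_concordance(dup, c("C1", "C2"))
  expect_equal(m["C1", "C2"], 1.0)

  opp <- make_variants(50, pos = 1:50, gt_C1 = "het", gt_C2 = "hom_ref")
  expect_equal(pairwise_concordance(opp, c("C1", "C2"))["C1", "C2"], 0.0)

  ## a pair with no co-called site is undefined, not zero
  nc <- make_variants(10, pos = 1:10, gt_C1 = "missing")
  expect_warning(m2 <- pairwise_concordance(nc, c("C1", "C2")),
                 "undefined")
  expect_true(is.na(m2["C1", "C2"]))
  expect_error(pairwise_concordance(dup, "C1"), "two samples")
})
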