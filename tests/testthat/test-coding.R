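cfg <- pipeline_config()

test_that("CADD tiers follow the strict 10/20/30 cutpoints", {
  expect_equal(as.character(cadd_tier(32, cfg)), "top01")
  expect_equal(as.character(cadd_tier(3.11, cfg)), "below")
  expect_equal(as.character(cadd_tier(c(10, 20, 30), cfg)),
               c("below", "top10", "top1"))
  expect_equal(as.character(cadd_tier(c(10.01, 20.01, 30.01), cfg)),
               c("top10", "top1", "top01"))
  expect_equal(as.character(cadd_tier(NA, cfg)), "unscored")
  ## monotone non-decreasing in the score
  scores <- sort(runif(50, 0, 45))
  tiers <- cadd_tier(scores, cfg)
  expect_true(all(diff(as.integer(tiers)) >= 0))
})

test_that("predictor rules encode the published cutoffs", {
  rules <- default_tool_rules(cfg)
  expect_equal(classify_tool(rules$sift, 0.03), "damaging")
  expect_equal(classify_tool(rules$sift, 0.05), "tolerated")  # strict <
  expect_equal(classify_tool(rules$fathmm, -1.5), "damaging") # inclusive <=
  expect_equal(classify_tool(rules$metasvm, 0), "tolerated")  # strict >
  expect_equal(classify_tool(rules$metasvm, 0.01), "damaging")
  expect_equal(classify_tool(rules$metalr, 0.5), "tolerated")
  expect_equal(classify_tool(rules$provean, -2.5), "damaging")
  expect_equal(classify_tool(rules$ri, 5), "damaging")        # inclusive >=
  expect_equal(classify_tool(rules$mutation_taster, c("A", "D", "N", "P")),
               c("damaging", "damaging", "tolerated", "tolerated"))
  expect_equal(classify_tool(rules$mutation_assessor, c("H", "M", "L", "N")),
               c("damaging", "damaging", "tolerated", "tolerated"))
  expect_equal(classify_tool(rules$lrt, NA), "unavailable")
  expect_error(classify_tool(rules$lrt, "Z"), "vocabulary")
})

test_that("consensus counts damaging votes over available predictors", {
  mk <- function(n_dam, n_avail) {
    v <- c(rep("damaging", n_dam), rep("tolerated", n_avail - n_dam),
           rep("unavailable", 12 - n_avail))
    stats::setNames(v, paste0("tool", 1:12))
  }
  nine <- consensus(mk(9, 12), cfg)
  expect_equal(nine$fraction, 0.75)
  expect_equal(nine$verdict, "deleterious")
  three <- consensus(mk(3, 12), cfg)
  expect_equal(three$verdict, "tolerated")
  expect_equal(consensus(mk(0, 0), cfg)$verdict, "insufficient")
  expect_equal(consensus(mk(3, 5), cfg)$verdict, "insufficient")
  ## 60% is inclusive over available predictors
  expect_equal(consensus(mk(6, 10), cfg)$verdict, "deleterious")
  expect_equal(consensus(mk(7, 12), cfg)$verdict, "tolerated")  # 0.583
  dup <- stats::setNames(rep("damaging", 2), c("sift", "sift"))
  expect_error(consensus(dup, cfg), "duplicate")
})

test_that("monotone score shifts never flip consensus off", {
  ## pushing any one predictor toward its damaging side can only keep or
  ## gain damaging votes
  rules <- default_tool_rules(cfg)
  set.seed(21)
  for (rep in 1:20) {
    vals <- list(sift = runif(1), polyphen2_hdiv = runif(1),
                 polyphen2_hvar = runif(1),
                 lrt = sample(c("D", "N", "U"), 1),
                 mutation_taster = sample(c("A", "D", "N", "P"), 1),
                 mutation_assessor = sample(c("H", "M", "L", "N"), 1),
                 fathmm = runif(1, -18, 11), metasvm = runif(1, -2, 3),
                 metalr = runif(1), vest3 = runif(1),
                 provean = runif(1, -14, 14), ri = runif(1, 0, 10))
    verdicts <- vapply(names(vals), function(nm)
      classify_tool(rules[[nm]], vals[[nm]]), character(1))
    before <- consensus(verdicts, cfg)
    vals$sift <- vals$sift / 2          # toward damaging (low)
    vals$metasvm <- vals$metasvm + 1    # toward damaging (high)
    verdicts2 <- vapply(names(vals), function(nm)
      classify_tool(rules[[nm]], vals[[nm]]), character(1))
    after <- consensus(verdicts2, cfg)
    expect_gte(after$n_damaging, before$n_damaging)
    if (before$verdict == "deleterious") {
      expect_equal(after$verdict, "deleterious")
    }
  }
})

test_that("conservation flags use the published cutoffs and missing rules", {
  high <- conservation_flags(5.3, 1.0, 7.6, cfg)
  expect_true(all(unlist(high[, 1:3])))
  expect_equal(high$n_conserved, 3L)

  ## boundaries: GERP and phastCons strict, phyloP inclusive
  edge <- conservation_flags(2.0, 0.3, 2.99, cfg)
  expect_false(any(unlist(edge[, 1:3])))
  expect_equal(conservation_flags(2.0, 0.3, 3.0, cfg)$n_conserved, 1L)

  miss <- conservation_flags(NA, 0.9, NA, cfg)
  expect_true(is.na(miss$gerp_flag))
  expect_true(miss$phastcons_flag)
  expect_equal(miss$n_conserved, 1L)
  expect_error(conservation_flags(1, 1.2, 1, cfg), "\\[0, 1\\]")
})

test_that("intolerance votes follow the RVIS/pLI/Z conventions", {
  one <- intolerance_votes(pli = 0.95, config = cfg)
  expect_true(one$pli_vote)
  expect_equal(one$n_intolerant, 1L)
  expect_equal(one$n_scores_present, 1L)

  tolerant <- intolerance_votes(0.5, 0.7, 0.3, 0.01, -1.2, cfg)
  expect_equal(tolerant$n_intolerant, 0L)
  expect_equal(tolerant$n_scores_present, 5L)

  four <- intolerance_votes(-0.5, -0.3, 0.2, 0.95, 1.8, cfg)
  expect_equal(four$n_intolerant, 4L)

  ## boundaries: pLI >= 0.9 inclusive, RVIS < 0 strict, Z > 0 strict
  expect_equal(intolerance_votes(0, 0, 0, 0.9, 0, cfg)$n_intolerant, 1L)
  expect_error(intolerance_votes(pli = 1.2, config = cfg), "\\[0, 1\\]")
})

test_that("the embedded Grantham matrix matches the published standard", {
  m <- grantham_matrix()
  expect_equal(dim(m), c(20, 20))
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(0L, 20))
  expect_equal(max(m), 215L)
  peak <- which(m == 215, arr.ind = TRUE)
  expect_equal(sort(rownames(m)[peak[1, ]]), c("C", "W"))

  g <- grantham("G", "R")
  expect_equal(g$distance, 125L)
  expect_equal(as.character(g$category), "moderately_radical")
  expect_equal(grantham("R", "G")$distance, 125L)  # symmetry
  expect_equal(grantham("A", "A")$distance, 0L)
  expect_equal(as.character(grantham("A", "A")$category), "conservative")
  ## category boundaries
  expect_equal(as.character(grantham(c("L", "I"), c("I", "F"))$category),
               c("conservative", "conservative"))
  expect_equal(as.character(cut(c(50, 51, 100, 101, 150, 151),
                                c(-Inf, 50, 100, 150, Inf),
                                labels = levels(g$category))),
               c("conservative", "moderately_conservative",
                 "moderately_conservative", "moderately_radical",
                 "moderately_radical", "radical"))
  expect_error(grantham("B", "A"), "non-standard")
})

test_that("the embedded matrix agrees with the physicochemical formula", {
  ## independent oracle: recompute every pairwise distance from the
  ## composition / polarity / molecular-volume properties, normalized to a
  ## mean of 100 over all residue pairs
  prop <- rbind(S = c(1.42, 9.2, 32), R = c(0.65, 10.5, 124),
                L = c(0, 4.9, 111), P = c(0.39, 8.0, 32.5),
                T = c(0.71, 8.6, 61), A = c(0, 8.1, 31),
                V = c(0, 5.9, 84), G = c(0.74, 9.0, 3),
                I = c(0, 5.2, 111), F = c(0, 5.2, 132),
                Y = c(0.20, 6.2, 136), C = c(2.75, 5.5, 55),
                H = c(0.58, 10.4, 96), Q = c(0.89, 10.5, 85),
                N = c(1.33, 11.6, 56), K = c(0.33, 11.3, 119),
                D = c(1.38, 13.0, 54), E = c(0.92, 12.3, 83),
                M = c(0, 5.7, 105), W = c(0.13, 5.4, 170))
  d <- matrix(0, 20, 20, dimnames = list(rownames(prop), rownames(prop)))
  for (i in 1:20) for (j in 1:20) {
    d[i, j] <- sqrt(1.833 * (prop[i, 1] - prop[j, 1])^2 +
                    0.1018 * (prop[i, 2] - prop[j, 2])^2 +
                    0.000399 * (prop[i, 3] - prop[j, 3])^2)
  }
  d <- round(d * 100 / mean(d[upper.tri(d)]))
  m <- grantham_matrix()[rownames(prop), rownames(prop)]
  diffs <- abs(d - m)
  ## printed standard deviates from the recomputed formula only by rounding
  ## noise, except the historically discrepant Asp-Trp entry (printed 181)
  expect_equal(m["D", "W"], 181L)
  diffs["D", "W"] <- diffs["W", "D"] <- 0
  expect_lte(max(diffs), 1)
})

test_that("assess_coding adjudicates the candidate evidence profiles", {
  fx <- table3_fixture()
  missense <- fx$variants[fx$variants$exonic_class == "nonsynonymous_SNV", ]
  missense <- variant_table(as.data.frame(missense),
                            samples = samples(fx$variants))
  a <- assess_coding(missense, cfg)
  by_gene <- stats::setNames(seq_len(nrow(a)), a$gene)

  top <- a[by_gene["CPXM1"], ]
  expect_true(top$passes)
  expect_equal(top$consensus_n_damaging, 9L)
  expect_equal(top$n_intolerant, 4L)
  expect_equal(top$cadd_tier, "top01")
  expect_equal(top$grantham_distance, 125L)
  expect_equal(top$grantham_category, "moderately_radical")
  expect_equal(top$n_conserved, 3L)

  expect_false(a$passes[by_gene["ZBTB41"]])
  expect_equal(a$gate_failed[by_gene["ZBTB41"]], "consensus")
  expect_false(a$passes[by_gene["C1orf27"]])
  expect_equal(a$gate_failed[by_gene["C1orf27"]], "intolerance")
  expect_false(a$passes[by_gene["FAM129A"]])
  expect_equal(a$gate_failed[by_gene["FAM129A"]], "intolerance")

  ## low Grantham distances for the three non-prioritized substitutions
  expect_true(all(a$grantham_distance[a$gene != "CPXM1"] < 30))

  ## a non-missense exonic record is assessed but cannot pass
  indel <- make_variants(1, ref = "A", alt = "ATTT",
                         exonic_class = "nonframeshift_insertion",
                         cadd_phred = 25)
  ai <- assess_coding(indel, cfg)
  expect_false(ai$passes)
  expect_equal(ai$gate_failed, "coding_class")
})

test_that("the conservation hard gate is enforced only when switched on", {
  hard <- pipeline_config(conservation_is_hard_gate = TRUE)
  v <- make_variants(1, cadd_phred = 25, aa_change = "G573R",
                     sift = 0.01, polyphen2_hdiv = 0.99,
                     polyphen2_hvar = 0.98, lrt = "D",
                     mutation_taster = "D", mutation_assessor = "H",
                     fathmm = -3, metasvm = 1, metalr = 0.9, vest3 = 0.9,
                     provean = -5, ri = 8, pli = 0.95,
                     gerp = 1.0, phastcons = 0.1, phylop = 0.5)
  expect_true(assess_coding(v, cfg)$passes)
  hard_out <- assess_coding(v, hard)
  expect_false(hard_out$passes)
  expect_equal(hard_out$gate_failed, "conservation")
})
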