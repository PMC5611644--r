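# DMR calling: Fisher exact test vs enumeration oracle, BH adjustment,
# bin building with coverage/site filters, selection, merging, annotation
# association, and the swap-symmetry property.

test_that("Fisher p-values match the enumeration oracle on known tables", {
  # identical proportions with symmetric margins
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  # fully separated table: 2 equally extreme tables out of choose(20,10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_oracle(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # a generic table against the oracle
  expect_equal(fisher_exact_2x2(2, 8, 3, 7), fisher_oracle(2, 8, 3, 7),
               tolerance = 1e-12)
  # and against stats::fisher.test as a second, independent implementation
  for (tb in list(c(2, 8, 3, 7), c(12, 3, 4, 9), c(0, 5, 5, 0), c(7, 7, 7, 7))) {
    expect_equal(
      fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
      stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9)
  }
  # empty-sample convention
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 7), "empty sample")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("BH adjustment reproduces the hand-executed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # q is monotone when sorted by p, and {q < alpha} is the step-up set
  set.seed(2)
  p <- c(runif(40), runif(40)^4)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_equal(q < 0.05, stepup_select(p, 0.05))
})

test_that("bin building applies the both-sample 10-100x coverage and 4-site rules", {
  th <- dmr_thresholds()
  mk <- function(nm, nu) make_methylome(seq(10, by = 10,
                                            length.out = length(nm)), nm, nu)
  # 4 sites all passing in both -> one bin
  a <- mk(rep(10, 4), rep(5, 4))
  b <- mk(rep(2, 4), rep(13, 4))
  expect_equal(nrow(build_bins(a, b, "CHH", th)), 1)
  # 3 passing sites -> dropped
  expect_equal(nrow(build_bins(mk(rep(10, 3), rep(5, 3)),
                               mk(rep(2, 3), rep(13, 3)), "CHH", th)), 0)
  # a site at coverage 9 in sample b knocks the bin from 4 to 3 -> dropped
  b2 <- mk(c(2, 2, 2, 2), c(13, 13, 13, 7))
  expect_equal(nrow(build_bins(a, b2, "CHH", th)), 0)
  # a site above 100x in sample a is excluded
  a3 <- mk(c(10, 10, 10, 80), c(5, 5, 5, 25))   # last site coverage 105
  expect_equal(nrow(build_bins(a3, b, "CHH", th)), 0)
  # pooled counts only include passing sites
  bb <- build_bins(a, b, "CHH", th)
  expect_equal(bb$a_meth, 40L)
  expect_equal(bb$n_sites_passing, 4L)
  expect_equal(bb$diff, 40 / 60 - 8 / 60)
})

test_that("bin selection requires both the difference and the FDR gate", {
  bins <- data.frame(chrom = "Chr1", start = c(0, 100, 200), end = c(100, 200, 300),
                     context = c("CG", "CG", "CHH"), n_sites_passing = 5L,
                     a_meth = 1L, a_unmeth = 1L, b_meth = 1L, b_unmeth = 1L,
                     level_a = 0, level_b = 0,
                     diff = c(0.45, 0.39, 0.25),
                     p_value = 0, q_value = c(0.001, 1e-10, 0.02))
  sel <- call_dmr_bins(bins, dmr_thresholds())
  # CG at diff 0.45, q 0.001 passes; CG at 0.39 fails on diff no matter the
  # q; CHH at q 0.02 fails the FDR < 0.01 gate
  expect_equal(nrow(sel), 1)
  expect_equal(sel$start, 0)
  expect_equal(sel$direction, "hyper")
  # exact threshold is inclusive on |diff|
  bins$diff <- c(0.40, -0.40, 0.20)
  bins$q_value <- 0.001
  sel2 <- call_dmr_bins(bins, dmr_thresholds())
  expect_equal(nrow(sel2), 3)
  expect_equal(sel2$direction, c("hyper", "hypo", "hyper"))
})

test_that("DMR merging bridges one gap window and separates directions", {
  mk <- function(starts, dir) data.frame(
    chrom = "Chr1", start = starts, end = starts + 100L, context = "CHH",
    n_sites_passing = 4L, diff = ifelse(dir == "hyper", 0.3, -0.3),
    direction = dir)
  # one intervening bin merges at the default gap of one window
  d1 <- merge_dmrs(mk(c(0, 200), "hyper"))
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$start, d1$end), c(0, 300))
  # two intervening bins do not
  d2 <- merge_dmrs(mk(c(0, 300), "hyper"))
  expect_equal(nrow(d2), 2)
  # adjacent hyper and hypo stay separate
  both <- rbind(mk(0, "hyper"), mk(100, "hypo"))
  d3 <- merge_dmrs(both)
  expect_equal(nrow(d3), 2)
  expect_setequal(d3$direction, c("hyper", "hypo"))
  # mean diff is site-count weighted
  w <- mk(c(0, 100), "hyper")
  w$diff <- c(0.2, 0.6)
  w$n_sites_passing <- c(1L, 3L)
  expect_equal(merge_dmrs(w)$mean_diff, (0.2 * 1 + 0.6 * 3) / 4)
})

test_that("annotation association uses >= 1 bp overlap on half-open intervals", {
  annos <- data.frame(chrom = "Chr1", start = c(200L, 600L), end = c(600L, 800L),
                      kind = "TE", id = c("TE_a", "TE_b"), strand = "+")
  dmrs <- data.frame(chrom = "Chr1", start = c(150L, 0L, 550L),
                     end = c(250L, 100L, 700L))
  out <- associate_annotations(dmrs, annos)
  expect_equal(out$annotation, c("TE_a", "intergenic", "TE_a,TE_b"))
  # half-open adjacency is not overlap
  adj <- associate_annotations(data.frame(chrom = "Chr1", start = 0L,
                                          end = 200L), annos)
  expect_equal(adj$annotation, "intergenic")
})

test_that("swapping the samples flips directions and negates differences", {
  planted <- data.frame(chrom = "Chr1", start = c(5000L, 20000L),
                        end = c(5600L, 20800L), context = "CHH",
                        stage_a = "stage_a", stage_b = "stage_b",
                        base_level = 0.1, diff = c(0.4, -0.08))
  cfg <- flat_two_stage_config(seed = 33, chrom_length = 40000L,
                               planted = planted)
  g <- simulate_genome(cfg)
  ma <- simulate_stage(cfg, "stage_a", g)
  mb <- simulate_stage(cfg, "stage_b", g)
  th <- dmr_thresholds()
  ab <- build_bins(ma, mb, "CHH", th)
  ba <- build_bins(mb, ma, "CHH", th)
  expect_equal(ab$start, ba$start)
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$q_value, ba$q_value, tolerance = 1e-12)
  sa <- call_dmr_bins(ab, th)
  sb <- call_dmr_bins(ba, th)
  expect_equal(sa$start, sb$start)
  expect_true(all(sa$direction != sb$direction) || nrow(sa) == 0)
})

test_that("the full caller recovers a planted DMR and reports its annotation", {
  planted <- data.frame(chrom = "Chr1", start = 10000L, end = 10700L,
                        context = "CHH", stage_a = "stage_a",
                        stage_b = "stage_b", base_level = 0.1, diff = 0.35)
  cfg <- flat_two_stage_config(seed = 55, chrom_length = 30000L,
                               planted = planted)
  g <- simulate_genome(cfg)
  ma <- simulate_stage(cfg, "stage_a", g)
  mb <- simulate_stage(cfg, "stage_b", g)
  annos <- data.frame(chrom = "Chr1", start = 9500L, end = 11000L,
                      kind = "TE", id = "TE_x", strand = "+")
  dmrs <- call_dmrs(ma, mb, "CHH", annotations = annos)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$annotation, "TE_x")
  # the called interval covers the planted core
  expect_lte(dmrs$start, 10100)
  expect_gte(dmrs$end, 10600)
  expect_true(!is.null(attr(dmrs, "bins")))
  # consensus mode with a replicate drawn from the same truth keeps the call
  cfg2 <- flat_two_stage_config(seed = 56, chrom_length = 30000L,
                                planted = planted)
  g2 <- simulate_genome(cfg2)
  reps <- list(list(a = simulate_stage(cfg2, "stage_a", g2),
                    b = simulate_stage(cfg2, "stage_b", g2)))
  dmrs2 <- call_dmrs(ma, mb, "CHH", replicates = reps)
  # consensus can only shrink the selected bin set; what survives must
  # still sit on the planted interval
  expect_gte(nrow(dmrs2), 1)
  expect_true(all(dmrs2$start < 10700 & dmrs2$end > 10000))
  expect_lte(sum(dmrs2$end - dmrs2$start), sum(dmrs$end - dmrs$start))
})
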