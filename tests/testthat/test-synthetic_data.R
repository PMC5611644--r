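# Synthetic-data generator: determinism, genome layout, marginal
# calibration of generated counts, planted features, siRNA enrichment.

test_that("identical configuration gives bit-identical outputs", {
  cfg <- sim_config(seed = 42, n_chroms = 1, chrom_length = 100000L,
                    n_tes = 10, te_length_range = c(300L, 1200L),
                    n_genes = 15, n_saturated = 20)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  m1 <- simulate_stage(cfg, "mature_embryo", g1)
  m2 <- simulate_stage(cfg, "mature_embryo", g2)
  expect_identical(m1, m2)
  s1 <- simulate_sirnas(cfg, g1, g1$annotations[1, ], n_reads = 5000)
  s2 <- simulate_sirnas(cfg, g2, g2$annotations[1, ], n_reads = 5000)
  expect_identical(s1, s2)
})

test_that("genome layout honours the configuration", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 1000000L,
                    pericentromere_fraction = 0.2, n_tes = 60, n_genes = 80)
  g <- simulate_genome(cfg)
  an <- g$annotations
  peri <- an[an$kind == "pericentromere", ]
  expect_equal(c(peri$start, peri$end), c(400000L, 600000L))  # centred 20%

  # features fit their chromosome and do not overlap within a kind
  expect_true(all(an$start >= 0 & an$end <= 1000000L))
  tes <- an[an$kind == "TE", ]
  tes <- tes[order(tes$start), ]
  expect_true(all(tes$start[-1] >= tes$end[-nrow(tes)]))

  # TE density inside the pericentromere at least 3x the arm density
  inside <- tes$start >= peri$start & tes$end <= peri$end
  dens_in <- sum(inside) / (peri$end - peri$start)
  dens_out <- sum(!inside) / (1000000L - (peri$end - peri$start))
  expect_gte(dens_in / dens_out, 3)

  # CHH sites far outnumber CG sites (about 5:1)
  tab <- table(g$sites$context)
  expect_gt(tab[["CHH"]] / tab[["CG"]], 3)

  # all generated reads/records lie within chromosome bounds
  expect_true(all(g$sites$pos >= 0 & g$sites$pos < 1000000L))

  # n_tes = 0 still yields a gene-only annotation set
  g0 <- simulate_genome(sim_config(seed = 5, n_chroms = 1,
                                   chrom_length = 100000L, n_tes = 0,
                                   n_genes = 10, n_saturated = 0))
  expect_equal(sum(g0$annotations$kind == "TE"), 0)
  expect_gt(sum(g0$annotations$kind == "gene"), 0)

  # features that cannot fit raise a configuration error
  expect_error(simulate_genome(sim_config(seed = 1, n_chroms = 1,
                                          chrom_length = 5000L, n_tes = 50,
                                          te_length_range = c(1000L, 2000L),
                                          n_genes = 0, n_saturated = 0)),
               "do not fit")
})

test_that("degenerate probabilities give degenerate counts", {
  prof1 <- rbind(CG = rep(1, 4), CHG = rep(1, 4), CHH = rep(1, 4))
  prof0 <- rbind(CG = rep(0, 4), CHG = rep(0, 4), CHH = rep(0, 4))
  colnames(prof1) <- colnames(prof0) <-
    c("te_edge", "te_interior", "gene_body", "background")
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 20000L,
                    n_tes = 2, n_genes = 2, te_length_range = c(300L, 900L),
                    gene_length_range = c(500L, 1000L),
                    stage_profiles = list(all_on = prof1, all_off = prof0),
                    n_saturated = 0, peri_chh_boost = c(none = 0))
  g <- simulate_genome(cfg)
  on <- simulate_stage(cfg, "all_on", g)
  expect_true(all(on$n_unmeth == 0L))
  expect_true(all(on$n_meth >= 1L))   # coverage floored at 1
  off <- simulate_stage(cfg, "all_off", g)
  expect_true(all(off$n_meth == 0L))
  expect_error(simulate_stage(cfg, "no_such_stage", g), "unknown stage")
})

test_that("pooled level converges to the configured probability", {
  # CHH background 0.15 over ~10,000 background sites at 20x: the pooled
  # binomial mean must sit within 0.15 +/- 0.01
  cfg <- flat_two_stage_config(seed = 21, chrom_length = 150000L,
                               p_chh = 0.15)
  g <- simulate_genome(cfg)
  m <- simulate_stage(cfg, "stage_a", g)
  chh <- m[m$context == "CHH", ]
  expect_gt(nrow(chh), 10000)
  pooled <- sum(chh$n_meth) / sum(chh$n_meth + chh$n_unmeth)
  expect_lt(abs(pooled - 0.15), 0.01)
})

test_that("planted features show up in the generated counts", {
  planted <- data.frame(chrom = "Chr1", start = 10000L, end = 11000L,
                        context = "CHH", stage_a = "stage_a",
                        stage_b = "stage_b", base_level = 0.1, diff = 0.5)
  cfg <- flat_two_stage_config(seed = 13, chrom_length = 50000L,
                               planted = planted)
  g <- simulate_genome(cfg)
  ma <- simulate_stage(cfg, "stage_a", g)
  mb <- simulate_stage(cfg, "stage_b", g)
  inside <- function(m) m$context == "CHH" & m$pos >= 10000 & m$pos < 11000
  la <- with(ma[inside(ma), ], sum(n_meth) / sum(n_meth + n_unmeth))
  lb <- with(mb[inside(mb), ], sum(n_meth) / sum(n_meth + n_unmeth))
  expect_gt(la - lb, 0.35)   # true difference 0.5 at ~60+ sites
  # saturated sites: true probability exactly 1 in the saturated stage
  cfg2 <- sim_config(seed = 14, n_chroms = 1, chrom_length = 100000L,
                     n_tes = 10, te_length_range = c(300L, 1200L),
                     n_genes = 5, n_saturated = 50)
  g2 <- simulate_genome(cfg2)
  m2 <- simulate_stage(cfg2, "mature_embryo", g2)
  key <- paste(m2$chrom, m2$pos, m2$strand)
  sat <- paste(g2$saturated_sites$chrom, g2$saturated_sites$pos,
               g2$saturated_sites$strand)
  expect_true(all(m2$n_unmeth[key %in% sat] == 0L))
})

test_that("planted-DMR overlap within one context and stage pair is rejected", {
  planted <- data.frame(chrom = "Chr1", start = c(100L, 500L),
                        end = c(600L, 900L), context = "CHH",
                        stage_a = "stage_a", stage_b = "stage_b",
                        base_level = 0.1, diff = 0.3)
  expect_error(flat_two_stage_config(seed = 1, chrom_length = 10000L,
                                     planted = planted), "overlap")
  expect_error(flat_two_stage_config(
    seed = 1, chrom_length = 10000L,
    planted = transform(planted[1, ], base_level = 0.9)), "\\[0,1\\]")
})

test_that("siRNA libraries are enriched over targets at the configured fold", {
  cfg <- sim_config(seed = 31, n_chroms = 1, chrom_length = 200000L,
                    n_tes = 5, n_genes = 5, n_saturated = 0)
  g <- simulate_genome(cfg)
  targets <- data.frame(chrom = "Chr1", start = 50000L, end = 60000L)
  # fold 10, 24-nt only: target vs an equal-width background window
  r <- simulate_sirnas(cfg, g, targets, n_reads = 100000L,
                       enrichment_fold = 10, frac_21_22 = 0)
  expect_true(all(r$length == 24L))
  expect_true(all(r$start >= 0 & r$end <= 200000L + 24L))
  in_t <- sum(r$start >= 50000 & r$start < 60000)
  in_b <- sum(r$start >= 100000 & r$start < 110000)
  ratio <- in_t / in_b
  expect_gt(ratio, 10 - 3 * sqrt(1 / in_t + 1 / in_b) * 10)
  expect_lt(ratio, 10 + 3 * sqrt(1 / in_t + 1 / in_b) * 10)

  # fold 1: uniform within sampling error
  r1 <- simulate_sirnas(cfg, g, targets, n_reads = 100000L,
                        enrichment_fold = 1, frac_21_22 = 0)
  in_t1 <- sum(r1$start >= 50000 & r1$start < 60000)
  expect_lt(abs(in_t1 - 5000), 4 * sqrt(5000))

  # zero background: every 24-nt read inside the target
  r0 <- simulate_sirnas(cfg, g,
                        data.frame(chrom = "Chr1", start = 0L, end = 200000L),
                        n_reads = 1000L, enrichment_fold = 1e9,
                        frac_21_22 = 0)
  expect_true(all(r0$start >= 0 & r0$start < 200000))
  expect_equal(attr(r0, "library_total"), 1000L)
})
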