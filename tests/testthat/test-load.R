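test_that("site classification applies the strict score threshold", {
  ann <- data.frame(chrom = "A01", pos = 1:5,
                    score = c(0.04, 0.05, NA, 0.2, NA),
                    context = c("genic", "genic", "intergenic", "genic", NA))
  expect_warning(got <- classify_sites(ann), "neither")
  expect_equal(got$class, c("deleterious", "other", "neutral-intergenic",
                            "other", "other"))
})

test_that("allele counting is twice hom plus het", {
  geno <- cbind(c(rep(2L, 3), rep(1L, 2), rep(0L, 5)))
  gm <- gm_from_geno(geno)
  ac <- count_alleles(gm, "G1")
  expect_equal(ac$count, 8L)
  expect_equal(ac$total, 20L)
  gm0 <- gm_from_geno(cbind(rep(0L, 4)))
  expect_equal(count_alleles(gm0, "G1")$count, 0L)

  withr::with_seed(51, geno <- matrix(
    sample(c(0L, 1L, 2L, NA), 10 * 30, TRUE, prob = c(.4, .3, .2, .1)),
    nrow = 10))
  gm <- gm_from_geno(geno)
  ac <- count_alleles(gm)
  brute <- sapply(seq_len(30), function(j) {
    g <- geno[, j][!is.na(geno[, j])]
    c(sum(unlist(lapply(g, function(x) c(x >= 1, x == 2)))), 2 * length(g))
  })
  expect_equal(ac$count, unname(brute[1, ]))
  expect_equal(ac$total, unname(brute[2, ]))
  # counting identity: contributions sum to 2 x called samples
  expect_true(all(ac$total == 2 * colSums(!is.na(geno))))
})

test_that("frequency spectra bin exactly, with the (0.95,1] fixed bin", {
  # 10 diploids; construct sites at known frequencies
  make_site <- function(f) {
    n_alt <- round(f * 20)
    c(rep(2L, n_alt %/% 2), rep(1L, n_alt %% 2),
      rep(0L, 10 - n_alt %/% 2 - n_alt %% 2))
  }
  geno <- cbind(make_site(0.98), make_site(0), make_site(0.5), make_site(1))
  gm <- gm_from_geno(geno)
  cls <- rep("deleterious", 4)
  sp <- frequency_spectrum(gm, cls, "G1", classes = "deleterious")
  expect_equal(sum(sp$count), 3L)        # frequency-0 site excluded
  expect_equal(sp$count[sp$fixed], 2L)   # 0.98 realizes as 20/20: both fixed
  # spectrum conservation
  expect_equal(sum(sp$count), sum(!is.na(count_alleles(gm, "G1")$freq) &
                                    count_alleles(gm, "G1")$freq > 0))

  withr::with_seed(61, {
    freqs <- round(runif(1000, 0.02, 1) * 20) / 20
    geno <- sapply(freqs, make_site)
  })
  gm2 <- gm_from_geno(geno)
  sp2 <- frequency_spectrum(gm2, rep("neutral-intergenic", 1000), "G1",
                            classes = "neutral-intergenic")
  realized <- count_alleles(gm2, "G1")$freq
  realized <- realized[realized > 0]
  brute <- hist(realized, breaks = seq(0, 1, 0.05), plot = FALSE,
                right = TRUE)$counts
  expect_equal(sp2$count, brute)
})

test_that("the 0.95 boundary sits outside the fixed bin", {
  geno <- cbind(c(rep(2L, 9), rep(1L, 1), rep(0L, 0)))  # 19/20 = 0.95
  gm <- gm_from_geno(geno)
  sp <- frequency_spectrum(gm, "deleterious", "G1", classes = "deleterious")
  expect_equal(sp$count[sp$fixed], 0L)
  expect_equal(sp$count[abs(sp$bin_hi - 0.95) < 1e-9], 1L)
})

test_that("relative load is 1 for identical spectra and flags empty bins", {
  geno <- cbind(c(2L, rep(0L, 9)), c(2L, rep(0L, 9)))
  gm <- gm_from_geno(geno)
  sp <- frequency_spectrum(gm, c("deleterious", "neutral-intergenic"), "G1")
  rl <- relative_load(sp)
  expect_equal(rl$ratio[!is.na(rl$ratio)], 1)
  expect_true(all(rl$undefined[is.na(rl$ratio)]))
})

test_that("individual load ratios and subgenome additivity", {
  # 1 sample; 10 deleterious sites carried, 100 intergenic sites carried
  cls <- rep(c("deleterious", "neutral-intergenic"), c(10, 100))
  geno <- matrix(1L, nrow = 1, ncol = 110)
  chrom <- rep(c("A01", "C01"), length.out = 110)
  gm <- gm_from_geno(geno, chrom = chrom,
                     pos = as.integer(ave(seq_len(110), chrom, FUN = seq_along)) * 10L)
  # classification table keyed on chrom/pos survives the site reordering
  cls_tab <- data.frame(chrom = chrom,
                        pos = as.integer(ave(seq_len(110), chrom, FUN = seq_along)) * 10L,
                        class = cls)
  il <- individual_load(gm, cls_tab)
  gen <- il[il$subgenome == "genome", ]
  expect_equal(gen$ratio, 0.1)
  a <- il[il$subgenome == "A", ]; c_ <- il[il$subgenome == "C", ]
  expect_equal(a$dsnp + c_$dsnp, gen$dsnp)
  expect_equal(a$isnp + c_$isnp, gen$isnp)

  # sample carrying intergenic variants but no deleterious ones: ratio 0
  ref_geno <- matrix(as.integer(cls == "neutral-intergenic"), nrow = 1)
  ref <- gm_from_geno(ref_geno, chrom = chrom,
                      pos = as.integer(ave(seq_len(110), chrom, FUN = seq_along)) * 10L)
  il0 <- individual_load(ref, cls_tab)
  expect_equal(il0$dsnp[il0$subgenome == "genome"], 0)
  expect_equal(il0$ratio[il0$subgenome == "genome"], 0)
  # sample with no intergenic variants at all: undefined, flagged
  none <- gm_from_geno(matrix(0L, 1, 110), chrom = chrom,
                       pos = as.integer(ave(seq_len(110), chrom, FUN = seq_along)) * 10L)
  iln <- individual_load(none, cls_tab)
  expect_true(all(iln$undefined))
  expect_true(all(is.na(iln$ratio)))
})

test_that("selection skew leaves its signature in spectra and load", {
  cfg <- simulation_config(
    seed = 71,
    chromosomes = data.frame(name = c("A01", "C01"), subgenome = c("A", "C"),
                             length = 2000000L),
    founder_count = c(EU = 20L, AS_DH = 10L),
    deleterious_fraction = 0.5, selection_skew = 0.5,
    gene_fraction = 0.5, n_qtl = 0L)
  f <- simulate_founders(cfg)
  gm <- f$genotypes$EU
  cls <- f$sites$class
  ac <- count_alleles(gm, "EU")
  md <- mean(ac$freq[cls == "deleterious"], na.rm = TRUE)
  mn <- mean(ac$freq[cls == "neutral-intergenic"], na.rm = TRUE)
  expect_gte(sum(cls == "deleterious"), 2000 * 0.2)
  tt <- stats::t.test(ac$freq[cls == "deleterious"],
                      ac$freq[cls == "neutral-intergenic"],
                      alternative = "less")
  expect_lt(tt$p.value, 1e-6)
  expect_lt(md, mn)
  sp <- frequency_spectrum(gm, cls, "EU")
  rl <- relative_load(sp)
  expect_lt(rl$ratio[rl$fixed], 1)
})

test_that("a hybrid with a low-load donor parent has a lower dSNP ratio", {
  withr::with_seed(81, {
    ns <- 4000
    cls <- rep(c("deleterious", "neutral-intergenic"), length.out = ns)
    p_neutral <- runif(ns, 0.05, 0.6)
    p_bg <- ifelse(cls == "deleterious", p_neutral * 0.5, p_neutral)
    p_donor <- ifelse(cls == "deleterious", p_neutral * 0.05, p_neutral)
    bg_hap <- function() rbinom(ns, 1, p_bg)
    donor_hap <- function() rbinom(ns, 1, p_donor)
    sibling <- rbind(bg_hap(), bg_hap())
    hybrid <- rbind(bg_hap(), donor_hap())
  })
  gm <- gm_from_haps(rbind(sibling, hybrid), pos = seq_len(4000) * 10L)
  il <- individual_load(gm, cls)
  r <- il$ratio[il$subgenome == "genome"]
  expect_lt(r[2], r[1])  # hybrid strictly lower
})
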