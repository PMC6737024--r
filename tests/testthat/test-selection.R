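test_that("windowed pi matches single-pair and all-pairs expectations", {
  # 2 haplotypes differing at 1 site, window 100 bp -> pi = 0.01
  hap <- rbind(c(0L), c(1L))
  gm <- gm_from_haps(hap, pos = 50L, chrom_len = 100L)
  pi1 <- windowed_pi(gm, "G1", window = 100, step = 100)
  expect_equal(pi1$value, 0.01)

  # monomorphic window -> 0
  gm0 <- gm_from_haps(rbind(c(1L), c(1L)), pos = 50L, chrom_len = 100L)
  expect_equal(windowed_pi(gm0, "G1", 100, 100)$value, 0)

  # 4 haplotypes, one site at frequency 0.5, window 100 bp -> (4/6)/100
  hap4 <- matrix(c(0L, 0L, 1L, 1L), ncol = 1)
  gm4 <- gm_from_haps(hap4, pos = 10L, chrom_len = 100L)
  v <- windowed_pi(gm4, "G1", 100, 100)$value
  expect_equal(v, (4 / 6) / 100)
  expect_equal(v, brute_pi(hap4, 100))
})

test_that("windowed pi equals the all-pairs oracle on random data", {
  withr::with_seed(101, {
    hap <- matrix(rbinom(10 * 1000, 1, runif(1000)), nrow = 10, byrow = TRUE)
  })
  gm <- gm_from_haps(hap, pos = sort(sample(0:99999, 1000)), chrom_len = 100000L)
  pw <- windowed_pi(gm, "G1", window = 100000, step = 100000)
  expect_lt(abs(pw$value - brute_pi(hap, 100000)), 1e-12)
})

test_that("window FST is 1 for fixed differences and <= 0 without them", {
  geno <- rbind(matrix(0L, 5, 3), matrix(2L, 5, 3))
  gm <- gm_from_geno(geno, groups = rep(c("A", "B"), each = 5),
                     chrom_len = 1000L)
  w <- windowed_fst(gm, "A", "B", window = 1000, step = 1000)
  expect_equal(w$value, 1)
  expect_equal(site_fst(gm, "A", "B"), rep(1, 3))

  withr::with_seed(11, geno2 <- matrix(rbinom(20 * 50, 2, 0.4), nrow = 20))
  gm2 <- gm_from_geno(rbind(geno2, geno2),
                      groups = rep(c("A", "B"), each = 20), chrom_len = 10000L)
  w2 <- windowed_fst(gm2, "A", "B", window = 10000, step = 10000)
  expect_lte(w2$value, 0)  # identical group counts: no between-group variance
})

test_that("per-site FST equals the independent ANOVA oracle", {
  # the spec's worked genotype counts
  ga <- rep(c(0L, 1L, 2L), c(6, 4, 0))
  gb <- rep(c(0L, 1L, 2L), c(1, 4, 5))
  gm <- gm_from_geno(cbind(c(ga, gb)), groups = rep(c("A", "B"), c(10, 10)))
  expect_lt(abs(site_fst(gm, "A", "B") - anova_fst(ga, gb)), 1e-10)

  withr::with_seed(202, {
    for (rep_i in 1:200) {
      nA <- sample(3:12, 1); nB <- sample(3:12, 1)
      pA <- runif(1); pB <- runif(1)
      ga <- rbinom(nA, 2, pA); gb <- rbinom(nB, 2, pB)
      if (sum(ga) + sum(gb) %in% c(0, 2 * (nA + nB))) next  # monomorphic
      gm <- gm_from_geno(cbind(c(ga, gb)), groups = rep(c("A", "B"), c(nA, nB)))
      got <- site_fst(gm, "A", "B")
      want <- anova_fst(ga, gb)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_lt(abs(got - want), 1e-10)
    }
  })
})

test_that("window FST never exceeds 1", {
  withr::with_seed(33, {
    for (i in 1:20) {
      geno <- matrix(rbinom(16 * 30, 2, runif(30)), nrow = 16, byrow = TRUE)
      gm <- gm_from_geno(geno, groups = rep(c("A", "B"), each = 8),
                         pos = sort(sample(0:9999, 30)), chrom_len = 10000L)
      w <- windowed_fst(gm, "A", "B", 10000, 10000)
      expect_lte(w$value, 1 + 1e-12)
    }
  })
})

test_that("Z-transformation is exact, guarded and well calibrated", {
  expect_equal(z_transform(c(0, 1, 2)), c(-1, 0, 1))
  expect_error(z_transform(c(2, 2, 2)), "variance")
  expect_error(z_transform(c(1, NA)), "non-missing")
  z <- z_transform(c(0, NA, 1, 2))
  expect_true(is.na(z[2]))
  zz <- withr::with_seed(404, z_transform(rnorm(1e5)))
  expect_lt(abs(mean(zz)), 1e-9)
  expect_lt(abs(sd(zz) - 1), 1e-9)
  frac <- mean(zz > 3)
  expect_lt(abs(frac - 1.35e-3), 3 * sqrt(1.35e-3 * (1 - 1.35e-3) / 1e5))
})

test_that("divergent-region merging equals the interval-union oracle", {
  win <- make_windows(c(chr1 = 140000L), window = 100000, step = 10000)
  z <- rep(1, nrow(win)); z[2:3] <- 4
  reg <- call_divergent_regions(win, 3, z = z)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, win$start[2])
  expect_equal(reg$end, win$end[3])
  expect_equal(reg$n_windows, 2L)
  expect_equal(reg$peak_z, 4)

  expect_equal(nrow(call_divergent_regions(win, 3, z = rep(1, nrow(win)))), 0L)

  withr::with_seed(55, {
    for (i in 1:20) {
      win2 <- make_windows(c(c1 = 300000L, c2 = 200000L), 100000, 10000)
      z2 <- rnorm(nrow(win2), 0, 2)
      reg2 <- call_divergent_regions(win2, 3, z = z2)
      flag <- z2 > 3
      if (!any(flag)) { expect_equal(nrow(reg2), 0L); next }
      want <- interval_union_oracle(win2[flag, ])
      got <- reg2[order(reg2$chrom, reg2$start), c("chrom", "start", "end")]
      rownames(got) <- NULL
      expect_equal(got, want)
    }
  })
})

test_that("feature intersection uses half-open overlap and a brute oracle", {
  regions <- data.frame(chrom = "c1", start = 150L, end = 300L)
  feats <- data.frame(chrom = "c1", start = c(100L, 200L), end = c(200L, 300L),
                      id = c("in", "also_in"))
  got <- intersect_features(regions, feats)
  expect_setequal(got$feature_ids, c("in", "also_in"))
  # [100,200) vs region starting at 200 does not overlap
  r2 <- data.frame(chrom = "c1", start = 200L, end = 300L)
  f2 <- data.frame(chrom = "c1", start = 100L, end = 200L, id = "g")
  expect_equal(intersect_features(r2, f2)$n_features, 0L)
  expect_warning(intersect_features(r2, data.frame(
    chrom = "cX", start = 1L, end = 5L, id = "z"), chromosomes = "c1"),
    "unknown")

  withr::with_seed(66, {
    regions <- data.frame(chrom = sample(c("c1", "c2"), 50, TRUE),
                          start = sample(0:9000, 50))
    regions$end <- regions$start + sample(100:2000, 50, TRUE)
    feats <- data.frame(chrom = sample(c("c1", "c2"), 1000, TRUE),
                        start = sample(0:10000, 1000, TRUE))
    feats$end <- feats$start + sample(10:500, 1000, TRUE)
    feats$id <- sprintf("f%04d", seq_len(1000))
  })
  got <- intersect_features(regions, feats)
  brute <- unique(unlist(lapply(seq_len(nrow(regions)), function(i)
    feats$id[feats$chrom == regions$chrom[i] &
               pmin(feats$end, regions$end[i]) -
               pmax(feats$start, regions$start[i]) >= 1])))
  expect_setequal(got$feature_ids, brute)
  expect_equal(got$n_features, length(brute))
})

test_that("LD decay behaves at its fixed points", {
  withr::with_seed(77, {
    g1 <- rbinom(500, 2, 0.4)
    geno <- cbind(g1, g1, rbinom(500, 2, 0.5))
  })
  gm <- gm_from_geno(geno, pos = c(100L, 1100L, 5000L), chrom_len = 10000L)
  ld <- ld_decay(gm, "G1", max_dist = 10000, n_bins = 10)
  bin_of_dup <- findInterval(1000, seq(0, 10000, 1000), left.open = TRUE)
  expect_equal(ld$mean_r2[bin_of_dup], 1)  # duplicated site pair alone in bin
  expect_true(any(is.na(ld$mean_r2)))      # empty bins reported missing

  withr::with_seed(78, {
    geno <- matrix(rbinom(500 * 40, 2, rep(runif(40, 0.2, 0.8), each = 500)),
                   nrow = 500)
  })
  gmi <- gm_from_geno(geno, pos = sort(sample(0:99999, 40)),
                      chrom_len = 100000L)
  ldi <- ld_decay(gmi, "G1", max_dist = 100000, n_bins = 5)
  expect_lt(max(ldi$mean_r2, na.rm = TRUE), 0.05)  # independent sites
})

test_that("a locally fixed tract is recovered by the 3-SD scan", {
  # 10 x 2 Mb genome, one 300 kb selected tract; windows spill at most one
  # window length past a tract edge, well under 1% of this complement
  cfg <- simulation_config(
    seed = 909,
    chromosomes = data.frame(
      name = c(sprintf("A%02d", 1:5), sprintf("C%02d", 1:5)),
      subgenome = rep(c("A", "C"), each = 5), length = 2000000L),
    founder_count = c(EU = 30L, AS_DH = 30L),
    selected_regions = data.frame(chrom = "C01", start = 800000L,
                                  end = 1100000L),
    introgression_events = data.frame(chrom = "A01", donor = "DONOR",
                                      recipient = "AS_DH", start = 0L,
                                      end = 1L, carrier_fraction = 0),
    n_qtl = 0L)
  f <- simulate_founders(cfg)
  gm <- filter_sites(combine_genotypes(f$genotypes))
  fst <- windowed_fst(gm, "EU", "AS_DH")
  fst$z <- z_transform(fst$value)
  reg <- call_divergent_regions(fst, 3)
  tract <- c(800000, 1100000)
  in_tract <- sum(pmax(0, pmin(reg$end[reg$chrom == "C01"], tract[2]) -
                         pmax(reg$start[reg$chrom == "C01"], tract[1])))
  total_called <- sum(reg$end - reg$start)
  genome_bp <- 10 * 2e6
  expect_gte(in_tract / diff(tract), 0.9)
  expect_lt((total_called - in_tract) / (genome_bp - diff(tract)), 0.01)
})
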