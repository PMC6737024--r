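small_cfg <- function(seed = 11, L = 100000L, ...) {
  simulation_config(
    seed = seed,
    chromosomes = data.frame(name = c("A01", "C01"),
                             subgenome = c("A", "C"), length = L),
    founder_count = c(EU = 6L, AS_DH = 5L, AS_DL = 4L),
    n_qtl = 2L, ...)
}

test_that("identical configuration gives byte-identical outputs", {
  f1 <- simulate_founders(small_cfg())
  f2 <- simulate_founders(small_cfg())
  expect_identical(f1$assemblies[["SL-1"]]$seqs, f2$assemblies[["SL-1"]]$seqs)
  expect_identical(f1$genotypes$EU$geno, f2$genotypes$EU$geno)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(f1, d1); write_dataset(f2, d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)), label = fn)
})

test_that("zero donor divergence leaves the donor identical to the ancestor", {
  f <- simulate_founders(small_cfg(donor_divergence = 0))
  expect_identical(f$assemblies$CDA$seqs, f$ancestral$seqs)
})

test_that("zero-length chromosomes are a configuration error", {
  expect_error(simulation_config(chromosomes = data.frame(
    name = "A01", subgenome = "A", length = 0L)), "length")
})

test_that("founder mutation counts follow the binomial sampling oracle", {
  cfg <- simulation_config(
    seed = 5,
    chromosomes = data.frame(name = "A01", subgenome = "A", length = 1000000L),
    founder_count = c(EU = 4L, AS_DH = 4L), polymorphism_density = 1e-3,
    n_qtl = 0L)
  f <- simulate_founders(cfg)
  # per-lineage mutated positions ~ Binomial(1e6, 1e-3)
  n_mut <- length(f$truth$founder_mutations[["SL-1.A01"]])
  sigma <- sqrt(1e6 * 1e-3 * (1 - 1e-3))
  expect_lt(abs(n_mut - 1000), 3 * sigma)
  # global segregating-site count drawn from the same binomial
  expect_lt(abs(nrow(f$sites) - 1000), 3 * sigma)
})

test_that("a cross without recombination copies whole parental chromosomes", {
  withr::with_seed(3, {
    p1 <- assembly_set("P1", c(chr1 = rand_dna(5000)))
    p2 <- assembly_set("P2", c(chr1 = rand_dna(5000)))
  })
  cr <- simulate_cross(p1, p2, recomb_rate = 0, mutation_rate = 0, seed = 9)
  expect_equal(nrow(cr$truth), 1L)
  src <- cr$truth$origin[1]
  expect_identical(cr$child$seqs[["chr1"]],
                   (if (src == "P1") p1 else p2)$seqs[["chr1"]])
})

test_that("forced crossovers produce the constructed truth track", {
  withr::with_seed(4, {
    p1 <- assembly_set("P1", c(chr1 = rand_dna(60000)))
    p2 <- assembly_set("P2", c(chr1 = rand_dna(60000)))
  })
  cr <- simulate_cross(p1, p2, mutation_rate = 0, seed = 1,
                       crossovers = list(chr1 = 30000L))
  expect_equal(cr$truth$start, c(0L, 30000L))
  expect_equal(cr$truth$end, c(30000L, 60000L))
  expect_equal(cr$truth$origin, c("P1", "P2"))
  expect_identical(substr(cr$child$seqs[["chr1"]], 1, 30000),
                   substr(p1$seqs[["chr1"]], 1, 30000))
  expect_identical(substr(cr$child$seqs[["chr1"]], 30001, 60000),
                   substr(p2$seqs[["chr1"]], 30001, 60000))
})

test_that("crossover counts follow the Poisson oracle", {
  withr::with_seed(6, {
    p1 <- assembly_set("P1", c(chr1 = rand_dna(1000)))
    p2 <- assembly_set("P2", c(chr1 = rand_dna(1000)))
  })
  counts <- withr::with_seed(13, vapply(seq_len(10000), function(i) {
    cr <- simulate_cross(p1, p2, recomb_rate = 2, mutation_rate = 0)
    # crossover count = internal tract boundaries (origins alternate)
    nrow(cr$truth) - 1L
  }, numeric(1)))
  # ties/boundary collisions at L=1000 are vanishingly rare; mean ~ Poisson(2)
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / 10000))
})

test_that("pedigree and admixture truth tracts tile every chromosome", {
  cfg <- small_cfg(seed = 21)
  f <- simulate_founders(cfg)
  ped <- simulate_pedigree(f)
  lens <- chromosome_lengths(f$ancestral)
  for (tk in ped$tracks) {
    for (ch in names(lens)) {
      tt <- tk[tk$chrom == ch, ]
      tt <- tt[order(tt$start), ]
      expect_equal(tt$start[1], 0)
      expect_equal(tt$end[nrow(tt)], unname(lens[[ch]]))
      if (nrow(tt) > 1) expect_equal(tt$start[-1], tt$end[-nrow(tt)])
    }
  }
  adm <- simulate_admixed_population(
    f$genotypes$AS_DH, f$donor_panel,
    data.frame(chrom = "A01", start = 20000L, end = 80000L,
               carrier_fraction = 0.5),
    n_samples = 10, seed = 31)
  for (h in unique(paste(adm$truth$sample_id, adm$truth$hap))) {
    tt <- adm$truth[paste(adm$truth$sample_id, adm$truth$hap) == h, ]
    for (ch in names(lens)) {
      tc <- tt[tt$chrom == ch, ]
      expect_equal(tc$start[1], 0)
      expect_equal(tc$end[nrow(tc)], unname(lens[[ch]]))
    }
  }
})

test_that("admixture carrier counts follow the binomial oracle", {
  f <- simulate_founders(small_cfg(seed = 8))
  ev <- function(cf) data.frame(chrom = "A01", start = 10000L, end = 90000L,
                                carrier_fraction = cf)
  adm0 <- simulate_admixed_population(f$genotypes$EU, f$donor_panel, ev(0),
                                      n_samples = 20, seed = 1)
  expect_false(any(adm0$truth$origin == "donor"))
  adm1 <- simulate_admixed_population(f$genotypes$EU, f$donor_panel, ev(1),
                                      n_samples = 20, seed = 2)
  carriers <- tapply(adm1$truth$origin == "donor", adm1$truth$sample_id, any)
  expect_true(all(carriers))
  adm <- simulate_admixed_population(f$genotypes$EU, f$donor_panel, ev(0.95),
                                     n_samples = 40, seed = 3)
  n_car <- length(adm$carriers[[1]])
  expect_lt(abs(n_car - 40 * 0.95), 3 * sqrt(40 * 0.95 * 0.05) + 1e-9)
  expect_error(simulate_admixed_population(
    f$genotypes$EU, f$donor_panel,
    data.frame(chrom = "A01", start = 0L, end = 2e6, carrier_fraction = 0.5),
    n_samples = 5), "outside")
})

test_that("site classes respect gene intervals and the selection skew", {
  genes <- data.frame(chrom = "A01", start = c(100L, 1000L), end = c(500L, 1500L))
  sites <- data.frame(chrom = "A01", pos = c(50L, 120L, 700L, 1499L, 1500L))
  withr::with_seed(2, {
    out <- assign_site_classes(sites, genes, deleterious_fraction = 1,
                               selection_skew = 1)
  })
  expect_equal(out$class,
               c("neutral-intergenic", "deleterious", "neutral-intergenic",
                 "deleterious", "neutral-intergenic"))
  expect_true(all(out$score[out$class == "deleterious"] < 0.05))
  expect_error(assign_site_classes(sites, genes, 0.2, -1), "skew")

  # skew 1: deleterious and neutral frequencies indistinguishable (KS)
  withr::with_seed(7, {
    big <- data.frame(chrom = "A01", pos = seq_len(4000) * 10L,
                      base_freq = runif(4000))
    g2 <- data.frame(chrom = "A01", start = 0L, end = 20001L)  # first half genic
    s1 <- assign_site_classes(big, g2, deleterious_fraction = 1,
                              selection_skew = 1)
  })
  ks <- suppressWarnings(ks.test(s1$freq[s1$class == "deleterious"],
                                 s1$freq[s1$class == "neutral-intergenic"]))
  expect_gt(ks$p.value, 0.01)

  # skew 0.5: mean frequency ratio near 0.5
  withr::with_seed(9, {
    big <- data.frame(chrom = "A01", pos = seq_len(10000) * 10L,
                      base_freq = runif(10000))
    g2 <- data.frame(chrom = "A01", start = 0L, end = 50001L)
    s2 <- assign_site_classes(big, g2, deleterious_fraction = 1,
                              selection_skew = 0.5)
  })
  ratio <- mean(s2$freq[s2$class == "deleterious"]) /
    mean(s2$freq[s2$class == "neutral-intergenic"])
  expect_gt(ratio, 0.4); expect_lt(ratio, 0.6)
})

test_that("written datasets round-trip losslessly", {
  f <- simulate_founders(small_cfg(seed = 17))
  ped <- simulate_pedigree(f)
  d <- tempfile()
  paths <- write_dataset(f, d, pedigree = ped)
  gm <- read_vcf(paths[["vcf"]], groups = paths[["groups"]])
  comb <- combine_genotypes(f$genotypes)
  expect_equal(unname(gm$geno), unname(comb$geno))
  expect_equal(gm$sites$pos, comb$sites$pos)
  expect_equal(gm$samples$group, comb$samples$group)
  expect_equal(gm$haplotypes, comb$haplotypes)
  # truth tract BED tiles the chromosomes
  bed <- read_bed(paths[["truth_tracts"]])
  lens <- chromosome_lengths(f$ancestral)
  for (ch in names(lens)) {
    tt <- bed[bed$chrom == ch, ]
    expect_equal(min(tt$start), 0)
    expect_equal(max(tt$end), unname(lens[[ch]]))
  }
  # empty genotype matrix still writes a valid header with zero records
  empty <- subset_genotypes(comb, sites = integer(0))
  ef <- tempfile(fileext = ".vcf")
  write_vcf(empty, ef)
  lines <- readLines(ef)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_equal(sum(!grepl("^#", lines)), 0L)
})
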