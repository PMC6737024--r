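# Independent oracles and small fixture builders. These deliberately use
# different algorithms from the package code paths they check.

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")

# build a genotype_matrix from an explicit haplotype matrix
gm_from_haps <- function(hap, pos = NULL, chrom = "A01", groups = NULL,
                         chrom_len = NULL) {
  ns <- ncol(hap)
  n <- nrow(hap) / 2
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(groups)) groups <- rep("G1", n)
  sites <- data.frame(chrom = rep(chrom, length.out = ns), pos = pos,
                      ref = "A", alt = "T")
  cl <- if (is.null(chrom_len)) NULL else setNames(chrom_len, unique(sites$chrom))
  genotype_matrix(NULL, sites,
                  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                             group = groups),
                  haplotypes = hap, chrom_lengths = cl)
}

# build a genotype_matrix from a genotype (0/1/2/NA) matrix
gm_from_geno <- function(geno, pos = NULL, chrom = "A01", groups = NULL,
                         chrom_len = NULL) {
  ns <- ncol(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(groups)) groups <- rep("G1", n)
  sites <- data.frame(chrom = rep(chrom, length.out = ns), pos = pos,
                      ref = "A", alt = "T")
  cl <- if (is.null(chrom_len)) NULL else setNames(chrom_len, unique(sites$chrom))
  genotype_matrix(geno, sites,
                  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                             group = groups),
                  chrom_lengths = cl)
}

# mean pairwise difference per bp over all haplotype pairs (brute force)
brute_pi <- function(hap, span) {
  nh <- nrow(hap)
  tot <- 0; np <- 0
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh) {
    tot <- tot + sum(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  tot / np / span
}

# Weir & Cockerham (1984) per-site FST via the random-effects ANOVA on raw
# allele indicators: independent of the closed-form component code.
anova_fst <- function(genoA, genoB) {
  # geno vectors (one site), values 0/1/2/NA per diploid
  alleles <- function(g) {
    g <- g[!is.na(g)]
    lapply(g, function(x) switch(as.character(x), `0` = c(0, 0),
                                 `1` = c(0, 1), `2` = c(1, 1)))
  }
  pops <- list(alleles(genoA), alleles(genoB))
  ni <- vapply(pops, length, numeric(1))
  if (any(ni < 2)) return(NA_real_)
  r <- 2
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(vapply(pops, function(p) sum(unlist(p)), numeric(1))) /
    (2 * sum(ni))
  # sums of squares
  SSG <- 0; SSI <- 0; SSP <- 0
  dfG <- sum(ni); dfI <- sum(ni - 1); dfP <- r - 1
  for (p in pops) {
    ybar_pop <- mean(unlist(p))
    for (ind in p) {
      ybar_ind <- mean(ind)
      SSG <- SSG + sum((ind - ybar_ind)^2)
      SSI <- SSI + 2 * (ybar_ind - ybar_pop)^2
    }
    SSP <- SSP + 2 * length(p) * (ybar_pop - pbar)^2
  }
  MSG <- SSG / dfG; MSI <- SSI / dfI; MSP <- SSP / dfP
  s2G <- MSG
  s2I <- (MSI - MSG) / 2
  s2P <- (MSP - MSI) / (2 * nc)
  denom <- s2P + s2I + s2G
  if (denom == 0) return(NA_real_)
  s2P / denom
}

# exact-match coverage oracle: per-diagonal equal runs of length >= k,
# union over all diagonals and reference chromosomes
coverage_oracle <- function(block, ref_seqs, k) {
  b <- strsplit(toupper(block), "")[[1]]
  Lb <- length(b)
  covered <- rep(FALSE, Lb)
  valid_b <- b %in% c("A", "C", "G", "T")
  for (s in ref_seqs) {
    r <- strsplit(toupper(s), "")[[1]]
    Lr <- length(r)
    valid_r <- r %in% c("A", "C", "G", "T")
    for (d in (-(Lb - k)):(Lr - k)) {
      i0 <- max(1L, 1L - d); i1 <- min(Lb, Lr - d)
      if (i1 - i0 + 1 < k) next
      idx <- i0:i1
      eq <- b[idx] == r[idx + d] & valid_b[idx] & valid_r[idx + d]
      rl <- rle(eq)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (q in which(rl$values & rl$lengths >= k))
        covered[idx[starts[q]:ends[q]]] <- TRUE
    }
  }
  sum(covered)
}

# substitute n ~ Binomial(L, rate) random positions (test-local twin of the
# generator's mutation step; used to build divergent source genomes)
mutate_seq_for_test <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  n <- rbinom(1, length(ch), rate)
  if (n == 0) return(seq)
  pos <- sample(length(ch), n)
  ch[pos] <- vapply(ch[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  paste(ch, collapse = "")
}

# brute-force union of half-open intervals, returned sorted
interval_union_oracle <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    iv <- df[df$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    cur_s <- iv$start[1]; cur_e <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= cur_e) cur_e <- max(cur_e, iv$end[i])
      else { out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
             cur_s <- iv$start[i]; cur_e <- iv$end[i] }
    }
    out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
  }
  res <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(res) <- c("chrom", "start", "end")
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  res
}
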