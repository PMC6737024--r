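# Sequence-level building blocks for the simulator. All draw from the
# current RNG stream; callers control seeding with withr::with_seed().

BASES <- c("A", "C", "G", "T")

# random chromosome of length L
random_chromosome <- function(L) {
  paste(sample(BASES, L, replace = TRUE), collapse = "")
}

# substitute bases at a per-bp rate; returns the new sequence and the 1-based
# positions mutated. Substituted base is always different from the original.
mutate_sequence <- function(seq, rate) {
  L <- nchar(seq)
  n <- rbinom(1L, L, min(rate, 1))
  if (n == 0L) return(list(seq = seq, pos = integer()))
  pos <- sort(sample.int(L, n))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  cur <- match(ch[pos], BASES)
  shift <- sample.int(3L, n, replace = TRUE)
  new <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  new[is.na(cur)] <- ch[pos][is.na(cur)]  # leave ambiguous bases untouched
  ch[pos] <- new
  list(seq = paste(ch, collapse = ""), pos = pos)
}

# merge abutting tracts with identical origin; tracts assumed sorted and
# tiling within chromosome
merge_tracts <- function(tr) {
  if (nrow(tr) <= 1L) return(tr)
  rows <- list(tr[1, , drop = FALSE])
  for (i in 2:nrow(tr)) {
    last <- rows[[length(rows)]]
    if (tr$chrom[i] == last$chrom && tr$origin[i] == last$origin &&
        tr$start[i] == last$end) {
      rows[[length(rows)]]$end <- tr$end[i]
    } else {
      rows[[length(rows) + 1L]] <- tr[i, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# intersect two tract sets on the same chromosome system; labels of b are
# appended to labels of a as "a_label:b_label" where they overlap
compose_tracts <- function(a, b) {
  out <- list()
  for (ch in unique(a$chrom)) {
    aa <- a[a$chrom == ch, , drop = FALSE]
    bb <- b[b$chrom == ch, , drop = FALSE]
    ra <- IRanges::IRanges(aa$start + 1L, aa$end)
    rb <- IRanges::IRanges(bb$start + 1L, bb$end)
    ov <- IRanges::findOverlaps(ra, rb)
    ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
    int <- IRanges::pintersect(ra[ia], rb[ib])
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(int) - 1L,
      end = IRanges::end(int),
      origin = paste0(aa$origin[ia], ":", bb$origin[ib]))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(a$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}
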