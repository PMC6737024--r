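# window grid in SNP space: chunks of window_snps consecutive sites per
# chromosome, with bp spans delimited at midpoints between flanking sites
ancestry_grid <- function(sites, window_snps) {
  stopifnot(window_snps >= 1)
  out <- lapply(unique(sites$chrom), function(ch) {
    si <- which(sites$chrom == ch)
    m <- length(si)
    starts <- seq.int(1L, m, by = window_snps)
    ends <- pmin(starts + window_snps - 1L, m)
    pos <- sites$pos[si]
    bp_start <- c(pos[1], (pos[ends[-length(ends)]] + pos[starts[-1]]) %/% 2 + 1L)
    bp_end <- c(bp_start[-1], pos[m] + 1L)
    data.frame(chrom = ch, window = seq_along(starts),
               start_site = si[starts], end_site = si[ends],
               start = as.integer(bp_start), end = as.integer(bp_end))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# minimum Hamming distance from each query row to any panel row, per window
min_panel_dist <- function(Q, P) {
  # 0/1 matrices; mismatches = rq + rp - 2 * Q P'
  M <- Q %*% t(P)
  d <- outer(rowSums(Q), rowSums(P), "+") - 2 * M
  apply(d, 1, min)
}

#' Paint haplotypes against two source panels
#'
#' For every window of `window_snps` consecutive sites, each query haplotype
#' is labelled with the source panel whose closest haplotype has the smaller
#' Hamming distance to the query in that window; exact ties are labelled
#' `unresolved`. This is a deliberate, testable stand-in for full
#' local-ancestry optimizers: the downstream fixation summary only needs
#' per-window source labels.
#'
#' @param x a phased [genotype_matrix()] of query samples.
#' @param panel_a,panel_b 0/1 haplotype matrices (source panels) on the same
#'   site list as `x`.
#' @param window_snps sites per window (default 50).
#' @param labels labels for the two sources.
#' @return data.frame of class `ancestry_tracks`: one row per
#'   (haplotype, window) with `sample_id`, `hap`, `chrom`, `window`,
#'   `start`, `end` (bp span), `start_site`, `end_site`, `label`. The window
#'   grid is kept in `attr(,"grid")`.
#' @export
paint_population <- function(x, panel_a, panel_b, window_snps = 50,
                             labels = c("sourceA", "sourceB")) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(x$haplotypes)) stop("query genotypes must be phased")
  if (nrow(panel_a) == 0L || nrow(panel_b) == 0L) stop("empty source panel")
  if (ncol(panel_a) != n_sites(x) || ncol(panel_b) != n_sites(x))
    stop("panels must share the query site list")
  grid <- ancestry_grid(x$sites, window_snps)
  H <- x$haplotypes
  nh <- nrow(H)
  lab <- matrix(NA_character_, nrow = nh, ncol = nrow(grid))
  for (w in seq_len(nrow(grid))) {
    cols <- grid$start_site[w]:grid$end_site[w]
    Q <- H[, cols, drop = FALSE]
    dA <- min_panel_dist(Q, panel_a[, cols, drop = FALSE])
    dB <- min_panel_dist(Q, panel_b[, cols, drop = FALSE])
    lab[, w] <- ifelse(dA < dB, labels[1],
                       ifelse(dB < dA, labels[2], "unresolved"))
  }
  ids <- x$samples$sample_id
  out <- data.frame(
    sample_id = rep(rep(ids, each = 2L), times = nrow(grid)),
    hap = rep(rep(c(1L, 2L), length(ids)), times = nrow(grid)),
    grid[rep(seq_len(nrow(grid)), each = nh),
         c("chrom", "window", "start", "end", "start_site", "end_site")],
    label = as.vector(lab))
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "labels") <- labels
  class(out) <- c("ancestry_tracks", "data.frame")
  out
}

#' Paint a single haplotype
#'
#' Convenience wrapper around the window painter for one query haplotype.
#'
#' @param hap 0/1 vector over the sites in `sites`.
#' @param panel_a,panel_b 0/1 haplotype panel matrices.
#' @param sites site table (`chrom`, `pos`) the haplotype is indexed on.
#' @param window_snps sites per window.
#' @param labels source labels.
#' @return data.frame with one row per window (`chrom`, `window`, `start`,
#'   `end`, `label`).
#' @export
paint_haplotype <- function(hap, panel_a, panel_b, sites, window_snps = 50,
                            labels = c("sourceA", "sourceB")) {
  if (nrow(panel_a) == 0L || nrow(panel_b) == 0L) stop("empty source panel")
  grid <- ancestry_grid(sites, window_snps)
  lab <- character(nrow(grid))
  for (w in seq_len(nrow(grid))) {
    cols <- grid$start_site[w]:grid$end_site[w]
    q <- hap[cols]
    dA <- min(colSums(abs(t(panel_a[, cols, drop = FALSE]) - q)))
    dB <- min(colSums(abs(t(panel_b[, cols, drop = FALSE]) - q)))
    lab[w] <- if (dA < dB) labels[1] else if (dB < dA) labels[2] else "unresolved"
  }
  data.frame(grid, label = lab)
}

#' Per-window donor-ancestry frequency across a population
#'
#' At sample level a diploid carries donor ancestry in a window if at least
#' one of its two haplotypes is donor-labelled there; at haplotype level the
#' fraction is computed over haplotypes directly.
#'
#' @param tracks an `ancestry_tracks` object from [paint_population()].
#' @param donor_label the source label counted as donor.
#' @param level `"sample"` (default) or `"haplotype"`.
#' @return data.frame of class `fixation_track`: per window `chrom`,
#'   `window`, `start`, `end`, `n_carriers`, `n`, `fraction`.
#' @export
population_ancestry_frequency <- function(tracks, donor_label,
                                          level = c("sample", "haplotype")) {
  level <- match.arg(level)
  grid <- attr(tracks, "grid")
  if (is.null(grid)) stop("tracks must come from paint_population()")
  key <- paste(tracks$chrom, tracks$window)
  gkey <- paste(grid$chrom, grid$window)
  is_donor <- tracks$label == donor_label
  if (level == "sample") {
    agg <- tapply(is_donor, list(tracks$sample_id, key), any)
    n_carriers <- colSums(agg[, gkey, drop = FALSE])
    n <- nrow(agg)
  } else {
    hap_id <- paste(tracks$sample_id, tracks$hap)
    agg <- tapply(is_donor, list(hap_id, key), any)
    n_carriers <- colSums(agg[, gkey, drop = FALSE])
    n <- nrow(agg)
  }
  out <- data.frame(grid[, c("chrom", "window", "start", "end")],
                    n_carriers = as.integer(n_carriers), n = n,
                    fraction = as.numeric(n_carriers) / n)
  class(out) <- c("fixation_track", "data.frame")
  out
}

#' Call near-fixed introgression regions
#'
#' Windows whose donor-ancestry fraction strictly exceeds the threshold are
#' merged (consecutive windows on a chromosome) into maximal regions. The
#' default threshold 0.9 implements the ">90% of samples" fixation rule, so
#' a fraction of exactly 0.9 is not flagged.
#'
#' @param fixation a `fixation_track` from [population_ancestry_frequency()].
#' @param threshold fixation threshold (strict inequality).
#' @return list with `regions` (data.frame `chrom`, `start`, `end`,
#'   `n_windows`, `max_fraction`) and `total_bp`.
#' @export
call_fixed_introgressions <- function(fixation, threshold = 0.9) {
  flag <- fixation$fraction > threshold
  if (!any(flag)) {
    return(list(regions = data.frame(chrom = character(), start = integer(),
                                     end = integer(), n_windows = integer(),
                                     max_fraction = numeric()),
                total_bp = 0))
  }
  f <- fixation[flag, , drop = FALSE]
  # group consecutive windows per chromosome
  grp <- cumsum(c(TRUE, f$chrom[-1] != f$chrom[-nrow(f)] |
                    f$window[-1] != f$window[-nrow(f)] + 1L))
  regions <- do.call(rbind, lapply(split(f, grp), function(b)
    data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end),
               n_windows = nrow(b), max_fraction = max(b$fraction))))
  rownames(regions) <- NULL
  list(regions = regions, total_bp = sum(regions$end - regions$start))
}
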