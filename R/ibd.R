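#' Segment chromosomes into fixed-length blocks
#'
#' Consecutive non-overlapping blocks anchored at position 0; the last block
#' of a chromosome may be shorter. The union of blocks covers each
#' chromosome exactly.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp (> 0).
#' @param block_size block length in bp (default 50 kb).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
segment_blocks <- function(chrom_lengths, block_size = 50000) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (block_size <= 0) stop("block_size must be > 0")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(0L, L - 1L, by = block_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + block_size, L)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# build a k-mer anchor index over an assembly (or plain character vector)
kmer_index <- function(x, k = 21) {
  seqs <- if (inherits(x, "assembly_set")) x$seqs else x
  if (k < 11 || k > 31) stop("anchor_k must be between 11 and 31")
  kmer_index_build(toupper(seqs), as.integer(k))
}

#' Accumulated exact-match length of a block against candidate parents
#'
#' For each parent, the total number of block positions covered by maximal
#' exact matches of length >= `anchor_k` anywhere in that parent's assembly.
#' Matches are counted without double-covering block positions, so repeated
#' hits cannot inflate the total. A block consisting entirely of ambiguous
#' bases scores zero against every parent and is flagged.
#'
#' @param block_seq block sequence (single string).
#' @param parents named list of [assembly_set()]s (or named character
#'   vectors of chromosome sequences).
#' @param anchor_k anchor length (11..31; default 21, near-unique in a
#'   gigabase-scale genome).
#' @return named numeric vector of accumulated match lengths, with attribute
#'   `ambiguous` set to `TRUE` when the block had no usable anchor at all.
#' @export
match_lengths <- function(block_seq, parents, anchor_k = 21) {
  stopifnot(is.character(block_seq), length(block_seq) == 1L)
  if (is.null(names(parents)) || any(names(parents) == ""))
    stop("parents must be named")
  block_seq <- toupper(block_seq)
  out <- vapply(parents, function(p) {
    idx <- kmer_index(p, anchor_k)
    kmer_match_coverage(idx, block_seq)
  }, numeric(1))
  ambiguous <- !grepl("[ACGT]", block_seq)
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Match table of a child assembly against candidate parents
#'
#' Cuts the child into blocks and scores every block against every parent by
#' accumulated exact-match coverage. Each parent is indexed once and its
#' index released before the next, keeping memory proportional to one
#' genome.
#'
#' @param child [assembly_set()] of the derived genome.
#' @param parents named list of candidate parent [assembly_set()]s.
#' @param block_size block length in bp.
#' @param anchor_k anchor length.
#' @return list of class `ibd_matches`: `blocks` (data.frame) and `matches`
#'   (blocks x parents numeric matrix).
#' @export
ibd_match_table <- function(child, parents, block_size = 50000, anchor_k = 21) {
  stopifnot(inherits(child, "assembly_set"), length(parents) >= 1L)
  if (is.null(names(parents))) stop("parents must be named")
  blocks <- segment_blocks(chromosome_lengths(child), block_size)
  block_seqs <- substring(child$seqs[blocks$chrom], blocks$start + 1L, blocks$end)
  m <- matrix(0, nrow = nrow(blocks), ncol = length(parents),
              dimnames = list(NULL, names(parents)))
  for (p in names(parents)) {
    idx <- kmer_index(parents[[p]], anchor_k)
    m[, p] <- vapply(block_seqs, function(s) kmer_match_coverage(idx, s),
                     numeric(1), USE.NAMES = FALSE)
    rm(idx)
  }
  structure(list(blocks = blocks, matches = m, block_size = block_size,
                 anchor_k = anchor_k), class = "ibd_matches")
}

#' Assign block origins by longest accumulated match
#'
#' Each block is labelled with the parent achieving the longest accumulated
#' match length. Exact ties between the top parents, and best matches below
#' `min_match_fraction` of the block length, are labelled `unassigned`.
#'
#' @param matches an `ibd_matches` from [ibd_match_table()], or a list with
#'   `blocks` and a `matches` matrix.
#' @param min_match_fraction assignment floor as a fraction of block length.
#' @return data.frame IBD track (`chrom`, `start`, `end`, `origin`) of class
#'   `ibd_track`; the candidate parent set is kept in `attr(,"parents")`.
#' @export
assign_blocks <- function(matches, min_match_fraction = 0.1) {
  m <- matches$matches
  blocks <- matches$blocks
  if (is.null(colnames(m)) || ncol(m) == 0L) stop("empty parent set")
  best <- do.call(pmax, as.data.frame(m))
  tied <- rowSums(m == best) > 1L
  origin <- colnames(m)[max.col(m, ties.method = "first")]
  floor_bp <- min_match_fraction * (blocks$end - blocks$start)
  origin[tied | best < floor_bp | best <= 0] <- "unassigned"
  track <- data.frame(blocks, origin = origin)
  attr(track, "parents") <- colnames(m)
  class(track) <- c("ibd_track", "data.frame")
  track
}

#' Decompose one parent's blocks into grandparental origins
#'
#' Blocks labelled `parent` are re-scored against the grandparent assemblies
#' only and relabelled `parent:grandparent` (or `parent:unresolved` on ties
#' or sub-floor matches). All other blocks are untouched.
#'
#' @param track an `ibd_track`.
#' @param child the derived genome the track describes (its block sequences
#'   are re-scored).
#' @param parent label of the parent to decompose.
#' @param grandparents named list of grandparent [assembly_set()]s.
#' @param anchor_k anchor length.
#' @param min_match_fraction assignment floor.
#' @return the updated `ibd_track`.
#' @export
decompose_parent <- function(track, child, parent, grandparents,
                             anchor_k = 21, min_match_fraction = 0.1) {
  parents_attr <- attr(track, "parents")
  if (!parent %in% c(parents_attr, track$origin))
    stop("parent '", parent, "' absent from track")
  sel <- which(track$origin == parent)
  if (length(sel) == 0L) return(track)
  block_seqs <- substring(child$seqs[track$chrom[sel]],
                          track$start[sel] + 1L, track$end[sel])
  m <- matrix(0, nrow = length(sel), ncol = length(grandparents),
              dimnames = list(NULL, names(grandparents)))
  for (g in names(grandparents)) {
    idx <- kmer_index(grandparents[[g]], anchor_k)
    m[, g] <- vapply(block_seqs, function(s) kmer_match_coverage(idx, s),
                     numeric(1), USE.NAMES = FALSE)
    rm(idx)
  }
  best <- do.call(pmax, as.data.frame(m))
  tied <- rowSums(m == best) > 1L
  sub <- colnames(m)[max.col(m, ties.method = "first")]
  floor_bp <- min_match_fraction * (track$end[sel] - track$start[sel])
  sub[tied | best < floor_bp | best <= 0] <- "unresolved"
  track$origin[sel] <- paste0(parent, ":", sub)
  track
}

#' Genome-wide contribution summary of an IBD track
#'
#' Per-label bp totals divided by the genome length, as percentages summing
#' to 100. Blocks must tile the genome; overlapping blocks are an error.
#' With `drop_unassigned = TRUE` percentages are renormalized over assigned
#' blocks only — the convention of pedigree pie charts, where every slice is
#' a parental line.
#'
#' @param track an `ibd_track` (or data.frame `chrom`,`start`,`end`,`origin`).
#' @param drop_unassigned exclude `unassigned` blocks from the denominator.
#' @return data.frame `origin`, `bp`, `percent`, sorted by decreasing
#'   contribution.
#' @export
summarize_contributions <- function(track, drop_unassigned = FALSE) {
  for (ch in unique(track$chrom)) {
    b <- track[track$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping blocks on chromosome ", ch)
  }
  if (drop_unassigned)
    track <- track[track$origin != "unassigned", , drop = FALSE]
  bp <- tapply(track$end - track$start, track$origin, sum)
  total <- sum(track$end - track$start)
  out <- data.frame(origin = names(bp), bp = as.numeric(bp),
                    percent = 100 * as.numeric(bp) / total)
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trace a derived genome to its pedigree parents
#'
#' End-to-end IBD tracing: block segmentation, per-parent accumulated
#' exact-match scoring, longest-match assignment and contribution summary.
#'
#' @inheritParams ibd_match_table
#' @inheritParams assign_blocks
#' @return list with `matches` (`ibd_matches`), `track` (`ibd_track`) and
#'   `summary` (contribution table).
#' @export
ibd_trace <- function(child, parents, block_size = 50000, anchor_k = 21,
                      min_match_fraction = 0.1) {
  matches <- ibd_match_table(child, parents, block_size, anchor_k)
  track <- assign_blocks(matches, min_match_fraction)
  list(matches = matches, track = track,
       summary = summarize_contributions(track))
}

#' Block-level truth labels from a tract table
#'
#' Labels each block with the origin covering the largest share of it
#' (majority origin), the standard resolution for comparing a block-level
#' call against base-pair-level truth.
#'
#' @param blocks data.frame `chrom`, `start`, `end`.
#' @param tracts truth tract table `chrom`, `start`, `end`, `origin`.
#' @return character vector of majority origins, one per block.
#' @export
block_truth_labels <- function(blocks, tracts) {
  vapply(seq_len(nrow(blocks)), function(i) {
    tt <- tracts[tracts$chrom == blocks$chrom[i] &
                   tracts$end > blocks$start[i] &
                   tracts$start < blocks$end[i], , drop = FALSE]
    if (nrow(tt) == 0L) return(NA_character_)
    ov <- pmin(tt$end, blocks$end[i]) - pmax(tt$start, blocks$start[i])
    bp <- tapply(ov, tt$origin, sum)
    names(bp)[which.max(bp)]
  }, character(1))
}
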