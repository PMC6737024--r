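#' Simulate a pedigree cross
#'
#' The child genome is a mosaic of the two parents: per chromosome, a
#' Poisson-distributed number of crossovers is placed uniformly and segments
#' alternate between the parents, starting from a randomly chosen one. A
#' per-generation mutation load is then applied. The returned truth track
#' records every segment's origin, tiling each chromosome exactly.
#'
#' @param parent1,parent2 [assembly_set()]s sharing chromosome names and
#'   lengths.
#' @param recomb_rate expected crossovers per chromosome per meiosis.
#' @param mutation_rate per-bp mutation rate applied to the child
#'   (one generation).
#' @param seed optional integer seed (isolated RNG state when given).
#' @param crossovers optional named list `chrom -> integer positions` forcing
#'   the crossover points; segments then start with `parent1`.
#' @param child_name name for the child assembly.
#' @return list with `child` (an `assembly_set`), `truth` (data.frame
#'   `chrom`, `start`, `end`, `origin`, 0-based half-open, tiling each
#'   chromosome) and `mutations` (1-based positions mutated per chromosome).
#' @export
simulate_cross <- function(parent1, parent2, recomb_rate = 2,
                           mutation_rate = 1e-4, seed = NULL,
                           crossovers = NULL, child_name = "child") {
  stopifnot(inherits(parent1, "assembly_set"), inherits(parent2, "assembly_set"))
  l1 <- chromosome_lengths(parent1); l2 <- chromosome_lengths(parent2)
  if (!identical(sort(names(l1)), sort(names(l2))) ||
      !identical(l1[names(l2)], l2))
    stop("parents must share chromosome names and lengths")
  run <- function() {
    seqs <- character(0); truth <- list(); muts <- list()
    parents <- list(parent1, parent2)
    pnames <- c(parent1$name, parent2$name)
    for (ch in names(l1)) {
      L <- l1[[ch]]
      if (!is.null(crossovers)) {
        cx <- sort(unique(as.integer(crossovers[[ch]])))
        cx <- cx[cx > 0L & cx < L]
        first <- 1L
      } else {
        ncx <- rpois(1L, recomb_rate)
        cx <- sort(unique(ceiling(runif(ncx, 0, L - 1))))
        cx <- cx[cx > 0L & cx < L]
        first <- sample.int(2L, 1L)
      }
      bounds <- c(0L, cx, L)
      origin_idx <- rep_len(c(first, 3L - first), length(bounds) - 1L)
      segs <- vapply(seq_len(length(bounds) - 1L), function(i)
        substr(parents[[origin_idx[i]]]$seqs[[ch]],
               bounds[i] + 1L, bounds[i + 1L]), "")
      child_seq <- paste(segs, collapse = "")
      m <- mutate_sequence(child_seq, mutation_rate)
      seqs[[ch]] <- m$seq
      muts[[ch]] <- m$pos
      truth[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                                end = bounds[-1],
                                origin = pnames[origin_idx])
    }
    truth <- merge_tracts(do.call(rbind, truth))
    list(child = assembly_set(child_name, seqs), truth = truth,
         mutations = muts)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Simulate a mosaic genome over several source assemblies
#'
#' Partitions each chromosome into segments (Poisson number of uniform
#' breakpoints) and draws every segment's origin from `sources` with the
#' given weights, then applies a mutation load. Used to build genomes whose
#' per-source contribution fractions are known exactly.
#'
#' @param sources named list of [assembly_set()]s on one chromosome system.
#' @param weights numeric sampling weights, one per source.
#' @param mean_segment expected segment length in bp.
#' @param mutation_rate per-bp mutation rate applied to the mosaic.
#' @param seed optional integer seed.
#' @param child_name name for the mosaic assembly.
#' @return list with `child`, `truth` (tiling tract table) and the realized
#'   per-source contribution percentages in `attr(truth, "realized_pct")`.
#' @export
simulate_mosaic <- function(sources, weights = rep(1, length(sources)),
                            mean_segment = 2e5, mutation_rate = 1e-4,
                            seed = NULL, child_name = "mosaic") {
  stopifnot(length(sources) >= 2L, length(weights) == length(sources))
  lens <- chromosome_lengths(sources[[1]])
  run <- function() {
    seqs <- character(0); truth <- list()
    for (ch in names(lens)) {
      L <- lens[[ch]]
      ncx <- rpois(1L, max(0, L / mean_segment - 1))
      cx <- sort(unique(ceiling(runif(ncx, 0, L - 1))))
      bounds <- c(0L, cx, L)
      origin <- sample(names(sources), length(bounds) - 1L, replace = TRUE,
                       prob = weights)
      segs <- vapply(seq_len(length(bounds) - 1L), function(i)
        substr(sources[[origin[i]]]$seqs[[ch]],
               bounds[i] + 1L, bounds[i + 1L]), "")
      m <- mutate_sequence(paste(segs, collapse = ""), mutation_rate)
      seqs[[ch]] <- m$seq
      truth[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                                end = bounds[-1], origin = origin)
    }
    truth <- merge_tracts(do.call(rbind, truth))
    bp <- tapply(truth$end - truth$start, truth$origin, sum)
    attr(truth, "realized_pct") <- 100 * bp / sum(bp)
    list(child = assembly_set(child_name, seqs), truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Simulate the four-line pedigree of the derived cultivar
#'
#' Executes [pedigree_spec()] on simulated founders: NY1 is derived from the
#' founder landrace by selfing, CY2 is the landrace x donor cross, and the
#' derived cultivar NY7 is NY1 x CY2. Truth tracks are returned at the
#' direct-parent level for every cross, plus the grandparent-level
#' decomposition of NY7's CY2 segments obtained by composing the NY7 and CY2
#' tracks.
#'
#' @param founders a `population_sim` from [simulate_founders()].
#' @param seed integer seed; defaults to the configuration seed + 1.
#' @return list with `assemblies` (all five lines) and `tracks`
#'   (`NY1`, `CY2`, `NY7`, `NY7_grand`).
#' @export
simulate_pedigree <- function(founders, seed = NULL) {
  stopifnot(inherits(founders, "population_sim"))
  cfg <- founders$config
  if (is.null(seed)) seed <- cfg$seed + 1L
  withr::with_seed(as.integer(seed), {
    sl1 <- founders$assemblies[["SL-1"]]
    cda <- founders$assemblies[["CDA"]]
    ny1 <- simulate_cross(sl1, sl1, cfg$recombination_rate,
                          cfg$mutation_rate, child_name = "NY1")
    cy2 <- simulate_cross(sl1, cda, cfg$recombination_rate,
                          cfg$mutation_rate, child_name = "CY2")
    ny7 <- simulate_cross(ny1$child, cy2$child, cfg$recombination_rate,
                          cfg$mutation_rate, child_name = "NY7")
    grand <- ny7$truth
    is_cy2 <- grand$origin == "CY2"
    if (any(is_cy2)) {
      dec <- compose_tracts(grand[is_cy2, , drop = FALSE], cy2$truth)
      grand <- rbind(grand[!is_cy2, , drop = FALSE], dec)
      grand <- grand[order(match(grand$chrom, names(chromosome_lengths(sl1))),
                           grand$start), ]
      rownames(grand) <- NULL
    }
    list(assemblies = list(`SL-1` = sl1, CDA = cda, NY1 = ny1$child,
                           CY2 = cy2$child, NY7 = ny7$child),
         tracks = list(NY1 = ny1$truth, CY2 = cy2$truth, NY7 = ny7$truth,
                       NY7_grand = grand))
  })
}
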