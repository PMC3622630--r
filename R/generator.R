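#' Exhaustive corpus of small SCS instances
#'
#' Enumerates every multiset of at most `max_n` binary strings with lengths
#' `1 .. max_len`, crossed with every length bound `0 .. max_bound`, in a
#' canonical order (strings sorted by length then lexicographically;
#' multisets by non-decreasing index; bounds ascending). The corpus is
#' duplicate-free under multiset equality and is the test bed on which the
#' reduction chain is checked instance by instance.
#'
#' @param max_len Maximum string length (default suite uses at most 3).
#' @param max_n Maximum multiset size.
#' @param max_bound Maximum length bound `l'`.
#' @return List of [scs_instance()] objects with a `manifest` attribute
#'   (counts per multiset size).
#' @export
exhaustive_scs_corpus <- function(max_len, max_n, max_bound) {
  stopifnot(max_len >= 0L, max_n >= 0L, max_bound >= 0L)
  pool <- if (max_len >= 1L)
    unlist(lapply(seq_len(max_len), all_strings)) else character(0)
  pool <- pool[order(nchar(pool), pool)]
  multisets <- list(integer(0))
  if (max_n >= 1L && length(pool) > 0L) {
    grow <- function(prefix, start, left) {
      if (left == 0L) return(list())
      out <- list()
      for (i in start:length(pool)) {
        ms <- c(prefix, i)
        out <- c(out, list(ms), grow(ms, i, left - 1L))
      }
      out
    }
    multisets <- c(multisets, grow(integer(0), 1L, max_n))
  }
  corpus <- list()
  for (ms in multisets) {
    for (bound in 0:max_bound) {
      corpus[[length(corpus) + 1L]] <-
        scs_instance(pool[ms], bound, alphabet = c("0", "1"))
    }
  }
  sizes <- vapply(multisets, length, integer(1L))
  attr(corpus, "manifest") <-
    data.frame(multiset_size = sort(unique(sizes)),
               n_multisets = as.integer(table(sizes)),
               n_instances = as.integer(table(sizes)) * (max_bound + 1L))
  corpus
}

#' Planted YES instances of DBSM
#'
#' Draws a random binary genome, samples reads as random substrings of it,
#' builds the de Bruijn graph and read walks from the reads (plus the
#' genome's own edges), and sets each edge's multiplicity to its exact
#' traversal count in the genome's walk. The genome walk is then a valid
#' superwalk by construction, so the instance is YES for every seed.
#'
#' @param genome_length Length of the random genome.
#' @param n_reads Number of reads.
#' @param read_length Length of each read; must satisfy
#'   `k + 1 <= read_length <= genome_length`.
#' @param k De Bruijn order.
#' @param seed Integer seed; identical arguments give identical instances.
#' @return A [dbsm_instance()] with attributes `genome` and `planted_walk`
#'   (the genome's own walk, a verifying witness).
#' @export
planted_dbsm <- function(genome_length, n_reads, read_length, k, seed) {
  if (read_length < k + 1L)
    stop_superwalk("read_length must be at least k + 1",
                   "superwalk_invalid_parameter")
  if (genome_length < read_length)
    stop_superwalk("genome_length must be at least read_length",
                   "superwalk_invalid_parameter")
  if (n_reads < 1L)
    stop_superwalk("n_reads must be positive", "superwalk_invalid_parameter")
  with_seed(seed, {
    genome <- paste0(sample(c("0", "1"), genome_length, replace = TRUE),
                     collapse = "")
    starts <- sample.int(genome_length - read_length + 1L, n_reads,
                         replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    built <- build_from_reads(reads, k)
    g_starts <- seq_len(genome_length - k)
    genome_walk <- substring(genome, g_starts, g_starts + k)
    graph <- debruijn_graph(k, unique(c(built$graph$edges, genome_walk)))
    mult <- stats::setNames(integer(length(graph$edges)), graph$edges)
    tab <- table(genome_walk)
    mult[names(tab)] <- as.integer(tab)
    inst <- dbsm_instance(graph, built$walks, mult)
    attr(inst, "genome") <- genome
    attr(inst, "planted_walk") <- genome_walk
    inst
  })
}

#' Perturb a DBSM instance towards a NO answer
#'
#' Two perturbation modes: `"bump_multiplicity"` adds 1 to one random
#' edge's multiplicity, which breaks the planted walk's exact-count
#' certificate but does not guarantee the perturbed instance is NO (such
#' instances are labelled `"unknown"` and must be resolved by the exact
#' solver); `"drop_read_edge"` sets one read-covered edge's multiplicity to
#' zero, which guarantees NO because some read traverses an edge no valid
#' superwalk may use.
#'
#' @param inst A [dbsm_instance()] with at least one positive multiplicity.
#' @param mode `"bump_multiplicity"` or `"drop_read_edge"`.
#' @param seed Integer seed.
#' @return The perturbed [dbsm_instance()], with attributes `perturbation`
#'   and `label` (`"unknown"` for bump, `"no"` for drop).
#' @export
perturb_to_no <- function(inst, mode = c("bump_multiplicity",
                                         "drop_read_edge"), seed) {
  stopifnot(inherits(inst, "dbsm_instance"))
  mode <- match.arg(mode)
  if (!any(inst$multiplicities > 0L))
    stop_superwalk("instance has no edge with positive multiplicity",
                   "superwalk_invalid_parameter")
  mult <- inst$multiplicities
  with_seed(seed, {
    if (mode == "bump_multiplicity") {
      e <- sample(names(mult), 1L)
      mult[e] <- mult[e] + 1L
      label <- "unknown"
    } else {
      covered <- unique(unlist(c(inst$read_walks, list(character(0)))))
      covered <- covered[mult[covered] > 0L]
      if (length(covered) == 0L)
        stop_superwalk("no read-covered edge with positive multiplicity",
                       "superwalk_invalid_parameter")
      e <- sample(covered, 1L)
      mult[e] <- 0L
      label <- "no"
    }
    out <- dbsm_instance(inst$graph, inst$read_walks, mult)
    attr(out, "perturbation") <- mode
    attr(out, "label") <- label
    out
  })
}
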