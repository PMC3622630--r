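#' De Bruijn graphs of order k
#'
#' A de Bruijn graph of order `k` has k-mers as vertices and `(k+1)`-mers as
#' edges; the edge spelled by a `(k+1)`-mer runs from its length-`k` prefix
#' to its length-`k` suffix. The vertex set is implied by the edges. The
#' graph is simple: duplicate `(k+1)`-mers across reads create one edge
#' (multiplicity is carried separately by [dbsm_instance()]).
#'
#' @param k Positive integer order.
#' @param edges Character vector of distinct `(k+1)`-mer strings.
#' @param alphabet Ordered character vector.
#' @return Object of class `debruijn_graph` with fields `k`, `alphabet`,
#'   `edges` (sorted), and `vertices` (implied k-mers, sorted).
#' @export
debruijn_graph <- function(k, edges, alphabet = c("0", "1")) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop_superwalk("k must be a positive integer", "superwalk_invalid_parameter")
  edges <- sort(unique(as.character(edges)))
  if (any(nchar(edges) != k + 1L))
    stop_superwalk("every edge must be a (k+1)-mer", "superwalk_invalid_input")
  check_over_alphabet(edges, alphabet)
  vertices <- sort(unique(c(substr(edges, 1L, k), substr(edges, 2L, k + 1L))))
  structure(list(k = k, alphabet = alphabet, edges = edges,
                 vertices = vertices),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat("De Bruijn graph: k = ", x$k, ", ", length(x$vertices),
      " vertex/vertices, ", length(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Build a de Bruijn graph and read walks from reads
#'
#' The graph's edges are all `(k+1)`-mers occurring in any read; read `i`'s
#' walk is its `(k+1)`-mers in order (`nchar(read) - k` edges). Reads
#' shorter than `k + 1` contribute no edge; by default they are an error,
#' or are dropped with a count in the result when `skip_short = TRUE`.
#'
#' @param reads Character vector of reads.
#' @param k Positive integer order.
#' @param alphabet Ordered character vector.
#' @param skip_short Drop too-short reads instead of erroring.
#' @return List with `graph` (a [debruijn_graph()]), `walks` (list of edge
#'   vectors, one per retained read), and `n_skipped`.
#' @examples
#' build_from_reads("0011", k = 2)$walks[[1]]  # c("001", "011")
#' @export
build_from_reads <- function(reads, k, alphabet = c("0", "1"),
                             skip_short = FALSE) {
  reads <- as.character(reads)
  k <- as.integer(k)
  short <- nchar(reads) < k + 1L
  if (any(short) && !skip_short)
    stop_superwalk(paste0(sum(short), " read(s) shorter than k + 1 = ",
                          k + 1L, " characters"),
                   "superwalk_read_too_short")
  if (any(short))
    warning(sum(short), " read(s) shorter than k + 1 dropped")
  kept <- reads[!short]
  walks <- lapply(kept, function(r) {
    starts <- seq_len(nchar(r) - k)
    substring(r, starts, starts + k)
  })
  graph <- debruijn_graph(k, unique(unlist(c(walks, list(character(0))))),
                          alphabet)
  list(graph = graph, walks = walks, n_skipped = sum(short))
}

#' Spell the string of a walk
#'
#' Inverse of read decomposition: the first edge followed by the last
#' character of each subsequent edge; the result has length
#' `k + 1 + (length(w) - 1)`.
#'
#' @param w Non-empty character vector of `(k+1)`-mer edges with
#'   consecutive incidence.
#' @param k Positive integer order.
#' @return The spelled string.
#' @examples
#' walk_to_string(c("001", "011"), k = 2)  # "0011"
#' @export
walk_to_string <- function(w, k) {
  w <- as.character(w)
  if (length(w) == 0L)
    stop_superwalk("cannot spell an empty walk", "superwalk_invalid_walk")
  if (!walk_is_valid(w, k))
    stop_superwalk("walk violates consecutive edge incidence",
                   "superwalk_invalid_walk")
  paste0(w[1L], paste0(substr(w[-1L], k + 1L, k + 1L), collapse = ""))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] (the reads here are
#' over arbitrary alphabets such as `{0,1}`, not necessarily DNA).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_reads <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- as.character(seqs)
  # keep only the identifier part of each description line
  names(out) <- vapply(strsplit(names(out), "[ \t]"), `[[`, character(1L), 1L)
  out
}
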