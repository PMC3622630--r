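#' Decision-problem instances
#'
#' Constructors for the three decision problems:
#'
#' * **SCS** (Shortest Common Superstring, decision form): given strings and
#'   a length bound `l'`, is there a string of length at most `l'` containing
#'   every given string as a substring?
#' * **CSM** (Common Superstring with Multiplicities): given strings and a
#'   per-character count `l_c` for every alphabet character, is there a
#'   string containing every given string as a substring whose character
#'   counts equal the `l_c` exactly? (Any solution has length `sum(l_c)`.)
#' * **DBSM** (De Bruijn Superwalk with Multiplicities): given a de Bruijn
#'   graph of order `k`, read walks, and an exact multiplicity for every
#'   edge, is there a walk containing every read walk as a contiguous
#'   subwalk and traversing each edge exactly its multiplicity?
#'
#' @param strings Character vector of instance strings (may be empty, may
#'   repeat).
#' @param length_bound Nonnegative integer `l'` (SCS).
#' @param alphabet Ordered character vector of allowed characters.
#' @param multiplicities Named nonnegative integer vector: per-character
#'   counts for CSM (one per alphabet character), per-edge counts for DBSM
#'   (one per graph edge).
#' @param graph A [debruijn_graph()] (DBSM).
#' @param read_walks List of walks; each walk is a character vector of
#'   `(k+1)`-mer edges with consecutive incidence (DBSM).
#' @return An object of class `scs_instance`, `csm_instance`, or
#'   `dbsm_instance`.
#' @name instances
NULL

#' @rdname instances
#' @export
scs_instance <- function(strings, length_bound, alphabet = c("0", "1")) {
  strings <- as.character(strings)
  check_over_alphabet(strings, alphabet)
  stopifnot(length(length_bound) == 1L, length_bound >= 0)
  structure(list(strings = strings,
                 length_bound = as.integer(length_bound),
                 alphabet = alphabet),
            class = "scs_instance")
}

#' @rdname instances
#' @export
csm_instance <- function(strings, multiplicities, alphabet = c("0", "1")) {
  strings <- as.character(strings)
  check_over_alphabet(strings, alphabet)
  if (!setequal(names(multiplicities), alphabet))
    stop_superwalk("multiplicities must be named by exactly the alphabet",
                   "superwalk_invalid_input")
  mult <- stats::setNames(as.integer(multiplicities[alphabet]), alphabet)
  stopifnot(all(mult >= 0L))
  structure(list(strings = strings, multiplicities = mult,
                 alphabet = alphabet),
            class = "csm_instance")
}

#' @rdname instances
#' @export
dbsm_instance <- function(graph, read_walks, multiplicities) {
  stopifnot(inherits(graph, "debruijn_graph"))
  read_walks <- lapply(read_walks, as.character)
  for (w in read_walks) {
    unknown <- setdiff(w, graph$edges)
    if (length(unknown) > 0L)
      stop_superwalk(paste0("read walk uses edge(s) not in the graph: ",
                            paste(unknown, collapse = ", ")),
                     "superwalk_invalid_input")
    if (!walk_is_valid(w, graph$k))
      stop_superwalk("read walk violates consecutive edge incidence",
                     "superwalk_invalid_walk")
  }
  if (!setequal(names(multiplicities), graph$edges))
    stop_superwalk("multiplicities must be named by exactly the graph edges",
                   "superwalk_invalid_input")
  edge_order <- sort(graph$edges)
  mult <- stats::setNames(as.integer(multiplicities[edge_order]), edge_order)
  stopifnot(all(mult >= 0L))
  structure(list(k = graph$k, alphabet = graph$alphabet, graph = graph,
                 read_walks = read_walks, multiplicities = mult),
            class = "dbsm_instance")
}

check_over_alphabet <- function(strings, alphabet) {
  cs <- unique(unlist(lapply(strings, chars)))
  bad <- setdiff(cs, alphabet)
  if (length(bad) > 0L)
    stop_superwalk(paste0("character(s) outside the alphabet: ",
                          paste(bad, collapse = ", ")),
                   "superwalk_invalid_input")
  invisible(TRUE)
}

#' @export
print.scs_instance <- function(x, ...) {
  cat("SCS instance: ", length(x$strings), " string(s), length bound l' = ",
      x$length_bound, "\n", sep = "")
  invisible(x)
}

#' @export
print.csm_instance <- function(x, ...) {
  cat("CSM instance: ", length(x$strings), " string(s), multiplicities ",
      paste0(names(x$multiplicities), "=", x$multiplicities,
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.dbsm_instance <- function(x, ...) {
  cat("DBSM instance: k = ", x$k, ", ", length(x$graph$edges), " edge(s), ",
      length(x$read_walks), " read walk(s), total multiplicity ",
      sum(x$multiplicities), "\n", sep = "")
  invisible(x)
}

# A walk is a sequence of (k+1)-mer edges where the k-suffix of each edge
# equals the k-prefix of the next. The empty walk is valid.
walk_is_valid <- function(edges, k) {
  if (length(edges) == 0L) return(TRUE)
  if (any(nchar(edges) != k + 1L)) return(FALSE)
  if (length(edges) == 1L) return(TRUE)
  suf <- substr(edges[-length(edges)], 2L, k + 1L)
  pre <- substr(edges[-1L], 1L, k)
  all(suf == pre)
}

#' Verify a candidate SCS solution
#'
#' @param candidate Candidate superstring over the instance alphabet.
#' @param inst An [scs_instance()].
#' @return `TRUE` iff `nchar(candidate) <= l'` and every instance string is
#'   a substring of `candidate`.
#' @export
verify_scs <- function(candidate, inst) {
  stopifnot(inherits(inst, "scs_instance"))
  check_over_alphabet(candidate, inst$alphabet)
  if (nchar(candidate) > inst$length_bound) return(FALSE)
  all(vapply(inst$strings, function(s)
    length(occurrence_positions(s, candidate)) > 0L, logical(1L)))
}

#' Verify a candidate CSM solution
#'
#' @param candidate Candidate superstring over the instance alphabet.
#' @param inst A [csm_instance()].
#' @return `TRUE` iff every instance string is a substring of `candidate`
#'   and the per-character counts of `candidate` equal the instance
#'   multiplicities exactly.
#' @export
verify_csm <- function(candidate, inst) {
  stopifnot(inherits(inst, "csm_instance"))
  check_over_alphabet(candidate, inst$alphabet)
  counts <- char_counts(candidate, inst$alphabet)
  if (!all(counts[inst$alphabet] == inst$multiplicities[inst$alphabet]))
    return(FALSE)
  all(vapply(inst$strings, function(s)
    length(occurrence_positions(s, candidate)) > 0L, logical(1L)))
}

#' Verify a candidate DBSM superwalk
#'
#' Checks that (a) the candidate is a valid walk, (b) it traverses every
#' edge exactly its multiplicity, and (c) every read walk occurs as a
#' contiguous block of the candidate edge sequence. Distinct reads may be
#' witnessed by overlapping or identical blocks. Edges of multiplicity zero
#' are handled uniformly by (b): any walk traversing them fails.
#'
#' @param candidate Character vector of edges (a walk; may be empty).
#' @param inst A [dbsm_instance()].
#' @return `TRUE` iff all three conditions hold.
#' @export
verify_dbsm <- function(candidate, inst) {
  stopifnot(inherits(inst, "dbsm_instance"))
  candidate <- as.character(candidate)
  unknown <- setdiff(candidate, inst$graph$edges)
  if (length(unknown) > 0L)
    stop_superwalk(paste0("candidate uses edge(s) not in the graph: ",
                          paste(unknown, collapse = ", ")),
                   "superwalk_invalid_input")
  if (!walk_is_valid(candidate, inst$k)) return(FALSE)
  counts <- stats::setNames(integer(length(inst$multiplicities)),
                            names(inst$multiplicities))
  if (length(candidate) > 0L) {
    tab <- table(candidate)
    counts[names(tab)] <- as.integer(tab)
  }
  if (!all(counts == inst$multiplicities)) return(FALSE)
  all(vapply(inst$read_walks, function(r)
    contains_subwalk(candidate, r), logical(1L)))
}

#' Contiguous subwalk containment
#'
#' A walk contains another walk as a subwalk when the latter's edge sequence
#' appears as a contiguous block of the former's. The empty walk is a
#' subwalk of every walk.
#'
#' @param haystack,needle Character vectors of edges.
#' @return `TRUE` iff `needle` occurs as a contiguous block of `haystack`.
#' @export
contains_subwalk <- function(haystack, needle) {
  m <- length(needle); n <- length(haystack)
  if (m == 0L) return(TRUE)
  if (m > n) return(FALSE)
  for (off in 0L:(n - m)) {
    if (all(haystack[off + seq_len(m)] == needle)) return(TRUE)
  }
  FALSE
}
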