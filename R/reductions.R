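#' Reduce an SCS instance to a CSM instance
#'
#' Encodes every instance string with the gadget code and sets both
#' character multiplicities to three times the SCS length bound:
#' `l_0 = l_1 = 3 l'`. Because each gadget is balanced with three `0`s and
#' three `1`s, a source string of length `l'` encodes to a string with
#' exactly `3 l'` of each character, so the two instances have the same
#' YES/NO answer.
#'
#' @param inst An [scs_instance()] over the binary alphabet.
#' @param code A [gadget_code()].
#' @return A [csm_instance()].
#' @examples
#' reduce_scs_to_csm(scs_instance("0", 1))
#' @export
reduce_scs_to_csm <- function(inst, code = default_gadget_code()) {
  stopifnot(inherits(inst, "scs_instance"))
  if (!identical(sort(inst$alphabet), c("0", "1")))
    stop_superwalk("the SCS to CSM reduction requires the binary alphabet",
                   "superwalk_unsupported_alphabet")
  half <- code$gadget_length %/% 2L
  csm_instance(vapply(inst$strings, gadget_encode, character(1L),
                      code = code, USE.NAMES = FALSE),
               c("0" = half * inst$length_bound,
                 "1" = half * inst$length_bound),
               alphabet = c("0", "1"))
}

#' Lift an SCS witness to a CSM witness
#'
#' Given a superstring `s_prime` of length `l'' <= l'` witnessing the SCS
#' instance, pads it with `0`s to length `l'` and encodes the result. The
#' padded encoding has exactly `3 l'` of each character and still contains
#' every encoded instance string, so it witnesses the reduced CSM instance.
#'
#' @param s_prime A string with `verify_scs(s_prime, inst)` true.
#' @param inst The original [scs_instance()].
#' @param code A [gadget_code()].
#' @return A CSM witness string.
#' @export
lift_scs_witness <- function(s_prime, inst, code = default_gadget_code()) {
  if (!verify_scs(s_prime, inst))
    stop_superwalk("s_prime does not witness the SCS instance",
                   "superwalk_invalid_witness")
  pad <- strrep("0", inst$length_bound - nchar(s_prime))
  gadget_encode(paste0(s_prime, pad), code)
}

#' Extract an SCS witness from a CSM witness
#'
#' The constructive inverse witness map. For each encoded instance string
#' the leftmost occurrence in `s` is recorded; the union of those
#' occurrence intervals is split into maximal covered runs. Overlapping
#' encoded occurrences align on gadget boundaries, so each run is itself
#' the image of a source string; each run is decoded and the decoded runs
#' are concatenated left to right. Every original string lies inside a
#' single run's decoding, and the total covered length is at most
#' `nchar(s) = 6 l'`, so the result witnesses the original SCS instance.
#'
#' @param s A string with `verify_csm(s, reduced)` true.
#' @param reduced The [csm_instance()] produced by [reduce_scs_to_csm()].
#' @param original The original [scs_instance()].
#' @param code A [gadget_code()].
#' @return An SCS witness string.
#' @export
extract_scs_witness <- function(s, reduced, original,
                                code = default_gadget_code()) {
  if (!verify_csm(s, reduced))
    stop_superwalk("s does not witness the CSM instance",
                   "superwalk_invalid_witness")
  enc <- reduced$strings
  enc <- enc[nchar(enc) > 0L]
  if (length(enc) == 0L) return("")
  starts <- integer(length(enc)); ends <- integer(length(enc))
  for (i in seq_along(enc)) {
    occ <- occurrence_positions(enc[i], s)
    if (length(occ) == 0L)
      stop_superwalk("an encoded string has no occurrence in s",
                     "superwalk_invalid_witness")
    starts[i] <- occ[1L]
    ends[i] <- occ[1L] + nchar(enc[i]) - 1L
  }
  # merge the leftmost-occurrence intervals into maximal covered runs
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  run_start <- starts[1L]; run_end <- ends[1L]
  pieces <- character(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= run_end + 1L) {
      run_end <- max(run_end, ends[i])
    } else {
      pieces <- c(pieces, substr(s, run_start, run_end))
      run_start <- starts[i]; run_end <- ends[i]
    }
  }
  pieces <- c(pieces, substr(s, run_start, run_end))
  paste0(vapply(pieces, gadget_decode, character(1L), code = code,
                USE.NAMES = FALSE),
         collapse = "")
}

#' Embedding of the two-loop graph into a de Bruijn graph of order k
#'
#' The CSM-to-DBSM reduction works on a conceptual one-vertex graph with
#' two loops, "edge 0" and "edge 1". For a given order `k` that graph is
#' embedded into a genuine de Bruijn graph: edge 0 becomes the loop
#' `0^(k+1)` at vertex `0^k`, and edge 1 becomes a cycle of `k + 1` edges
#' through `0^k` that carries a single `1` through every position of the
#' `(k+1)`-mer: `0^k 1`, `0^(k-1) 1 0`, ..., `1 0^k`.
#'
#' @param k Positive integer order.
#' @param alphabet Ordered character vector with at least two symbols; the
#'   first two play the roles of `0` and `1`.
#' @return Object of class `embedding_map` with fields `k`, `zero_edge`,
#'   `one_cycle`, and `base_vertex` (`0^k`).
#' @examples
#' build_embedding(2)  # zero_edge "000", one_cycle c("001", "010", "100")
#' @export
build_embedding <- function(k, alphabet = c("0", "1")) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop_superwalk("k must be a positive integer",
                   "superwalk_invalid_parameter")
  if (length(alphabet) < 2L)
    stop_superwalk("the alphabet must have at least two symbols",
                   "superwalk_invalid_parameter")
  z <- alphabet[1L]; o <- alphabet[2L]
  zero_edge <- strrep(z, k + 1L)
  one_cycle <- vapply(seq_len(k + 1L), function(i)
    paste0(strrep(z, k + 1L - i), o, strrep(z, i - 1L)), character(1L))
  structure(list(k = k, alphabet = alphabet, zero_edge = zero_edge,
                 one_cycle = one_cycle, base_vertex = strrep(z, k)),
            class = "embedding_map")
}

#' @export
print.embedding_map <- function(x, ...) {
  cat("Embedding (k = ", x$k, "): zero edge ", x$zero_edge,
      ", one-cycle ", paste(x$one_cycle, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Translate a binary string into a walk on the embedded graph
#'
#' Each `0` of the string contributes one traversal of the zero loop; each
#' `1` contributes the full one-cycle in order. All pieces start and end at
#' the base vertex `0^k`, so the concatenation is a valid walk of length
#' `#zeros + (k + 1) * #ones`.
#'
#' @param s Binary string.
#' @param emb An [build_embedding()] result.
#' @return Character vector of edges (possibly empty).
#' @export
translate_string_to_walk <- function(s, emb) {
  stopifnot(inherits(emb, "embedding_map"))
  cs <- chars(s)
  bad <- setdiff(cs, c("0", "1"))
  if (length(bad) > 0L)
    stop_superwalk(paste0("non-binary character(s): ",
                          paste(bad, collapse = ", ")),
                   "superwalk_invalid_input")
  pieces <- lapply(cs, function(ch)
    if (ch == "0") emb$zero_edge else emb$one_cycle)
  as.character(unlist(c(pieces, list(character(0)))))
}

#' Reduce a CSM instance to a DBSM instance
#'
#' The graph is the embedded two-loop graph for the given `k`; each CSM
#' string becomes a read walk via [translate_string_to_walk()]; the zero
#' loop gets multiplicity `l_0` and every edge of the one-cycle gets
#' multiplicity `l_1`. A superwalk meeting those multiplicities spells out
#' (via the inverse translation) exactly a string with `l_0` zeros and
#' `l_1` ones containing all the CSM strings, so the answer is preserved.
#' The zero edge is kept in the graph even when `l_0 = 0`.
#'
#' @param inst A [csm_instance()] over the binary alphabet.
#' @param k Positive integer order.
#' @param alphabet Target alphabet with at least two symbols.
#' @return A [dbsm_instance()].
#' @export
reduce_csm_to_dbsm <- function(inst, k, alphabet = c("0", "1")) {
  stopifnot(inherits(inst, "csm_instance"))
  if (!identical(sort(inst$alphabet), c("0", "1")))
    stop_superwalk("the CSM to DBSM reduction requires the binary alphabet",
                   "superwalk_unsupported_alphabet")
  emb <- build_embedding(k, alphabet)
  graph <- debruijn_graph(k, c(emb$zero_edge, emb$one_cycle), alphabet)
  walks <- lapply(inst$strings, translate_string_to_walk, emb = emb)
  mult <- stats::setNames(
    rep(inst$multiplicities[["1"]], length(emb$one_cycle)), emb$one_cycle)
  mult[emb$zero_edge] <- inst$multiplicities[["0"]]
  dbsm_instance(graph, walks, mult)
}

#' Parse a DBSM witness walk on the embedded graph back to a CSM witness
#'
#' Greedy left-to-right inverse of [translate_string_to_walk()]: a zero
#' edge yields `'0'`; a complete one-cycle block yields `'1'`; anything
#' else (a partial cycle) is an error.
#'
#' @param w Character vector of edges over the embedded graph.
#' @param emb An [build_embedding()] result.
#' @return The parsed binary string.
#' @export
map_walk_witness_to_csm <- function(w, emb) {
  stopifnot(inherits(emb, "embedding_map"))
  w <- as.character(w)
  out <- character(0)
  i <- 1L
  cyc <- emb$one_cycle
  clen <- length(cyc)
  while (i <= length(w)) {
    if (w[i] == emb$zero_edge) {
      out <- c(out, "0")
      i <- i + 1L
    } else if (i + clen - 1L <= length(w) &&
               all(w[i:(i + clen - 1L)] == cyc)) {
      out <- c(out, "1")
      i <- i + clen
    } else {
      stop_superwalk(paste0("walk is not parseable at edge ", i,
                            ": partial one-cycle block"),
                     "superwalk_unparseable_walk")
    }
  }
  paste0(out, collapse = "")
}
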