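#' Solver results
#'
#' Every exact solver returns a `solver_result`: the YES/NO answer, a
#' witness when the answer is YES (a string for SCS/CSM, an edge vector for
#' DBSM), and a search-size diagnostic. Witnesses always pass the matching
#' verifier. All searches explore in fixed lexicographic order, so repeated
#' runs return identical witnesses.
#'
#' @param answer Logical: `TRUE` for YES.
#' @param witness The witness, or `NULL` for NO.
#' @param nodes_explored Number of search nodes (or DP states) visited.
#' @param kind One of `"scs"`, `"csm"`, `"dbsm"`.
#' @return Object of class `solver_result`.
#' @export
solver_result <- function(answer, witness = NULL, nodes_explored = 0,
                          kind = c("scs", "csm", "dbsm")) {
  kind <- match.arg(kind)
  stopifnot(is.logical(answer), length(answer) == 1L)
  if (answer && is.null(witness))
    stop_superwalk("a YES result requires a witness", "superwalk_internal")
  structure(list(answer = answer, witness = witness,
                 nodes_explored = as.numeric(nodes_explored), kind = kind),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(toupper(x$kind), " solver: ", if (x$answer) "YES" else "NO", sep = "")
  if (x$answer) {
    w <- if (is.character(x$witness) && length(x$witness) == 1L)
      x$witness else paste(x$witness, collapse = " ")
    cat(", witness: ", if (nchar(w) > 0L) w else "(empty)", sep = "")
  }
  cat(" (", format(x$nodes_explored, big.mark = ","), " nodes)\n", sep = "")
  invisible(x)
}

check_size <- function(value, limit, what, force) {
  if (value > limit && !force)
    stop_superwalk(paste0(what, " (", value, ") exceeds the exact-search ",
                          "soft limit ", limit,
                          "; pass force = TRUE to override"),
                   "superwalk_size_limit")
  invisible(TRUE)
}

#' Exact solver for the Shortest Common Superstring decision problem
#'
#' Removes strings that are substrings of others, then finds the minimum
#' superstring length by dynamic programming over subsets of strings with
#' pairwise maximal overlaps (Held-Karp style). The answer is YES iff the
#' optimum is at most the length bound; the witness is a shortest merge.
#'
#' @param inst An [scs_instance()].
#' @param force Override the soft size limit of 8 distinct strings.
#' @return A [solver_result()] of kind `"scs"`.
#' @examples
#' solve_scs_exact(scs_instance(c("01", "10"), 3))
#' @export
solve_scs_exact <- function(inst, force = FALSE) {
  stopifnot(inherits(inst, "scs_instance"))
  strs <- unique(inst$strings)
  strs <- strs[nchar(strs) > 0L]
  if (length(strs) > 1L) {
    keep <- vapply(seq_along(strs), function(i)
      !any(vapply(seq_along(strs)[-i], function(j)
        length(occurrence_positions(strs[i], strs[j])) > 0L,
        logical(1L))), logical(1L))
    strs <- strs[keep]
  }
  strs <- sort(strs)
  n <- length(strs)
  check_size(n, 8L, "number of substring-free strings", force)
  if (n == 0L) {
    return(solver_result(TRUE, witness = "", nodes_explored = 1, kind = "scs"))
  }
  lens <- nchar(strs)
  # ov[i, j]: longest suffix of strs[i] equal to a prefix of strs[j]
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (t in rev(seq_len(min(lens[i], lens[j])))) {
      if (substr(strs[i], lens[i] - t + 1L, lens[i]) ==
          substr(strs[j], 1L, t)) { ov[i, j] <- t; break }
    }
  }
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, full, n)        # dp[mask, j]: best length ending in j
  parent <- matrix(0L, full, n)
  for (j in seq_len(n)) dp[bitwShiftL(1L, j - 1L), j] <- lens[j]
  nodes <- 0
  for (mask in seq_len(full)) {
    for (j in seq_len(n)) {
      if (!is.finite(dp[mask, j])) next
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) == 0L) next
      for (i in seq_len(n)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nmask <- bitwOr(mask, bit)
        cand <- dp[mask, j] + lens[i] - ov[j, i]
        nodes <- nodes + 1
        if (cand < dp[nmask, i]) {
          dp[nmask, i] <- cand
          parent[nmask, i] <- j
        }
      }
    }
  }
  best_j <- which.min(dp[full, ])
  opt <- dp[full, best_j]
  # reconstruct the shortest merge
  order_idx <- integer(n)
  mask <- full; j <- best_j
  for (pos in rev(seq_len(n))) {
    order_idx[pos] <- j
    pj <- parent[mask, j]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  witness <- strs[order_idx[1L]]
  for (pos in seq_len(n)[-1L]) {
    i <- order_idx[pos]; p <- order_idx[pos - 1L]
    witness <- paste0(witness,
                      substr(strs[i], ov[p, i] + 1L, lens[i]))
  }
  stopifnot(nchar(witness) == opt)
  if (opt <= inst$length_bound)
    solver_result(TRUE, witness = witness, nodes_explored = nodes,
                  kind = "scs")
  else
    solver_result(FALSE, nodes_explored = nodes, kind = "scs")
}

#' Exact solver for Common Superstring with Multiplicities
#'
#' Depth-first construction of candidate strings character by character in
#' alphabet order, so the returned witness is the lexicographically least
#' solution. The search prunes on remaining per-character budgets and on a
#' feasibility check that every not-yet-matched instance string can still
#' fit: some suffix-of-prefix overlap must leave it enough remaining length
#' and enough remaining characters of each kind.
#'
#' @param inst A [csm_instance()].
#' @param force Override the soft limit of 24 on the total multiplicity.
#' @return A [solver_result()] of kind `"csm"`.
#' @examples
#' solve_csm_exact(csm_instance("000111", c("0" = 3, "1" = 3)))
#' @export
solve_csm_exact <- function(inst, force = FALSE) {
  stopifnot(inherits(inst, "csm_instance"))
  total <- sum(inst$multiplicities)
  check_size(total, 24L, "total multiplicity", force)
  alpha <- inst$alphabet
  A <- length(alpha)
  strs <- unique(inst$strings)
  strs <- strs[nchar(strs) > 0L]
  svec <- lapply(strs, function(s) match(chars(s), alpha))
  slen <- lengths(svec)
  # tail_counts[[i]][t + 1, a]: count of alphabet symbol a in s_i[(t+1)..]
  tail_counts <- lapply(svec, function(v) {
    m <- matrix(0L, length(v) + 1L, A)
    for (t in rev(seq_along(v)))
      m[t, ] <- m[t + 1L, ] + tabulate(v[t], A)
    m
  })
  budget0 <- as.integer(inst$multiplicities[alpha])
  ns <- length(svec)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0
  prefix <- integer(total)

  feasible <- function(depth, budget, matched) {
    rem_len <- total - depth
    for (i in seq_len(ns)) {
      if (matched[i]) next
      ok <- FALSE
      for (t in 0:min(depth, slen[i] - 1L)) {
        if (t > 0L &&
            !identical(prefix[(depth - t + 1L):depth], svec[[i]][1:t]))
          next
        if (slen[i] - t <= rem_len &&
            all(tail_counts[[i]][t + 1L, ] <= budget)) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }

  dfs <- function(depth, budget, matched) {
    env$nodes <- env$nodes + 1
    if (depth == total) {
      if (all(matched)) return(paste0(alpha[prefix[seq_len(total)]],
                                      collapse = ""))
      return(NULL)
    }
    if (!feasible(depth, budget, matched)) return(NULL)
    for (a in seq_len(A)) {
      if (budget[a] == 0L) next
      prefix[depth + 1L] <<- a
      nb <- budget; nb[a] <- nb[a] - 1L
      nm <- matched
      for (i in seq_len(ns)) {
        if (nm[i] || slen[i] > depth + 1L) next
        if (identical(prefix[(depth + 2L - slen[i]):(depth + 1L)], svec[[i]]))
          nm[i] <- TRUE
      }
      res <- dfs(depth + 1L, nb, nm)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  witness <- dfs(0L, budget0, rep(FALSE, ns))
  if (is.null(witness))
    solver_result(FALSE, nodes_explored = env$nodes, kind = "csm")
  else
    solver_result(TRUE, witness = witness, nodes_explored = env$nodes,
                  kind = "csm")
}

#' Exact solver for De Bruijn Superwalk with Multiplicities
#'
#' Depth-first search over edge sequences from every possible start vertex,
#' maintaining remaining multiplicities and, for every read, the set of
#' in-progress partial block matches. Branches are pruned when no remaining
#' overlap can still host an unmatched read (either its remaining edges
#' exceed the remaining walk length or some edge it still needs is
#' exhausted). Edges are explored in lexicographic order, so the witness is
#' deterministic.
#'
#' @param inst A [dbsm_instance()].
#' @param force Override the soft limit of 30 on the total multiplicity.
#' @return A [solver_result()] of kind `"dbsm"`; the witness is a character
#'   vector of edges.
#' @export
solve_dbsm_exact <- function(inst, force = FALSE) {
  stopifnot(inherits(inst, "dbsm_instance"))
  total <- sum(inst$multiplicities)
  check_size(total, 30L, "total multiplicity", force)
  edges <- names(inst$multiplicities)      # sorted lexicographically
  E <- length(edges)
  k <- inst$k
  verts <- inst$graph$vertices
  epre <- match(substr(edges, 1L, k), verts)
  esuf <- match(substr(edges, 2L, k + 1L), verts)
  rem0 <- as.integer(inst$multiplicities)
  reads <- lapply(inst$read_walks, function(w) match(w, edges))
  reads <- reads[lengths(reads) > 0L]       # empty reads are vacuous
  nr <- length(reads)
  rlen <- lengths(reads)
  # tail_edge_counts[[r]][p + 1, e]: occurrences of edge e in r[(p+1)..]
  tail_edge_counts <- lapply(reads, function(v) {
    m <- matrix(0L, length(v) + 1L, E)
    for (t in rev(seq_along(v)))
      m[t, ] <- m[t + 1L, ] + tabulate(v[t], E)
    m
  })
  env <- new.env(parent = emptyenv())
  env$nodes <- 0
  walk <- integer(total)

  feasible <- function(depth, rem, matched, active) {
    rem_len <- total - depth
    for (r in seq_len(nr)) {
      if (matched[r]) next
      ok <- FALSE
      for (t in c(active[[r]], 0L)) {
        if (rlen[r] - t <= rem_len &&
            all(tail_edge_counts[[r]][t + 1L, ] <= rem)) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }

  dfs <- function(depth, cur, rem, matched, active) {
    env$nodes <- env$nodes + 1
    if (depth == total) {
      if (all(matched)) return(walk[seq_len(total)])
      return(NULL)
    }
    if (!feasible(depth, rem, matched, active)) return(NULL)
    for (e in seq_len(E)) {
      if (rem[e] == 0L) next
      if (depth > 0L && epre[e] != cur) next
      walk[depth + 1L] <<- e
      nrem <- rem; nrem[e] <- nrem[e] - 1L
      nm <- matched
      na <- active
      for (r in seq_len(nr)) {
        if (nm[r]) next
        cand <- c(na[[r]] + 1L, 1L)
        cand <- cand[reads[[r]][cand] == e]
        if (any(cand == rlen[r])) {
          nm[r] <- TRUE
        } else {
          na[[r]] <- cand
        }
      }
      res <- dfs(depth + 1L, esuf[e], nrem, nm, na)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  res <- dfs(0L, 0L, rem0, rep(FALSE, nr), rep(list(integer(0)), nr))
  if (is.null(res))
    solver_result(FALSE, nodes_explored = env$nodes, kind = "dbsm")
  else
    solver_result(TRUE, witness = edges[res], nodes_explored = env$nodes,
                  kind = "dbsm")
}

#' Polynomial solver for the single-edge-read special case of DBSM
#'
#' When every read walk consists of a single edge (or is empty), DBSM
#' collapses to an exact-multiplicity Eulerian walk question: duplicate
#' each edge by its multiplicity and ask whether the resulting directed
#' multigraph admits an Eulerian walk, with every single-edge read's edge
#' present at multiplicity at least one. The witness is built with the
#' standard cycle-splicing construction; when all degrees are balanced the
#' walk starts at the lexicographically least non-isolated vertex.
#'
#' @param inst A [dbsm_instance()] whose reads all have at most one edge.
#' @return A [solver_result()] of kind `"dbsm"`.
#' @export
solve_dbsm_single_edge <- function(inst) {
  stopifnot(inherits(inst, "dbsm_instance"))
  if (any(lengths(inst$read_walks) > 1L))
    stop_superwalk("a read has more than one edge: not the single-edge case",
                   "superwalk_wrong_special_case")
  mult <- inst$multiplicities
  needed <- unique(unlist(c(inst$read_walks, list(character(0)))))
  if (length(needed) > 0L && any(mult[needed] < 1L))
    return(solver_result(FALSE, nodes_explored = 1, kind = "dbsm"))
  pos <- mult[mult > 0L]
  if (length(pos) == 0L)
    return(solver_result(TRUE, witness = character(0), nodes_explored = 1,
                         kind = "dbsm"))
  k <- inst$k
  pre <- substr(names(pos), 1L, k)
  suf <- substr(names(pos), 2L, k + 1L)
  verts <- sort(unique(c(pre, suf)))
  outdeg <- stats::setNames(numeric(length(verts)), verts)
  indeg <- outdeg
  for (i in seq_along(pos)) {
    outdeg[pre[i]] <- outdeg[pre[i]] + pos[i]
    indeg[suf[i]] <- indeg[suf[i]] + pos[i]
  }
  d <- outdeg - indeg
  if (any(abs(d) > 1) || sum(d == 1) > 1L || sum(d == -1) > 1L)
    return(solver_result(FALSE, nodes_explored = 1, kind = "dbsm"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pre, to = suf, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  if (igraph::components(g)$no > 1L)
    return(solver_result(FALSE, nodes_explored = 1, kind = "dbsm"))
  start <- if (any(d == 1)) verts[d == 1][1L] else verts[1L]
  # Hierholzer on the multigraph: per-vertex outgoing edge lists in
  # lexicographic order, each edge repeated by its multiplicity
  adj <- lapply(stats::setNames(verts, verts), function(v) {
    e <- rep(names(pos)[pre == v], times = pos[pre == v])
    sort(e)
  })
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  st_v <- start
  st_e <- character(0)
  circuit <- character(0)
  steps <- 0
  while (length(st_v) > 0L) {
    v <- st_v[length(st_v)]
    if (ptr[v] <= length(adj[[v]])) {
      e <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      st_v <- c(st_v, substr(e, 2L, k + 1L))
      st_e <- c(st_e, e)
      steps <- steps + 1
    } else {
      st_v <- st_v[-length(st_v)]
      if (length(st_e) > 0L) {
        circuit <- c(st_e[length(st_e)], circuit)
        st_e <- st_e[-length(st_e)]
      }
    }
  }
  if (length(circuit) != sum(pos))   # unreachable after connectivity check
    return(solver_result(FALSE, nodes_explored = steps, kind = "dbsm"))
  solver_result(TRUE, witness = circuit, nodes_explored = steps,
                kind = "dbsm")
}
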