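# Seeded random instance builders for round-trip and agreement tests.

rand_scs_instance <- function() {
  n <- sample(0:3, 1L)
  strings <- vapply(seq_len(n), function(i)
    rand_binary_string(sample(1:5, 1L)), character(1L))
  scs_instance(as.character(strings), sample(0:8, 1L))
}

rand_csm_instance <- function() {
  n <- sample(0:3, 1L)
  strings <- vapply(seq_len(n), function(i)
    rand_binary_string(sample(1:4, 1L)), character(1L))
  csm_instance(as.character(strings),
               c("0" = sample(0:5, 1L), "1" = sample(0:5, 1L)))
}

rand_dbsm_instance <- function() {
  planted_dbsm(genome_length = sample(6:10, 1L), n_reads = sample(1:3, 1L),
               read_length = 4L, k = sample(1:2, 1L),
               seed = sample.int(10000L, 1L))
}

# Random DBSM instance whose reads are all single edges; mixes YES and NO
# shapes (disconnection, imbalance, multiplicity-zero read edges arise by
# chance). Total multiplicity is capped at 12.
rand_single_edge_instance <- function() {
  k <- sample(1:2, 1L)
  universe <- superwalk:::all_strings(k + 1L)
  edges <- sample(universe, sample(1:min(4L, length(universe)), 1L))
  mult <- stats::setNames(sample(0:3, length(edges), replace = TRUE), edges)
  while (sum(mult) > 12L) mult[sample(names(mult), 1L)] <- 0L
  n_reads <- sample(0:3, 1L)
  reads <- lapply(seq_len(n_reads), function(i) sample(edges, 1L))
  dbsm_instance(debruijn_graph(k, edges), reads, mult)
}
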