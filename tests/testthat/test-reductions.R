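test_that("the SCS to CSM reduction encodes strings and triples the bound", {
  red <- reduce_scs_to_csm(scs_instance("0", 1))
  expect_identical(red$strings, "000111")
  expect_identical(red$multiplicities, c("0" = 3L, "1" = 3L))
  red0 <- reduce_scs_to_csm(scs_instance(character(0), 0))
  expect_identical(red0$strings, character(0))
  expect_identical(red0$multiplicities, c("0" = 0L, "1" = 0L))
  red2 <- reduce_scs_to_csm(scs_instance(c("01", "10"), 3))
  expect_identical(red2$strings, c("000111001011", "001011000111"))
  expect_identical(red2$multiplicities, c("0" = 9L, "1" = 9L))
  expect_error(reduce_scs_to_csm(scs_instance("a", 1, alphabet = "a")),
               class = "superwalk_unsupported_alphabet")
})

test_that("SCS witnesses lift to CSM witnesses by zero-padding", {
  expect_identical(lift_scs_witness("0", scs_instance("0", 1)), "000111")
  expect_identical(lift_scs_witness("0", scs_instance("0", 2)),
                   "000111000111")
  expect_identical(lift_scs_witness("", scs_instance(character(0), 0)), "")
  expect_error(lift_scs_witness("1", scs_instance("0", 1)),
               class = "superwalk_invalid_witness")
})

test_that("CSM witnesses extract to SCS witnesses via covered runs", {
  orig <- scs_instance("01", 2)
  red <- reduce_scs_to_csm(orig)
  expect_identical(extract_scs_witness("000111001011", red, orig), "01")
  orig0 <- scs_instance(character(0), 0)
  expect_identical(
    extract_scs_witness("", reduce_scs_to_csm(orig0), orig0), "")
  # leftmost occurrence covers positions 1-6 only; the padding is dropped
  orig1 <- scs_instance("1", 2)
  red1 <- reduce_scs_to_csm(orig1)
  expect_identical(extract_scs_witness("001011000111", red1, orig1), "1")
  expect_error(extract_scs_witness("001011", red1, orig1),
               class = "superwalk_invalid_witness")
})

test_that("the embedding maps edge 0 to a loop and edge 1 to a k+1 cycle", {
  e1 <- build_embedding(1)
  expect_identical(e1$zero_edge, "00")
  expect_identical(e1$one_cycle, c("01", "10"))
  e2 <- build_embedding(2)
  expect_identical(e2$zero_edge, "000")
  expect_identical(e2$one_cycle, c("001", "010", "100"))
  expect_error(build_embedding(0), class = "superwalk_invalid_parameter")
  expect_error(build_embedding(1, alphabet = "0"),
               class = "superwalk_invalid_parameter")
  for (k in 1:5) {
    emb <- build_embedding(k)
    expect_length(emb$one_cycle, k + 1L)
    ones <- vapply(emb$one_cycle, function(e)
      sum(superwalk:::chars(e) == "1"), integer(1L))
    expect_true(all(ones == 1L))
    expect_identical(substr(emb$one_cycle[1L], 1L, k), emb$base_vertex)
    expect_identical(substr(emb$one_cycle[k + 1L], 2L, k + 1L),
                     emb$base_vertex)
    expect_false(emb$zero_edge %in% emb$one_cycle)
    expect_true(superwalk:::walk_is_valid(emb$one_cycle, k))
  }
})

test_that("strings translate to walks with the right traversal counts", {
  expect_identical(translate_string_to_walk("1", build_embedding(2)),
                   c("001", "010", "100"))
  expect_identical(translate_string_to_walk("", build_embedding(1)),
                   character(0))
  expect_identical(translate_string_to_walk("01", build_embedding(1)),
                   c("00", "01", "10"))
  expect_error(translate_string_to_walk("2", build_embedding(1)),
               class = "superwalk_invalid_input")
  withr::with_seed(505, {
    for (i in 1:25) {
      k <- sample(1:3, 1L)
      emb <- build_embedding(k)
      s <- rand_binary_string(sample(0:8, 1L))
      w <- translate_string_to_walk(s, emb)
      cc <- char_counts(s)
      expect_length(w, cc[["0"]] + (k + 1L) * cc[["1"]])
      expect_identical(sum(w == emb$zero_edge), cc[["0"]])
      for (e in emb$one_cycle) expect_identical(sum(w == e), cc[["1"]])
      expect_true(superwalk:::walk_is_valid(w, k))
      expect_identical(map_walk_witness_to_csm(w, emb), s)
    }
  })
})

test_that("the CSM to DBSM reduction builds the embedded instance", {
  red <- reduce_csm_to_dbsm(csm_instance("000111", c("0" = 3, "1" = 3)),
                            k = 1)
  expect_identical(red$graph$edges, c("00", "01", "10"))
  expect_identical(red$read_walks[[1]],
                   c("00", "00", "00", "01", "10", "01", "10", "01", "10"))
  expect_identical(red$multiplicities, c("00" = 3L, "01" = 3L, "10" = 3L))
  red0 <- reduce_csm_to_dbsm(csm_instance(character(0),
                                          c("0" = 0, "1" = 0)), k = 1)
  expect_length(red0$read_walks, 0L)
  expect_true(all(red0$multiplicities == 0L))
  red2 <- reduce_csm_to_dbsm(csm_instance("1", c("0" = 0, "1" = 1)), k = 2)
  expect_identical(red2$read_walks[[1]], c("001", "010", "100"))
  expect_identical(red2$multiplicities,
                   c("000" = 0L, "001" = 1L, "010" = 1L, "100" = 1L))
  # the graph always has exactly k + 2 edges
  for (k in 1:4) {
    r <- reduce_csm_to_dbsm(csm_instance("0", c("0" = 1, "1" = 0)), k = k)
    expect_length(r$graph$edges, k + 2L)
  }
})

test_that("partial one-cycle blocks are rejected by the inverse parse", {
  emb <- build_embedding(1)
  expect_identical(map_walk_witness_to_csm(c("00", "01", "10"), emb), "01")
  expect_identical(map_walk_witness_to_csm(character(0), emb), "")
  expect_error(map_walk_witness_to_csm("01", emb),
               class = "superwalk_unparseable_walk")
})

test_that("encoded strings are exactly six times their source length", {
  withr::with_seed(606, {
    for (i in 1:25) {
      s <- rand_binary_string(sample(0:10, 1L))
      expect_identical(nchar(gadget_encode(s)), 6L * nchar(s))
    }
  })
})
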