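test_that("the exact SCS solver answers the worked examples", {
  r <- solve_scs_exact(scs_instance(c("01", "10"), 3))
  expect_true(r$answer)
  expect_true(r$witness %in% c("010", "101"))
  expect_false(solve_scs_exact(scs_instance(c("01", "10"), 2))$answer)
  r0 <- solve_scs_exact(scs_instance(character(0), 0))
  expect_true(r0$answer)
  expect_identical(r0$witness, "")
})

test_that("the exact SCS solver agrees with naive enumeration", {
  for (inst in exhaustive_scs_corpus(2, 2, 4)) {
    r <- solve_scs_exact(inst)
    expect_identical(r$answer, naive_scs_answer(inst))
    if (r$answer) expect_true(verify_scs(r$witness, inst))
  }
})

test_that("the exact CSM solver answers the worked examples", {
  r <- solve_csm_exact(csm_instance("000111", c("0" = 3, "1" = 3)))
  expect_true(r$answer)
  expect_identical(r$witness, "000111")
  expect_false(solve_csm_exact(
    csm_instance(c("000111001011", "001011000111"),
                 c("0" = 6, "1" = 6)))$answer)
  r0 <- solve_csm_exact(csm_instance(character(0), c("0" = 0, "1" = 0)))
  expect_true(r0$answer)
  expect_identical(r0$witness, "")
})

test_that("the exact CSM solver agrees with naive enumeration", {
  withr::with_seed(707, {
    for (i in 1:60) {
      n <- sample(0:2, 1L)
      strings <- vapply(seq_len(n), function(j)
        rand_binary_string(sample(1:4, 1L)), character(1L))
      inst <- csm_instance(as.character(strings),
                           c("0" = sample(0:4, 1L), "1" = sample(0:4, 1L)))
      r <- solve_csm_exact(inst)
      expect_identical(r$answer, naive_csm_answer(inst))
      if (r$answer) expect_true(verify_csm(r$witness, inst))
    }
  })
})

test_that("the CSM answer is invariant under string permutation and the
           witness is lexicographically least", {
  inst <- csm_instance(c("01", "10"), c("0" = 2, "1" = 2))
  perm <- csm_instance(c("10", "01"), c("0" = 2, "1" = 2))
  r1 <- solve_csm_exact(inst)
  r2 <- solve_csm_exact(perm)
  expect_identical(r1$answer, r2$answer)
  expect_identical(r1$witness, r2$witness)
  # every string with those counts containing both "01" and "10":
  # 0101 0110 1010 1001 -> least is 0101
  expect_identical(r1$witness, "0101")
})

test_that("the exact DBSM solver answers the worked examples", {
  g <- debruijn_graph(1, c("00", "01", "10"))
  read <- c("00", "00", "00", "01", "10", "01", "10", "01", "10")
  inst <- dbsm_instance(g, list(read), c("00" = 3, "01" = 3, "10" = 3))
  r <- solve_dbsm_exact(inst)
  expect_true(r$answer)
  expect_true(verify_dbsm(r$witness, inst))
  no <- dbsm_instance(debruijn_graph(1, "00"), list("00"), c("00" = 0))
  expect_false(solve_dbsm_exact(no)$answer)
  empty <- dbsm_instance(debruijn_graph(1, "00"), list(), c("00" = 0))
  r0 <- solve_dbsm_exact(empty)
  expect_true(r0$answer)
  expect_length(r0$witness, 0L)
})

test_that("the Eulerian solver handles the two-loop worked examples", {
  g <- debruijn_graph(1, c("00", "01", "10"))
  inst <- dbsm_instance(g, list("00", "01"),
                        c("00" = 2, "01" = 1, "10" = 1))
  r <- solve_dbsm_single_edge(inst)
  expect_true(r$answer)
  expect_true(verify_dbsm(r$witness, inst))
  # two disconnected loops with positive multiplicities
  g2 <- debruijn_graph(1, c("00", "11"))
  expect_false(solve_dbsm_single_edge(
    dbsm_instance(g2, list(), c("00" = 1, "11" = 1)))$answer)
  # all multiplicities zero, no reads
  r0 <- solve_dbsm_single_edge(
    dbsm_instance(debruijn_graph(1, "00"), list(), c("00" = 0)))
  expect_true(r0$answer)
  expect_length(r0$witness, 0L)
  expect_error(solve_dbsm_single_edge(
    dbsm_instance(g, list(c("01", "10")),
                  c("00" = 0, "01" = 1, "10" = 1))),
    class = "superwalk_wrong_special_case")
})

test_that("the Eulerian solver agrees with the exact search", {
  withr::with_seed(808, {
    n_yes <- 0L
    for (i in 1:300) {
      inst <- rand_single_edge_instance()
      re <- solve_dbsm_exact(inst)
      rs <- solve_dbsm_single_edge(inst)
      expect_identical(rs$answer, re$answer)
      if (rs$answer) {
        n_yes <- n_yes + 1L
        expect_true(verify_dbsm(rs$witness, inst))
        expect_true(verify_dbsm(re$witness, inst))
      }
    }
    expect_gt(n_yes, 10L)  # the random mix must exercise both answers
    expect_lt(n_yes, 290L)
  })
})

test_that("soft size limits refuse loudly and can be overridden", {
  big_scs <- scs_instance(superwalk:::all_strings(4)[1:9], 40)
  expect_error(solve_scs_exact(big_scs), class = "superwalk_size_limit")
  expect_true(solve_scs_exact(big_scs, force = TRUE)$answer)
  big_csm <- csm_instance(character(0), c("0" = 20, "1" = 20))
  expect_error(solve_csm_exact(big_csm), class = "superwalk_size_limit")
  big_dbsm <- dbsm_instance(debruijn_graph(1, "00"), list(), c("00" = 31))
  expect_error(solve_dbsm_exact(big_dbsm), class = "superwalk_size_limit")
  expect_true(solve_dbsm_exact(big_dbsm, force = TRUE)$answer)
})

test_that("solver results carry witnesses only on YES", {
  expect_error(solver_result(TRUE, witness = NULL, kind = "scs"),
               class = "superwalk_internal")
  r <- solver_result(FALSE, kind = "csm")
  expect_null(r$witness)
  expect_output(print(solve_scs_exact(scs_instance("0", 1))), "YES")
})
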