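#' Read and write instances as JSON
#'
#' The on-disk dialect is a single JSON object with a `"problem"` tag:
#'
#' * SCS: `{"problem":"scs","alphabet":["0","1"],"strings":[...],"length_bound":3}`
#' * CSM: `{"problem":"csm","alphabet":[...],"strings":[...],"multiplicities":{"0":3,"1":3}}`
#' * DBSM: `{"problem":"dbsm","k":1,"alphabet":[...],"edges":{"00":3,...},"reads":[["00","01"],...]}`
#'
#' With `unary = TRUE`, multiplicities are serialized as strings of `'1'`
#' repeated `m` times (and `"unary": true` is recorded), honouring the
#' convention that multiplicities are part of the input size. Both forms
#' are accepted on read.
#'
#' @param inst An instance object.
#' @param path File path.
#' @param unary Serialize multiplicities in unary notation.
#' @return `read_instance` returns the instance; `write_instance` returns
#'   `path` invisibly.
#' @name instance_io
NULL

#' @rdname instance_io
#' @export
write_instance <- function(inst, path, unary = FALSE) {
  ser_mult <- function(m) {
    if (unary) as.list(stats::setNames(strrep("1", m), names(m)))
    else as.list(m)
  }
  obj <- if (inherits(inst, "scs_instance")) {
    list(problem = "scs", alphabet = as.list(inst$alphabet),
         strings = as.list(inst$strings),
         length_bound = inst$length_bound)
  } else if (inherits(inst, "csm_instance")) {
    list(problem = "csm", alphabet = as.list(inst$alphabet),
         strings = as.list(inst$strings),
         multiplicities = ser_mult(inst$multiplicities))
  } else if (inherits(inst, "dbsm_instance")) {
    list(problem = "dbsm", k = inst$k, alphabet = as.list(inst$alphabet),
         edges = ser_mult(inst$multiplicities),
         reads = lapply(inst$read_walks, as.list))
  } else {
    stop_superwalk("not a recognised instance object",
                   "superwalk_invalid_input")
  }
  if (unary) obj$unary <- TRUE
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname instance_io
#' @export
read_instance <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$problem))
    stop_superwalk("instance JSON lacks a 'problem' tag",
                   "superwalk_invalid_input")
  unary <- isTRUE(obj$unary)
  parse_mult <- function(m) {
    vals <- if (unary) vapply(m, function(x) nchar(as.character(x)),
                              integer(1L))
            else vapply(m, as.integer, integer(1L))
    stats::setNames(vals, names(m))
  }
  alphabet <- as.character(unlist(c(obj$alphabet, list(character(0)))))
  switch(obj$problem,
    scs = scs_instance(as.character(unlist(c(obj$strings,
                                             list(character(0))))),
                       obj$length_bound, alphabet),
    csm = csm_instance(as.character(unlist(c(obj$strings,
                                             list(character(0))))),
                       parse_mult(obj$multiplicities), alphabet),
    dbsm = {
      mult <- parse_mult(obj$edges)
      graph <- debruijn_graph(obj$k, names(mult), alphabet)
      reads <- lapply(obj$reads, function(r)
        as.character(unlist(c(r, list(character(0))))))
      dbsm_instance(graph, reads, mult)
    },
    stop_superwalk(paste0("unknown problem tag: ", obj$problem),
                   "superwalk_invalid_input"))
}

#' Write a DBSM graph as a plain edge-list file
#'
#' One line per edge: the `(k+1)`-mer, a tab, and its multiplicity.
#'
#' @param inst A [dbsm_instance()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(inst, path) {
  stopifnot(inherits(inst, "dbsm_instance"))
  writeLines(paste0(names(inst$multiplicities), "\t", inst$multiplicities),
             path)
  invisible(path)
}
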