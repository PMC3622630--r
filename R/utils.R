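# Internal helpers shared across modules.

# Split a string into its character vector (always character(0) for "").
chars <- function(s) {
  if (nchar(s) == 0L) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1L]]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# All strings of length `len` over `alphabet`, in lexicographic order.
all_strings <- function(len, alphabet = c("0", "1")) {
  if (len == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse columns for lex order
  out <- do.call(paste0, rev(grid))
  sort(out)
}

stop_superwalk <- function(msg, class) {
  stop(structure(class = c(class, "superwalk_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
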