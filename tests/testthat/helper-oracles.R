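# Independent brute-force oracles used to cross-check the implementation.

# All strings of length 0..max_len over the binary alphabet.
all_binary_up_to <- function(max_len, include_empty = TRUE) {
  out <- unlist(lapply(seq_len(max_len), function(l)
    superwalk:::all_strings(l)))
  if (include_empty) c("", out) else out
}

# Brute-force SCS decision: enumerate every string of length <= l'.
naive_scs_answer <- function(inst) {
  for (len in 0:inst$length_bound) {
    for (cand in superwalk:::all_strings(len, inst$alphabet)) {
      if (all(vapply(inst$strings, function(s)
        grepl(s, cand, fixed = TRUE) || nchar(s) == 0L, logical(1L))))
        return(TRUE)
    }
  }
  FALSE
}

# Brute-force CSM decision: enumerate every string of the implied length.
naive_csm_answer <- function(inst) {
  total <- sum(inst$multiplicities)
  for (cand in superwalk:::all_strings(total, inst$alphabet)) {
    if (verify_csm(cand, inst)) return(TRUE)
  }
  total == 0L && verify_csm("", inst)
}

# All lengths t >= 1 such that the length-t suffix of s1 equals the
# length-t prefix of s2 (includes non-proper overlaps).
naive_overlaps <- function(s1, s2) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  Filter(function(t)
    substr(s1, n1 - t + 1L, n1) == substr(s2, 1L, t),
    seq_len(min(n1, n2)))
}

# Set-intersection formulation of the gadget non-overlap property.
naive_nonoverlap_ok <- function(code) {
  g <- unname(code$gadgets)
  sufs <- unlist(lapply(g, function(s)
    substring(s, seq_len(nchar(s))[-1L], nchar(s))))
  pres <- unlist(lapply(g, function(s)
    substring(s, 1L, seq_len(nchar(s) - 1L))))
  length(intersect(sufs, pres)) == 0L
}

# All-offsets subwalk scanner.
naive_contains_subwalk <- function(haystack, needle) {
  if (length(needle) == 0L) return(TRUE)
  if (length(needle) > length(haystack)) return(FALSE)
  any(vapply(0:(length(haystack) - length(needle)), function(off)
    identical(haystack[off + seq_along(needle)], needle), logical(1L)))
}

rand_binary_string <- function(len) {
  if (len == 0L) return("")
  paste0(sample(c("0", "1"), len, replace = TRUE), collapse = "")
}
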