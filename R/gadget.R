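#' Character gadget codes
#'
#' A gadget code maps each source character to a fixed binary string (a
#' "gadget"). The packaged default maps `"0"` to `"000111"` and `"1"` to
#' `"001011"`. These two strings are balanced (three `0`s and three `1`s
#' each) and mutually non-overlapping: no proper suffix of either gadget
#' equals a proper prefix of either gadget. Those two properties are what
#' make encodings impossible to misalign, so that every occurrence of an
#' encoded string inside another encoded string sits on a gadget boundary.
#'
#' @param gadgets Named character vector mapping single source characters to
#'   gadget strings of equal length.
#' @param check If `TRUE` (default) the constructor enforces equal gadget
#'   lengths and pairwise distinctness. Balance and non-overlap are *not*
#'   enforced here (so that deliberately broken codes can be built for
#'   testing); use [verify_nonoverlap()] to check the overlap property.
#' @return An object of class `gadget_code` with fields `gadgets` (named
#'   character vector) and `gadget_length`.
#' @examples
#' code <- default_gadget_code()
#' gadget_encode("01", code)
#' @export
gadget_code <- function(gadgets, check = TRUE) {
  stopifnot(is.character(gadgets), length(gadgets) >= 1L,
            !is.null(names(gadgets)))
  if (check) {
    lens <- nchar(gadgets)
    if (length(unique(lens)) != 1L)
      stop_superwalk("all gadget strings must have equal length",
                     "superwalk_invalid_gadgets")
    if (anyDuplicated(gadgets))
      stop_superwalk("gadget strings must be pairwise distinct",
                     "superwalk_invalid_gadgets")
    if (any(nchar(names(gadgets)) != 1L))
      stop_superwalk("gadget names must be single characters",
                     "superwalk_invalid_gadgets")
  }
  structure(list(gadgets = gadgets, gadget_length = nchar(gadgets[[1L]])),
            class = "gadget_code")
}

#' @rdname gadget_code
#' @export
default_gadget_code <- function() {
  gadget_code(c("0" = "000111", "1" = "001011"))
}

#' @export
print.gadget_code <- function(x, ...) {
  cat("Gadget code (length ", x$gadget_length, "):\n", sep = "")
  for (ch in names(x$gadgets))
    cat("  '", ch, "' -> ", x$gadgets[[ch]], "\n", sep = "")
  invisible(x)
}

#' Encode a source string by gadget concatenation
#'
#' Replaces each character of `source` by its gadget and concatenates in
#' order. The result has length `gadget_length * nchar(source)`.
#'
#' @param source Source string; every character must have a gadget.
#' @param code A [gadget_code()]; defaults to the packaged pair.
#' @return The encoded binary string.
#' @examples
#' gadget_encode("0")   # "000111"
#' gadget_encode("01")  # "000111001011"
#' @export
gadget_encode <- function(source, code = default_gadget_code()) {
  cs <- chars(source)
  if (length(cs) == 0L) return("")
  unknown <- setdiff(cs, names(code$gadgets))
  if (length(unknown) > 0L)
    stop_superwalk(paste0("no gadget for character(s): ",
                          paste(unique(unknown), collapse = ", ")),
                   "superwalk_invalid_input")
  paste0(code$gadgets[cs], collapse = "")
}

#' Decode a gadget-encoded string
#'
#' Inverse of [gadget_encode()]: cuts `encoded` into consecutive blocks of
#' `gadget_length` characters and maps each block back to its source
#' character. Errors if the length is not a multiple of the gadget length or
#' if a block matches no gadget.
#'
#' @param encoded Encoded binary string.
#' @inheritParams gadget_encode
#' @return The unique source string whose encoding equals `encoded`.
#' @examples
#' gadget_decode("001011")  # "1"
#' @export
gadget_decode <- function(encoded, code = default_gadget_code()) {
  L <- code$gadget_length
  n <- nchar(encoded)
  if (n %% L != 0L)
    stop_superwalk("encoded length is not a multiple of the gadget length",
                   "superwalk_not_image")
  if (n == 0L) return("")
  starts <- seq(1L, n, by = L)
  blocks <- substring(encoded, starts, starts + L - 1L)
  lookup <- stats::setNames(names(code$gadgets), code$gadgets)
  src <- lookup[blocks]
  if (anyNA(src)) {
    bad <- blocks[is.na(src)][1L]
    stop_superwalk(paste0("block '", bad, "' matches no gadget: not the ",
                          "image of any source string"),
                   "superwalk_not_image")
  }
  paste0(src, collapse = "")
}

#' Per-character occurrence counts
#'
#' Counts occurrences of `"0"` and `"1"` (and any other characters present)
#' in a string. For any source string `s`, the encoding under the default
#' code satisfies `char_counts(gadget_encode(s))` = `3 * nchar(s)` for both
#' binary characters, because each gadget is balanced.
#'
#' @param s A string.
#' @param alphabet Characters that must appear in the result even at count
#'   zero.
#' @return Named integer vector of counts.
#' @examples
#' char_counts(gadget_encode("10"))  # c("0" = 6, "1" = 6)
#' @export
char_counts <- function(s, alphabet = c("0", "1")) {
  cs <- chars(s)
  counts <- stats::setNames(integer(length(alphabet)), alphabet)
  tab <- table(cs)
  extra <- setdiff(names(tab), alphabet)
  if (length(extra) > 0L)
    counts <- c(counts, stats::setNames(integer(length(extra)), extra))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Check the suffix/prefix non-overlap property of a gadget code
#'
#' Enumerates every ordered pair of gadgets (including each gadget with
#' itself) and every proper-suffix / proper-prefix length, and reports all
#' pairs where a proper suffix of one gadget equals a proper prefix of
#' another. The packaged default code has no such pair, which is the
#' alignment property all positional structure of encodings rests on.
#'
#' @inheritParams gadget_encode
#' @return A list with `ok` (logical) and `violations` (data frame with
#'   columns `from`, `to`, `overlap` listing each violating suffix/prefix
#'   string pair; zero rows when `ok`).
#' @examples
#' verify_nonoverlap()$ok  # TRUE
#' @export
verify_nonoverlap <- function(code = default_gadget_code()) {
  g <- code$gadgets
  viol <- list()
  for (a in seq_along(g)) {
    for (b in seq_along(g)) {
      la <- nchar(g[[a]]); lb <- nchar(g[[b]])
      for (len in seq_len(min(la, lb) - 1L)) {
        suf <- substr(g[[a]], la - len + 1L, la)
        pre <- substr(g[[b]], 1L, len)
        if (suf == pre)
          viol[[length(viol) + 1L]] <-
            data.frame(from = names(g)[a], to = names(g)[b],
                       overlap = suf, stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol) > 0L) do.call(rbind, viol) else
    data.frame(from = character(0), to = character(0),
               overlap = character(0), stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' All (possibly overlapping) occurrence positions of one string in another
#'
#' Positions are 1-based. Overlapping occurrences are all reported. The
#' empty pattern occurs at every position `1 .. nchar(outer) + 1`.
#'
#' @param inner Pattern string.
#' @param outer Text string.
#' @return Integer vector of 1-based start positions, ascending.
#' @examples
#' occurrence_positions(gadget_encode("0"), gadget_encode("100"))  # 7, 13
#' @export
occurrence_positions <- function(inner, outer) {
  m <- nchar(inner); n <- nchar(outer)
  if (m == 0L) return(seq_len(n + 1L))
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(outer, starts, starts + m - 1L) == inner]
}

#' Map an encoded occurrence position back to the source string
#'
#' An occurrence of an encoded string inside another encoded string always
#' starts at a position congruent to 1 modulo the gadget length; this maps
#' such a position `6k + 1` (for the default length 6) to the source
#' position `k + 1`.
#'
#' @param encoded_pos 1-based position in the encoded string; must be
#'   congruent to 1 modulo `gadget_length`.
#' @inheritParams gadget_encode
#' @return The corresponding 1-based position in the source string.
#' @examples
#' position_to_source(7)  # 2
#' @export
position_to_source <- function(encoded_pos, code = default_gadget_code()) {
  L <- code$gadget_length
  if (encoded_pos < 1L || (encoded_pos - 1L) %% L != 0L)
    stop_superwalk(paste0("position ", encoded_pos, " is not congruent to 1 ",
                          "modulo ", L),
                   "superwalk_not_aligned")
  (encoded_pos - 1L) %/% L + 1L
}
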