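# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Hamming distance between equal-length strings
#'
#' Position-wise mismatch count. `N` (or any non-matching character) counts
#' as a mismatch. Vectorized over `a` and `b` (recycled pairwise).
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming(): strings must have equal length")
  }
  mapply(function(x, y) {
    sum(charToRaw(x) != charToRaw(y))
  }, a, b, USE.NAMES = FALSE)
}

# Hamming distance from one string to each string in a character vector,
# all the same length. Byte-matrix implementation; fast enough for the
# library sizes this package handles.
hamming_to_all <- function(x, pool) {
  if (length(pool) == 0L) return(integer(0))
  xb <- charToRaw(x)
  vapply(pool, function(s) sum(charToRaw(s) != xb), integer(1),
         USE.NAMES = FALSE)
}

# Character matrix (n x width) from a vector of equal-width strings.
string_matrix <- function(x, width) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

# Collapse a character matrix back to strings, row-wise.
matrix_strings <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

# Random DNA strings, vectorized.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n * width, replace = TRUE),
              nrow = n, ncol = width)
  matrix_strings(m)
}

# Derive a reproducible child seed from a base seed and a stage label,
# staying below .Machine$integer.max.
derive_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(label), 8L)
  (as.integer(seed) + sum(h * seq_along(h))) %% 2147483L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
}
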