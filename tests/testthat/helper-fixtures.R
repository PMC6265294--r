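# Shared fixtures and independent oracles used across test files.

# Assemble a well-formed 40-mer read from two 18-mer halves.
make_read <- function(h1, h2, spacer = "TTCG") paste0(h1, spacer, h2)

# A HalfLibrary built directly from explicit sequences (bypasses the
# rejection sampler so degenerate libraries can be constructed).
manual_library <- function(seqs, min_dist = NA_integer_) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("bc%05d", seq_along(seqs))
  structure(list(sequences = seqs, length = nchar(seqs[[1]]),
                 min_pairwise_distance = min_dist),
            class = "HalfLibrary")
}

# Brute-force minimum pairwise Hamming distance over a sequence set.
oracle_min_pairwise <- function(seqs) {
  n <- length(seqs)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- min(best, hamming(seqs[i], seqs[j]))
    }
  }
  best
}

# Exhaustive-scan alignment oracle mirroring the end-anchored rule:
# distance 0, or distance exactly 1 with the mismatch at the first or
# last position; unique minimal-distance candidate wins.
oracle_align <- function(half, lib) {
  seqs <- lib$sequences
  L <- nchar(half)
  d <- vapply(seqs, function(s) hamming(half, s), integer(1))
  terminal <- vapply(seqs, function(s) {
    mm <- which(strsplit(half, "")[[1]] != strsplit(s, "")[[1]])
    length(mm) == 1 && (mm == 1 || mm == L)
  }, logical(1))
  cand <- which(d == 0 | (d == 1 & terminal))
  if (length(cand) == 0) return(list(id = NA_character_, status = "unmatched"))
  dmin <- min(d[cand])
  best <- cand[d[cand] == dmin]
  if (length(best) == 1) list(id = names(seqs)[best], status = "unique")
  else list(id = NA_character_, status = "ambiguous")
}

# Long-format variant table builder: maf_matrix has variants in rows and
# samples in columns; depth is the per-cell total coverage.
variant_table_from_maf <- function(maf_matrix, depth = 100,
                                   n_callers = 3, germline_vaf = 0,
                                   in_population_db = FALSE,
                                   is_silent = FALSE,
                                   region_class = "exonic",
                                   platform = "targeted") {
  vids <- rownames(maf_matrix)
  sids <- colnames(maf_matrix)
  alt <- round(maf_matrix * depth)
  data.frame(
    variant_id = rep(vids, times = length(sids)),
    sample_id = rep(sids, each = length(vids)),
    ref_reads = as.vector(depth - alt),
    alt_reads = as.vector(alt),
    n_callers = n_callers, germline_vaf = germline_vaf,
    in_population_db = in_population_db, is_silent = is_silent,
    region_class = region_class, platform = platform,
    stringsAsFactors = FALSE)
}
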