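# Barcode quantification: spacer filtering, read splitting, half-barcode
# alignment against the reference half-library, and paired counting with
# counts-per-million normalization.
#
# Read layout (1-based, inclusive): positions 1-18 = half-barcode 1,
# 19-22 = spacer "TTCG", 23-40 = half-barcode 2. Reads longer than 40 bp
# are truncated to their first 40 bases; shorter reads are rejected.

SPACER <- "TTCG"

#' Filter reads on the inter-barcode spacer
#'
#' A read is kept iff it is at least 40 bases long and the 4-mer at
#' positions 19-22 is within Hamming distance `max_mismatch` of `TTCG`.
#' `N` bases count as mismatches.
#'
#' @param reads Character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param max_mismatch Allowed spacer mismatches (default 1).
#' @return List with `kept` (character vector of surviving reads,
#'   truncated to 40 bases) and `log` (input / kept / dropped-by-reason
#'   counts).
#' @export
spacer_filter <- function(reads, max_mismatch = 1L) {
  reads <- as.character(reads)
  n <- length(reads)
  long_enough <- nchar(reads) >= 40L
  spacer_obs <- substr(reads[long_enough], 19L, 22L)
  d <- integer(length(spacer_obs))
  for (i in 1:4) {
    d <- d + (substr(spacer_obs, i, i) != substr(SPACER, i, i))
  }
  spacer_ok <- d <= max_mismatch
  kept <- substr(reads[long_enough][spacer_ok], 1L, 40L)
  list(kept = kept,
       log = list(input = n,
                  kept = length(kept),
                  dropped_short = n - sum(long_enough),
                  dropped_spacer = sum(!spacer_ok)))
}

#' Split spacer-passing reads into half-barcodes
#'
#' Half 1 is positions 1-18, half 2 positions 23-40 (1-based inclusive).
#' Reads shorter than 40 bases are rejected per read.
#'
#' @param reads Character vector of read sequences.
#' @return List with `half1`, `half2` (character vectors over kept reads)
#'   and `n_rejected`.
#' @export
split_reads <- function(reads) {
  reads <- as.character(reads)
  ok <- nchar(reads) >= 40L
  list(half1 = substr(reads[ok], 1L, 18L),
       half2 = substr(reads[ok], 23L, 40L),
       n_rejected = sum(!ok))
}

#' Align half-barcodes to the reference half-library
#'
#' A half maps to a library sequence at Hamming distance 0, or at
#' distance exactly 1 when the single mismatch sits at the first or last
#' base (end-anchored tolerance, the default); `mismatch_anywhere = TRUE`
#' relaxes the mismatch to any position. A half is assigned iff exactly
#' one library sequence attains the minimal distance; multiple candidates
#' give `"ambiguous"`, none give `"unmatched"`. `N` bases count as
#' mismatches.
#'
#' @param halves Character vector of half-barcode sequences, same length
#'   as the library sequences.
#' @param library A `HalfLibrary`.
#' @param mismatch_anywhere Allow the single mismatch at any position.
#' @return List with `id` (library id or `NA`) and `status`
#'   (`"unique"`, `"ambiguous"`, `"unmatched"`), both aligned to `halves`.
#' @export
align_half <- function(halves, library, mismatch_anywhere = FALSE) {
  stopifnot(inherits(library, "HalfLibrary"))
  halves <- as.character(halves)
  if (length(halves) && any(nchar(halves) != library$length)) {
    stop(sprintf("half-barcode length must equal library length (%d)",
                 library$length))
  }
  lib <- library$sequences
  ids <- names(lib)
  L <- library$length

  res_id <- rep(NA_character_, length(halves))
  status <- rep("unmatched", length(halves))

  # Work on unique sequences only; exact matches first.
  uh <- unique(halves)
  exact <- match(uh, lib)
  u_id <- ifelse(is.na(exact), NA_character_, ids[exact])
  u_status <- ifelse(is.na(exact), "unmatched", "unique")

  todo <- which(is.na(exact))
  if (length(todo)) {
    if (mismatch_anywhere) {
      for (j in todo) {
        dd <- hamming_to_all(uh[j], lib)
        cand <- which(dd == 1L)
        if (length(cand) == 1L) {
          u_id[j] <- ids[cand]
          u_status[j] <- "unique"
        } else if (length(cand) > 1L) {
          u_status[j] <- "ambiguous"
        }
      }
    } else {
      # Distance-1 candidates with the mismatch at a terminal position:
      # identical suffix (2..L) with a different first base, or identical
      # prefix (1..L-1) with a different last base.
      lib_suf <- substr(lib, 2L, L)
      lib_pre <- substr(lib, 1L, L - 1L)
      suf_map <- split(seq_along(lib), lib_suf)
      pre_map <- split(seq_along(lib), lib_pre)
      for (j in todo) {
        h <- uh[j]
        cand <- integer(0)
        s <- suf_map[[substr(h, 2L, L)]]
        if (!is.null(s)) {
          cand <- c(cand, s[substr(lib[s], 1L, 1L) != substr(h, 1L, 1L)])
        }
        p <- pre_map[[substr(h, 1L, L - 1L)]]
        if (!is.null(p)) {
          cand <- c(cand, p[substr(lib[p], L, L) != substr(h, L, L)])
        }
        cand <- unique(cand)
        if (length(cand) == 1L) {
          u_id[j] <- ids[cand]
          u_status[j] <- "unique"
        } else if (length(cand) > 1L) {
          u_status[j] <- "ambiguous"
        }
      }
    }
  }
  ix <- match(halves, uh)
  list(id = u_id[ix], status = u_status[ix])
}

#' Count paired barcodes per sample
#'
#' Runs the full quantification chain per sample — spacer filter, split,
#' half alignment — and counts reads whose two halves both align uniquely
#' to the half-library, preserving their pairing. CPM normalizes each
#' sample column to one million (`CPM_i = Counts_i / sum(Counts) * 1e6`).
#'
#' @param reads_by_sample Named list of per-sample read vectors
#'   (character or `DNAStringSet`).
#' @param library A `HalfLibrary`.
#' @param spacer_mismatch Allowed spacer mismatches (default 1).
#' @param mismatch_anywhere Passed to [align_half()].
#' @return An object of class `CountMatrix`: list with `barcodes`
#'   (data.frame `half1`, `half2`, `key`), `samples`, `counts`, `cpm`
#'   (barcode x sample matrices), and a per-sample filter `log`.
#' @export
count_pairs <- function(reads_by_sample, library, spacer_mismatch = 1L,
                        mismatch_anywhere = FALSE) {
  stopifnot(inherits(library, "HalfLibrary"))
  if (is.null(names(reads_by_sample))) {
    names(reads_by_sample) <- sprintf("S%02d",
                                      seq_along(reads_by_sample))
  }
  samples <- names(reads_by_sample)
  per_sample <- vector("list", length(samples))
  names(per_sample) <- samples
  logs <- list()

  for (s in samples) {
    sf <- spacer_filter(reads_by_sample[[s]],
                        max_mismatch = spacer_mismatch)
    sp <- split_reads(sf$kept)
    a1 <- align_half(sp$half1, library,
                     mismatch_anywhere = mismatch_anywhere)
    a2 <- align_half(sp$half2, library,
                     mismatch_anywhere = mismatch_anywhere)
    paired <- a1$status == "unique" & a2$status == "unique"
    key <- if (any(paired)) {
      paste0(a1$id[paired], ":", a2$id[paired])
    } else {
      character(0)     # paste0() would coerce zero-length args to ""
    }
    tab <- table(key)
    per_sample[[s]] <- tab
    logs[[s]] <- c(sf$log,
                   list(dropped_half_unaligned =
                          sum(a1$status == "unmatched" |
                              a2$status == "unmatched"),
                        dropped_half_ambiguous =
                          sum(paired == FALSE &
                              (a1$status == "ambiguous" |
                               a2$status == "ambiguous") &
                              a1$status != "unmatched" &
                              a2$status != "unmatched"),
                        counted = sum(paired),
                        zero_sample = sum(paired) == 0L))
  }

  keys <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, nrow = length(keys), ncol = length(samples),
                   dimnames = list(keys, samples))
  for (s in samples) {
    tab <- per_sample[[s]]
    counts[names(tab), s] <- as.integer(tab)
  }
  totals <- colSums(counts)
  cpm <- counts
  storage.mode(cpm) <- "double"
  pos <- totals > 0
  if (any(pos)) {
    cpm[, pos] <- sweep(counts[, pos, drop = FALSE], 2L, totals[pos],
                        "/") * 1e6
  }
  if (any(!pos)) {
    warning("sample(s) with zero surviving reads: ",
            paste(samples[!pos], collapse = ", "))
    cpm[, !pos] <- 0
  }
  halves <- if (length(keys)) {
    do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  } else {
    matrix(character(0), ncol = 2L)
  }
  structure(list(
    barcodes = data.frame(half1 = halves[, 1L], half2 = halves[, 2L],
                          key = keys, stringsAsFactors = FALSE),
    samples = samples, counts = counts, cpm = cpm, log = logs),
    class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d barcode pairs x %d samples (%s reads counted)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Quantify barcodes from FASTQ files
#'
#' Convenience wrapper: reads one FASTQ per sample listed in the sample
#' sheet and calls [count_pairs()].
#'
#' @param fastq_dir Directory holding `<sample_id>.fastq` files.
#' @param library A `HalfLibrary` or path to a half-library FASTA.
#' @param samples Sample sheet data.frame (`sample_id`, `mouse`, `site`,
#'   `lesion`) or path to a CSV with those columns.
#' @param ... Passed to [count_pairs()].
#' @return A `CountMatrix`.
#' @export
quantify_fastq <- function(fastq_dir, library, samples, ...) {
  if (is.character(library)) library <- read_half_library(library)
  if (is.character(samples)) {
    samples <- utils::read.csv(samples, stringsAsFactors = FALSE)
  }
  reads <- lapply(samples$sample_id, function(sid) {
    fp <- file.path(fastq_dir, paste0(sid, ".fastq"))
    if (!file.exists(fp)) stop("missing FASTQ for sample ", sid)
    as.character(Biostrings::readDNAStringSet(fp, format = "fastq"))
  })
  names(reads) <- samples$sample_id
  count_pairs(reads, library, ...)
}
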