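# Synthetic experiment generator: half-barcode libraries, clone
# populations, multi-organ seeding, reads, MAF tables, and MCMC
# assignment traces. Every downstream stage of the package can be
# exercised against the ground truth these functions record.

#' Generate a half-barcode reference library
#'
#' Builds a library of unique fixed-length nucleotide sequences whose
#' pairwise Hamming distance is at least `min_dist`, emulating the
#' half-barcode reference set of a high-complexity lentiviral barcode
#' library (the full clone label space is the Cartesian product of two
#' half-libraries).
#'
#' Sequences are drawn by rejection sampling; the attempt budget is capped
#' so infeasible requests fail loudly instead of looping forever.
#'
#' @param n Number of sequences (>= 1).
#' @param length Sequence length in bases (default 18).
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param max_attempts Rejection-sampling attempt cap per sequence.
#' @return An object of class `HalfLibrary`: list with `sequences` (named
#'   character vector, ids `bc0001`, ...), `length`, and
#'   `min_pairwise_distance`.
#' @examples
#' lib <- make_half_library(20, length = 18, min_dist = 3, seed = 1)
#' @export
make_half_library <- function(n, length = 18L, min_dist = 3L, seed = 1L,
                              max_attempts = 200L) {
  stopifnot_scalar_count(n, "n")
  stopifnot_scalar_count(length, "length")
  stopifnot_scalar_count(min_dist, "min_dist", min = 0L)
  if (min_dist > length) {
    stop(sprintf(
      "infeasible half library: min_dist (%d) exceeds length (%d)",
      min_dist, length))
  }
  set.seed(as.integer(seed))
  seqs <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- random_dna(1L, length)
      if (i == 1L ||
          all(hamming_to_all(cand, seqs[seq_len(i - 1L)]) >= min_dist)) {
        seqs[i] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        paste0("could not build half library (n=%d, length=%d, ",
               "min_dist=%d): attempt cap reached at sequence %d"),
        n, length, min_dist, i))
    }
  }
  names(seqs) <- sprintf("bc%05d", seq_len(n))
  structure(
    list(sequences = seqs, length = as.integer(length),
         min_pairwise_distance = as.integer(min_dist)),
    class = "HalfLibrary")
}

#' @export
print.HalfLibrary <- function(x, ...) {
  cat(sprintf("HalfLibrary: %d sequences of length %d, min distance %d\n",
              length(x$sequences), x$length, x$min_pairwise_distance))
  invisible(x)
}

#' Write / read a half library as FASTA
#'
#' @param library A `HalfLibrary`.
#' @param path Output FASTA path.
#' @return `write_half_library` returns `path` invisibly;
#'   `read_half_library` returns a `HalfLibrary` (with
#'   `min_pairwise_distance` recomputed only when `check = TRUE`).
#' @param check Recompute the minimum pairwise distance on read.
#' @export
write_half_library <- function(library, path) {
  x <- Biostrings::DNAStringSet(library$sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_half_library
#' @export
read_half_library <- function(path, check = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) stop("half library sequences differ in length")
  if (anyDuplicated(seqs)) stop("half library sequences are not unique")
  md <- NA_integer_
  if (check && length(seqs) > 1L) {
    md <- min(vapply(seq_len(length(seqs) - 1L), function(i) {
      min(hamming_to_all(seqs[i], seqs[(i + 1L):length(seqs)]))
    }, integer(1)))
  }
  structure(list(sequences = seqs, length = widths,
                 min_pairwise_distance = md),
            class = "HalfLibrary")
}

#' Default parameters for a simulated barcoding experiment
#'
#' The defaults describe the study conditions the generator emulates:
#' transduction at MOI 0.2 so most labeled cells carry a single integrant,
#' an engraftment (tumor-initiating) probability of 0.04, a
#' negative-binomial clone-size distribution in the primary (MFP) tumor,
#' polyclonal metastatic seeding of a few hundred clones per lesion, and a
#' handful of low-abundance clones per mouse that come to dominate every
#' lesion of that mouse.
#'
#' @param n_cells Cells exposed to the barcode library per mouse.
#' @param moi Multiplicity of infection; integrants per cell are
#'   Poisson(`moi`) and unlabeled cells (0 integrants) are discarded.
#' @param p_tic Per-clone engraftment (tumor-initiating cell) probability.
#' @param mice Named list: per mouse, a character vector of lesion sites
#'   drawn from `c("lung", "liver", "brain")`; every mouse also gets one
#'   MFP tumor sample.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion
#'   (`size`) of per-clone MFP abundance.
#' @param seeders_per_lesion Number of clones seeding each lesion.
#' @param n_dominant Dominant clones per mouse (shared across lesions).
#' @param dominance_factor Multiplicative abundance boost of dominant
#'   clones within lesions; must exceed 1.
#' @param seeding_alpha Seeding weight is MFP abundance ^ `seeding_alpha`.
#' @param reads_per_sample Sequencing reads emitted per sample.
#' @param error_rate Per-base substitution error rate of emitted reads.
#' @param junk_fraction Fraction of reads that are uniform random 40-mers.
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 1e6, moi = 0.2, p_tic = 0.04,
                       mice = list(A = c("lung", "lung", "liver"),
                                   B = c("lung", "lung", "liver", "brain")),
                       nb_mean = 50, nb_dispersion = 0.5,
                       seeders_per_lesion = 300, n_dominant = 5,
                       dominance_factor = 500, seeding_alpha = 1,
                       reads_per_sample = 1e6, error_rate = 0.001,
                       junk_fraction = 0.05) {
  p <- list(n_cells = n_cells, moi = moi, p_tic = p_tic, mice = mice,
            nb_mean = nb_mean, nb_dispersion = nb_dispersion,
            seeders_per_lesion = seeders_per_lesion,
            n_dominant = n_dominant, dominance_factor = dominance_factor,
            seeding_alpha = seeding_alpha,
            reads_per_sample = reads_per_sample, error_rate = error_rate,
            junk_fraction = junk_fraction)
  class(p) <- c("sim_params", "list")
  p
}

# Draw reads for one sample: multinomial over clone abundances, each read
# half1 + TTCG + half2 with iid substitution errors, plus junk 40-mers.
emit_sample_reads <- function(pair_seqs, abundance, n_reads, error_rate,
                              junk_fraction) {
  n_junk <- stats::rbinom(1L, n_reads, junk_fraction)
  n_real <- n_reads - n_junk
  counts <- if (n_real > 0L) {
    as.integer(stats::rmultinom(1L, n_real, prob = abundance))
  } else {
    integer(length(abundance))
  }
  reads <- rep(pair_seqs, counts)
  if (error_rate > 0 && length(reads) > 0L) {
    width <- nchar(reads[1L])
    n_err <- stats::rbinom(length(reads), width, error_rate)
    hit <- which(n_err > 0L)
    for (i in hit) {
      pos <- sample.int(width, n_err[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(DNA_ALPHABET, b), 1L)
      }, character(1))
      reads[i] <- paste0(ch, collapse = "")
    }
  }
  junk <- random_dna(n_junk, if (length(reads)) nchar(reads[1L]) else 40L)
  out <- c(reads, junk)
  list(reads = sample(out), true_counts = counts, n_junk = n_junk)
}

#' Simulate a barcoded multi-organ metastasis experiment
#'
#' Emulates the experimental design end to end for each mouse: Poisson
#' integrant labeling at the configured MOI, Bernoulli engraftment,
#' negative-binomial clone sizes in the MFP tumor, polyclonal lesion
#' seeding with weight proportional to MFP abundance (raised to
#' `seeding_alpha`), a per-mouse set of low-abundance dominant clones
#' boosted by `dominance_factor` in every lesion, and multinomial read
#' sampling with substitution errors and a junk-read fraction. Barcode
#' pairs are drawn uniformly from `library` squared (labeled cells carry
#' one pair each).
#'
#' @param params A [sim_params()] record.
#' @param library A `HalfLibrary` (used for both read halves).
#' @param seed Integer seed; the run is fully reproducible from
#'   `(params, seed)`.
#' @return A list of class `sim_experiment` with elements
#'   `truth` (per-mouse ground-truth ledger: clone pairs, engraftment,
#'   MFP abundance, per-lesion seeding and dominant sets, per-sample true
#'   read counts), `reads` (named list of per-sample read character
#'   vectors), `samples` (sample sheet data.frame with columns
#'   `sample_id`, `mouse`, `site`, `lesion`), and `params`.
#' @export
simulate_experiment <- function(params, library, seed = 1L) {
  stopifnot(inherits(params, "sim_params"), inherits(library, "HalfLibrary"))
  if (params$dominance_factor <= 1) {
    stop("dominance_factor must exceed 1 (cannot create dominance)")
  }
  set.seed(as.integer(seed))
  lib_ids <- names(library$sequences)
  spacer <- "TTCG"

  truth <- list()
  reads <- list()
  sheet <- list()

  for (mouse in names(params$mice)) {
    integrants <- stats::rpois(params$n_cells, params$moi)
    n_labeled <- sum(integrants > 0L)
    h1 <- sample(lib_ids, n_labeled, replace = TRUE)
    h2 <- sample(lib_ids, n_labeled, replace = TRUE)
    engrafted <- stats::rbinom(n_labeled, 1L, params$p_tic) == 1L
    n_eng <- sum(engrafted)
    if (n_eng == 0L) stop("no clone engrafted; increase n_cells or p_tic")
    eh1 <- h1[engrafted]
    eh2 <- h2[engrafted]
    clone_id <- paste0(eh1, ":", eh2)
    # Distinct cells may draw the same pair; collapse to clonal labels.
    keep <- !duplicated(clone_id)
    clone_id <- clone_id[keep]
    eh1 <- eh1[keep]
    eh2 <- eh2[keep]
    n_clones <- length(clone_id)
    mfp_abund <- stats::rnbinom(n_clones, size = params$nb_dispersion,
                                mu = params$nb_mean) + 1
    pair_seqs <- paste0(library$sequences[eh1], spacer,
                        library$sequences[eh2])

    sites <- params$mice[[mouse]]
    bad <- setdiff(sites, c("lung", "liver", "brain"))
    if (length(bad)) stop("unknown lesion site(s): ",
                          paste(bad, collapse = ", "))
    if (params$seeders_per_lesion > n_clones) {
      stop(sprintf(
        "seeders_per_lesion (%d) exceeds engrafted clone count (%d)",
        params$seeders_per_lesion, n_clones))
    }
    n_dom <- min(params$n_dominant, n_clones)
    # Dominant clones come from the low-abundance half of the MFP.
    low <- which(mfp_abund <= stats::median(mfp_abund))
    if (length(low) < n_dom) low <- seq_len(n_clones)
    dominant <- sample(low, n_dom)

    mfp_sample <- paste0(mouse, "_MFP")
    sheet[[length(sheet) + 1L]] <- data.frame(
      sample_id = mfp_sample, mouse = mouse, site = "MFP",
      lesion = "MFP", stringsAsFactors = FALSE)
    em <- emit_sample_reads(pair_seqs, mfp_abund,
                            params$reads_per_sample, params$error_rate,
                            params$junk_fraction)
    reads[[mfp_sample]] <- em$reads
    sample_counts <- list()
    sample_counts[[mfp_sample]] <- em$true_counts

    seeding_sets <- list()
    lesion_counter <- stats::setNames(integer(3),
                                      c("lung", "liver", "brain"))
    for (site in sites) {
      lesion_counter[site] <- lesion_counter[site] + 1L
      lesion <- paste0(site, lesion_counter[site])
      sid <- paste0(mouse, "_", lesion)
      w <- mfp_abund ^ params$seeding_alpha
      seeders <- sample(n_clones, params$seeders_per_lesion, prob = w)
      seeders <- union(seeders, dominant)
      lesion_abund <- numeric(n_clones)
      lesion_abund[seeders] <- mfp_abund[seeders]
      lesion_abund[dominant] <- lesion_abund[dominant] *
        params$dominance_factor
      em <- emit_sample_reads(pair_seqs, lesion_abund,
                              params$reads_per_sample, params$error_rate,
                              params$junk_fraction)
      reads[[sid]] <- em$reads
      sample_counts[[sid]] <- em$true_counts
      seeding_sets[[sid]] <- clone_id[sort(seeders)]
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample_id = sid, mouse = mouse, site = site, lesion = lesion,
        stringsAsFactors = FALSE)
    }

    truth[[mouse]] <- list(
      clones = data.frame(clone = clone_id, half1 = eh1, half2 = eh2,
                          mfp_abundance = mfp_abund,
                          dominant = seq_len(n_clones) %in% dominant,
                          stringsAsFactors = FALSE),
      n_labeled = n_labeled,
      n_engrafted = n_eng,
      dominant_set = clone_id[sort(dominant)],
      seeding_sets = seeding_sets,
      true_counts = sample_counts)
  }

  structure(list(truth = truth, reads = reads,
                 samples = do.call(rbind, sheet), params = params,
                 seed = as.integer(seed)),
            class = "sim_experiment")
}

#' Construct a subclone phantom for MAF simulation
#'
#' A phantom is a binary variant-by-subclone genotype matrix plus
#' per-sample subclone mixing proportions; it stands in for the subclonal
#' structure that drives reproducible MAF shifts between primary tumors
#' and metastases.
#'
#' @param genotype Binary matrix, variants in rows, subclones in columns.
#' @param mixing Matrix of subclone proportions, subclones in rows and
#'   samples in columns; each column must sum to 1.
#' @param depth Target read depth (scalar, or matrix matching
#'   variants x samples).
#' @return An object of class `SubclonePhantom`.
#' @export
subclone_phantom <- function(genotype, mixing, depth) {
  genotype <- as.matrix(genotype)
  mixing <- as.matrix(mixing)
  if (!all(genotype %in% c(0, 1))) stop("genotype must be binary")
  if (ncol(genotype) != nrow(mixing)) {
    stop("genotype columns must match mixing rows (subclones)")
  }
  if (any(mixing < 0) || any(mixing > 1) ||
      any(abs(colSums(mixing) - 1) > 1e-8)) {
    stop("mixing proportions must lie in [0,1] and sum to 1 per sample")
  }
  if (any(depth < 1)) stop("depth must be >= 1")
  if (is.null(rownames(genotype))) {
    rownames(genotype) <- sprintf("var%03d", seq_len(nrow(genotype)))
  }
  if (is.null(colnames(mixing))) {
    colnames(mixing) <- sprintf("S%02d", seq_len(ncol(mixing)))
  }
  structure(list(genotype = genotype, mixing = mixing, depth = depth),
            class = "SubclonePhantom")
}

#' Simulate a variant read-count table from a subclone phantom
#'
#' For variant v and sample s the expected mutant allele frequency is
#' `mu = sum_k genotype[v,k] * mixing[k,s] * 0.5` (heterozygous diploid
#' convention); alternate reads are Binomial(depth, mu) and reference
#' reads make up the remainder.
#'
#' @param phantom A [subclone_phantom()].
#' @param seed Integer seed.
#' @return A data.frame in long format with columns `variant_id`,
#'   `sample_id`, `ref_reads`, `alt_reads`, `maf`, plus the expected
#'   frequency `mu`.
#' @export
simulate_maf_table <- function(phantom, seed = 1L) {
  stopifnot(inherits(phantom, "SubclonePhantom"))
  set.seed(as.integer(seed))
  mu <- (phantom$genotype %*% phantom$mixing) * 0.5
  if (any(mu > 1 + 1e-12)) stop("expected MAF exceeds 1; invalid phantom")
  nv <- nrow(mu)
  ns <- ncol(mu)
  depth <- phantom$depth
  if (length(depth) == 1L) depth <- matrix(depth, nv, ns)
  alt <- matrix(stats::rbinom(nv * ns, as.integer(depth), as.vector(mu)),
                nv, ns)
  data.frame(
    variant_id = rep(rownames(mu), times = ns),
    sample_id = rep(colnames(mu), each = nv),
    ref_reads = as.vector(as.integer(depth) - alt),
    alt_reads = as.vector(alt),
    maf = as.vector(alt / as.integer(depth)),
    mu = as.vector(mu),
    stringsAsFactors = FALSE)
}

#' Simulate an MCMC cluster-assignment trace
#'
#' Each iteration copies the true assignment, then reassigns each variant
#' to a uniformly chosen *other* cluster with its flip probability.
#' `flip_rate` may be a single probability or a named vector with one
#' entry per true cluster, so stable and unstable clusters can coexist in
#' one trace.
#'
#' @param true_clusters Named vector mapping variant id to cluster label.
#' @param n_iters Number of iterations (>= 1).
#' @param flip_rate Flip probability in `[0, 1)`; scalar or named
#'   per-cluster vector.
#' @param seed Integer seed.
#' @return An object of class `AssignmentTrace`: list with `labels`
#'   (iterations x variants matrix), `variants`, `n_iters`, and
#'   `true_clusters`.
#' @export
simulate_assignment_trace <- function(true_clusters, n_iters,
                                      flip_rate = 0, seed = 1L) {
  stopifnot_scalar_count(n_iters, "n_iters")
  if (is.null(names(true_clusters))) {
    names(true_clusters) <- sprintf("var%03d", seq_along(true_clusters))
  }
  labels <- sort(unique(as.character(true_clusters)))
  k <- length(labels)
  if (any(flip_rate < 0) || any(flip_rate >= 1)) {
    stop("flip_rate must lie in [0, 1)")
  }
  if (k == 1L && any(flip_rate > 0)) {
    stop("cannot flip assignments with a single cluster")
  }
  per_variant <- if (length(flip_rate) == 1L) {
    rep(flip_rate, length(true_clusters))
  } else {
    if (is.null(names(flip_rate)) || !all(labels %in% names(flip_rate))) {
      stop("per-cluster flip_rate must be named by cluster label")
    }
    unname(flip_rate[as.character(true_clusters)])
  }
  set.seed(as.integer(seed))
  v <- length(true_clusters)
  true_idx <- match(as.character(true_clusters), labels)
  mat <- matrix(rep(true_idx, each = n_iters), nrow = n_iters)
  flip <- matrix(stats::runif(n_iters * v), nrow = n_iters) <
    matrix(rep(per_variant, each = n_iters), nrow = n_iters)
  if (any(flip)) {
    n_flip <- sum(flip)
    r <- sample.int(k - 1L, n_flip, replace = TRUE)
    old <- mat[flip]
    mat[flip] <- r + (r >= old)
  }
  lab_mat <- matrix(labels[mat], nrow = n_iters,
                    dimnames = list(NULL, names(true_clusters)))
  structure(list(labels = lab_mat, variants = names(true_clusters),
                 n_iters = as.integer(n_iters),
                 true_clusters = true_clusters),
            class = "AssignmentTrace")
}

#' Write simulated sample reads as FASTQ files
#'
#' One file per sample (`<sample_id>.fastq`) with a constant quality
#' string; quality is not used by the quantification logic.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths.
#' @export
write_sample_fastq <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in names(sim$reads)) {
    seqs <- sim$reads[[sid]]
    path <- file.path(dir, paste0(sid, ".fastq"))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("%s_read%06d", sid, seq_along(seqs))
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = qual)
    paths[sid] <- path
  }
  paths
}
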