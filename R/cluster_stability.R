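# Post-hoc robustness testing of mutation clusters from an MCMC
# clustering trace (e.g. a Dirichlet-process clustering of variants):
# pairwise co-assignment probabilities, category counts, and a
# chi-square test of deviation from the trace-wide baseline with
# Bonferroni correction over candidate clusters.

as_label_matrix <- function(trace) {
  if (inherits(trace, "AssignmentTrace")) return(trace$labels)
  if (is.matrix(trace)) return(trace)
  stop("trace must be an AssignmentTrace or an iterations x variants matrix")
}

#' Pairwise co-assignment probability matrix
#'
#' `P[i, j]` is the fraction of post-burn-in iterations in which variants
#' i and j carry the same cluster label; symmetric with unit diagonal.
#'
#' @param trace An `AssignmentTrace` (see
#'   [simulate_assignment_trace()]) or an iterations x variants label
#'   matrix with variant column names.
#' @param burn_in Iterations to discard from the front (default 0; must
#'   be smaller than the iteration count).
#' @return Variant x variant probability matrix.
#' @export
coassignment_matrix <- function(trace, burn_in = 0L) {
  labels <- as_label_matrix(trace)
  n_iter <- nrow(labels)
  if (burn_in >= n_iter) {
    stop(sprintf("burn_in (%d) must be smaller than the iteration count (%d)",
                 burn_in, n_iter))
  }
  post <- labels[(burn_in + 1L):n_iter, , drop = FALSE]
  cooc <- matrix(0, ncol(post), ncol(post),
                 dimnames = list(colnames(post), colnames(post)))
  for (k in unique(as.vector(post))) {
    ind <- post == k
    storage.mode(ind) <- "numeric"
    cooc <- cooc + crossprod(ind)
  }
  p <- cooc / nrow(post)
  diag(p) <- 1
  p
}

#' Discretize within-cluster co-assignment probabilities
#'
#' Counts unordered within-member pairs per category: `below`
#' (`p < 0.5`), `low` (`0.5 <= p < 0.9`), `high` (`0.9 <= p <= 1`). The
#' two upper bins are the published discretization; the `below` bin makes
#' the partition total so a goodness-of-fit test is well defined.
#'
#' @param P Co-assignment probability matrix.
#' @param members Variant ids (>= 2) forming the candidate cluster.
#' @return Named integer vector `c(below, low, high)`.
#' @export
categorize_pairs <- function(P, members) {
  if (length(members) < 2L) {
    stop("candidate cluster needs at least 2 members")
  }
  sub <- P[members, members, drop = FALSE]
  v <- sub[upper.tri(sub)]
  c(below = sum(v < 0.5),
    low = sum(v >= 0.5 & v < 0.9),
    high = sum(v >= 0.9))
}

#' Test robustness of candidate mutation clusters
#'
#' Candidate clusters are the modal (most frequent) post-burn-in
#' assignment of each variant, ties broken by the smallest label. For
#' each candidate cluster with at least two members, the within-cluster
#' pair category counts are compared to the expected counts under the
#' baseline category frequencies — estimated from all unordered variant
#' pairs in the trace (`baseline = "global"`, the default) or uniform
#' over categories (`baseline = "uniform"`) — with a chi-square
#' goodness-of-fit test. Categories with zero expected count are merged
#' (`below` into `low`) and logged. P-values are Bonferroni-corrected
#' over the number of tested clusters; a cluster is robust iff its
#' adjusted p is below `alpha`. Singleton clusters are untestable and
#' reported non-robust with reason `"too small"`.
#'
#' @param trace An `AssignmentTrace` or label matrix.
#' @param burn_in Burn-in iterations (default 2500, matching a
#'   10,000-iteration trace).
#' @param alpha Significance level after Bonferroni (default 0.05).
#' @param baseline `"global"` or `"uniform"`.
#' @return Object of class `StabilityReport`: list with `clusters`
#'   (data.frame: label, size, category counts, statistic, p, p_adj,
#'   robust, reason), `members` (list per cluster), `retained_variants`
#'   (variants of robust clusters), and `baseline_freq`.
#' @export
test_cluster_robustness <- function(trace, burn_in = 2500L, alpha = 0.05,
                                    baseline = c("global", "uniform")) {
  baseline <- match.arg(baseline)
  labels <- as_label_matrix(trace)
  if (burn_in >= nrow(labels)) {
    stop("burn_in must be smaller than the iteration count")
  }
  post <- labels[(burn_in + 1L):nrow(labels), , drop = FALSE]
  P <- coassignment_matrix(labels, burn_in = burn_in)
  variants <- colnames(labels) %||% as.character(seq_len(ncol(labels)))

  modal <- apply(post, 2L, function(col) {
    tab <- table(col)
    names(tab)[tab == max(tab)][1L]   # tie -> smallest label
  })
  members <- split(variants, modal)

  all_pairs <- P[upper.tri(P)]
  base_freq <- if (baseline == "global") {
    c(below = mean(all_pairs < 0.5),
      low = mean(all_pairs >= 0.5 & all_pairs < 0.9),
      high = mean(all_pairs >= 0.9))
  } else {
    c(below = 1 / 3, low = 1 / 3, high = 1 / 3)
  }

  rows <- list()
  for (lab in names(members)) {
    mem <- members[[lab]]
    if (length(mem) < 2L) {
      rows[[lab]] <- data.frame(
        label = lab, size = length(mem), below = NA_integer_,
        low = NA_integer_, high = NA_integer_, statistic = NA_real_,
        p = NA_real_, p_adj = NA_real_, robust = FALSE,
        reason = "too small", stringsAsFactors = FALSE)
      next
    }
    obs <- categorize_pairs(P, mem)
    expected <- base_freq * sum(obs)
    reason <- ""
    if (any(expected == 0)) {
      # Merge 'below' into 'low' so the partition has no empty
      # expectation.
      obs <- c(below_low = obs[["below"]] + obs[["low"]],
               high = obs[["high"]])
      expected <- c(below_low = (base_freq[["below"]] +
                                   base_freq[["low"]]) * sum(obs),
                    high = base_freq[["high"]] * sum(obs))
      reason <- "merged below+low (zero expectation)"
    }
    use <- expected > 0
    stat <- sum((obs[use] - expected[use])^2 / expected[use])
    df <- sum(use) - 1L
    p <- if (df < 1L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    cnt <- categorize_pairs(P, mem)
    rows[[lab]] <- data.frame(
      label = lab, size = length(mem), below = cnt[["below"]],
      low = cnt[["low"]], high = cnt[["high"]], statistic = stat,
      p = p, p_adj = NA_real_, robust = NA, reason = reason,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  testable <- !is.na(res$p)
  n_tests <- sum(testable)
  res$p_adj[testable] <- pmin(1, res$p[testable] * n_tests)
  res$robust[testable] <- res$p_adj[testable] < alpha
  res$robust[!testable] <- FALSE

  retained <- unlist(members[res$label[res$robust]], use.names = FALSE)
  structure(list(clusters = res, members = members,
                 retained_variants = retained, baseline_freq = base_freq,
                 burn_in = as.integer(burn_in), alpha = alpha),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf(
    "StabilityReport: %d/%d candidate clusters robust, %d variants retained\n",
    sum(x$clusters$robust), nrow(x$clusters),
    length(x$retained_variants)))
  print(x$clusters[, c("label", "size", "below", "low", "high", "p_adj",
                       "robust")])
  invisible(x)
}

#' Read / write an assignment trace as TSV
#'
#' Long format with columns `iteration`, `variant_id`, `cluster_label`.
#'
#' @param trace An `AssignmentTrace` or label matrix.
#' @param path TSV path.
#' @return `read_trace_tsv` returns an iterations x variants label
#'   matrix usable by [coassignment_matrix()].
#' @export
write_trace_tsv <- function(trace, path) {
  labels <- as_label_matrix(trace)
  long <- data.frame(
    iteration = rep(seq_len(nrow(labels)), times = ncol(labels)),
    variant_id = rep(colnames(labels), each = nrow(labels)),
    cluster_label = as.vector(labels), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  iters <- sort(unique(long$iteration))
  vars <- unique(long$variant_id)
  m <- matrix(NA_character_, length(iters), length(vars),
              dimnames = list(NULL, vars))
  m[cbind(match(long$iteration, iters),
          match(long$variant_id, vars))] <- as.character(long$cluster_label)
  if (anyNA(m)) stop("trace TSV does not label every variant at every iteration")
  m
}
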