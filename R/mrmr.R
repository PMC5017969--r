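# Minimum-Redundancy Maximum-Relevance feature ranking on discretized
# features.  Relevance D is the mean mutual information between selected
# features and the class; redundancy R the 1/|S|^2-normalized pairwise
# mutual information within the selected set; the greedy criterion at
# each step maximizes phi = D - R incrementally.

#' Discretize a continuous feature into three states
#'
#' z-threshold scheme: thresholds at mu - sigma and mu + sigma of the
#' vector give states 0 (low), 1 (mid), 2 (high).  A constant vector maps
#' to a single state.  The scheme is invariant to strictly increasing
#' affine rescaling because the thresholds move with mu and sigma.
#'
#' @param values numeric vector (length >= 2).
#' @return integer vector of states in {0, 1, 2}.
#' @export
discretize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  mu <- mean(values); s <- stats::sd(values)
  findInterval(values, c(mu - s, mu + s))
}

#' Mutual information between two discrete vectors (bits)
#'
#' Plug-in estimate over the observed joint cell counts.
#'
#' @param a,b equal-length vectors of discrete symbols.
#' @return non-negative mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 observations")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  idx <- which(joint > 0, arr.ind = TRUE)
  p <- joint[idx]
  max(0, sum(p * log2(p / (pa[idx[, 1]] * pb[idx[, 2]]))))
}

.entropy_discrete <- function(a) mutual_information(a, a)

#' Mean relevance of a feature set to the class
#'
#' `D = (1/|S|) * sum_i I(x_i; c)`.
#'
#' @param S integer vector of feature column indices.
#' @param c_labels discrete class labels.
#' @param Fdisc discretized feature matrix (samples x features).
#' @export
relevance <- function(S, c_labels, Fdisc) {
  if (length(S) == 0L) stop("empty feature set")
  mean(vapply(S, function(i) mutual_information(Fdisc[, i], c_labels),
              numeric(1)))
}

#' Normalized redundancy of a feature set
#'
#' `R = (1/|S|^2) * sum_{i,j} I(x_i; x_j)` including self-terms, so a
#' singleton set has `R = H(f)`.
#'
#' @param S integer vector of feature column indices.
#' @param Fdisc discretized feature matrix.
#' @export
redundancy <- function(S, Fdisc) {
  k <- length(S)
  if (k == 0L) stop("empty feature set")
  tot <- 0
  for (i in S) for (j in S)
    tot <- tot + mutual_information(Fdisc[, i], Fdisc[, j])
  tot / k^2
}

#' Greedy mRMR feature ranking
#'
#' First pick maximizes I(x; c); each subsequent pick maximizes the
#' incremental criterion `I(x; c) - (1/|S|) * sum_{j in S} I(x; x_j)`.
#' Ties break toward the lower feature index.  Per-step relevance D,
#' redundancy R and score phi = D - R of the growing set are recorded.
#'
#' @param F_table numeric feature matrix (samples x features), or an
#'   already-discretized integer matrix if `discretized = TRUE`.
#' @param c_labels class labels.
#' @param k number of features to select (default 12).
#' @param discretized set TRUE if `F_table` is already discrete.
#' @return A `selection_result`: list(ranked_indices, per_step, k, names).
#' @export
mrmr_rank <- function(F_table, c_labels, k = 12, discretized = FALSE) {
  F_table <- as.matrix(F_table)
  p <- ncol(F_table)
  n <- nrow(F_table)
  if (k > p) stop("k exceeds the number of features (", p, ")")
  if (n < 10L) stop("need at least 10 samples")
  if (length(c_labels) != n) stop("label length mismatch")
  Fd <- if (discretized) F_table else apply(F_table, 2, discretize)
  rel <- vapply(seq_len(p), function(i)
    mutual_information(Fd[, i], c_labels), numeric(1))
  mi_cache <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(mi_cache[i, j])) {
      v <- mutual_information(Fd[, i], Fd[, j])
      mi_cache[i, j] <<- v; mi_cache[j, i] <<- v
    }
    mi_cache[i, j]
  }
  selected <- integer(0)
  per_step <- data.frame(index = integer(k), relevance = numeric(k),
                         redundancy = numeric(k), score = numeric(k))
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- vapply(remaining, function(i) {
      if (length(selected) == 0L) rel[i]
      else rel[i] - mean(vapply(selected, function(j) pair_mi(i, j),
                                numeric(1)))
    }, numeric(1))
    best <- remaining[which.max(crit)]   # which.max takes first -> low index
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    D <- mean(rel[selected])
    R <- {
      tot <- 0
      for (i in selected) for (j in selected) tot <- tot + pair_mi(i, j)
      tot / length(selected)^2
    }
    per_step[step, ] <- list(best, D, R, D - R)
  }
  nm <- colnames(F_table)
  structure(list(ranked_indices = selected, per_step = per_step, k = k,
                 names = if (!is.null(nm)) nm[selected] else NULL),
            class = "selection_result")
}

#' Write a selection result as JSON
#' @param sel a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(list(ranked_indices = sel$ranked_indices,
                            names = sel$names, k = sel$k,
                            per_step = sel$per_step),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
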