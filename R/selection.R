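#' @name selection
#' @title Joint-mutual-information feature selection
#'
#' @description
#' Whole-sequence classification concatenates eleven feature tracks of 1796
#' values each; joint-mutual-information (JMI) selection keeps the five
#' tracks that jointly carry the most information about the VF condition,
#' shrinking the autoencoder input from 19,756 to 8,980 values. Mutual
#' information is estimated with the plugin (empirical-frequency) estimator
#' after equal-width discretization.
NULL

#' Discretize values into equal-width bins
#'
#' @param values finite numeric vector.
#' @param n_bins number of bins (>= 2).
#' @return integer codes in `0 .. n_bins - 1`; a constant input maps to
#'   code 0.
#' @export
discretize_equal_width <- function(values, n_bins = 8) {
  if (n_bins < 2) vf_input_error("n_bins must be >= 2")
  if (any(!is.finite(values))) vf_input_error("values must be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) return(integer(length(values)))
  codes <- floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins)
  as.integer(pmin(codes, n_bins - 1))
}

#' Plugin mutual information between a discrete feature and labels
#'
#' @param x_codes integer (or factor-like) vector of feature codes.
#' @param y label vector of the same length.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(x_codes, y) {
  if (length(x_codes) != length(y)) vf_input_error("length mismatch")
  if (length(y) < 1) vf_input_error("empty input")
  joint <- table(x_codes, y) / length(y)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Greedy joint-mutual-information feature selection
#'
#' First picks the single most informative feature `argmax I(X_j; Y)`; each
#' subsequent pick maximizes the summed joint criterion
#' `sum_{s in selected} I(X_j, X_s; Y)` over the remaining candidates
#' (the Yang-Moody form). Ties break toward the lower feature index.
#'
#' @param feature_matrix numeric matrix (n_samples x n_features).
#' @param labels label vector (length n_samples).
#' @param k number of features to select.
#' @param n_bins discretization bins (default 8).
#' @return a `vf_selection`: list with `selected_ids` (ordered), `scores`
#'   (criterion value at each pick, bits), `n_bins`, and `feature_names`
#'   when the matrix has column names.
#' @export
jmi_select <- function(feature_matrix, labels, k, n_bins = 8) {
  p <- ncol(feature_matrix)
  if (k > p) vf_config_error("k = %d exceeds the %d available features", k, p)
  if (nrow(feature_matrix) != length(labels)) vf_input_error("labels length mismatch")
  codes <- apply(feature_matrix, 2, discretize_equal_width, n_bins = n_bins)
  relevance <- vapply(seq_len(p), function(j) mutual_information(codes[, j], labels), 0)
  selected <- which.max(relevance)        # which.max takes the first (lowest) max
  scores <- relevance[selected]
  while (length(selected) < k) {
    cand <- setdiff(seq_len(p), selected)
    crit <- vapply(cand, function(j) {
      sum(vapply(selected, function(s) {
        joint_codes <- codes[, j] * n_bins + codes[, s]
        mutual_information(joint_codes, labels)
      }, 0))
    }, 0)
    pick <- cand[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
  }
  structure(list(selected_ids = selected, scores = scores, n_bins = n_bins,
                 feature_names = colnames(feature_matrix)[selected]),
            class = "vf_selection")
}
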