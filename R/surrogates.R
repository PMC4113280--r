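#' Surrogate target ensemble by repetition shuffling
#'
#' The null hypothesis of no information transfer is built by destroying
#' the source-target pairing while leaving everything else intact: the
#' repetition axis of the *target* channel is permuted, each repetition's
#' internal time order untouched. The permutation is a derangement (no
#' repetition stays in place) since a fixed repetition would leak the
#' original pairing into the null; for R = 2 the only derangement is the
#' swap.
#'
#' @param y numeric matrix `[repetition, sample]` (a target channel, see
#'   [channel_matrix()]).
#' @param seed optional integer seed for reproducibility.
#' @return Matrix with permuted repetition rows; the permutation used is
#'   attached as attribute `"perm"`.
#' @export
make_surrogate <- function(y, seed = NULL) {
  y <- as.matrix(y)
  R <- nrow(y)
  if (R < 2) stop("surrogate scheme undefined for a single repetition")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    perm <- sample.int(R)
    if (!any(perm == seq_len(R))) break
  }
  out <- y[perm, , drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' Permutation test of an observed TE value against surrogates
#'
#' The p-value is the literal proportion of surrogate TE values greater
#' than or equal to the observed one, `p = #\{te_surr >= te_orig\} / N'`.
#' With `conservative = TRUE` the positively biased variant
#' `(count + 1) / (N' + 1)` is used instead, which can never return 0.
#'
#' @param te_orig observed TE (nats).
#' @param te_surr numeric vector of surrogate TE values.
#' @param alpha significance level.
#' @param conservative use the `(c+1)/(N'+1)` p-value.
#' @return List with `p_value` and logical `significant`.
#' @export
permutation_test <- function(te_orig, te_surr, alpha = 0.05,
                             conservative = FALSE) {
  if (length(te_surr) == 0) stop("empty surrogate distribution")
  cnt <- sum(te_surr >= te_orig)
  p <- if (conservative) (cnt + 1) / (length(te_surr) + 1)
       else cnt / length(te_surr)
  list(p_value = p, significant = p < alpha)
}

#' Multiple-comparison correction across tests
#'
#' @param p_values numeric vector of per-comparison p-values.
#' @param method `"fdr_bh"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @param alpha level of the corrected procedure.
#' @return Logical vector of corrected significance flags (empty input
#'   yields empty output).
#' @export
correct_multiple <- function(p_values, method = c("fdr_bh", "bonferroni"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(logical(0))
  p.adjust(p_values, method = if (method == "fdr_bh") "BH" else "bonferroni") < alpha
}

#' Group-level link thresholding by a binomial test
#'
#' Across subjects, a link (channel pair) is called significant at the
#' group level when the number of subjects showing it exceeds what a
#' binomial null with per-subject probability `p0` explains: the link is
#' flagged when `P(X >= count | n_subjects, p0) < alpha`.
#'
#' @param link_presence logical matrix `[subjects, links]` of per-subject
#'   significance flags.
#' @param p0 per-subject null probability of a link, in (0, 1); a natural
#'   default is the per-subject corrected alpha level.
#' @param alpha group-level significance level.
#' @return Logical vector, one flag per link; the per-link tail
#'   probabilities are attached as attribute `"p_tail"`.
#' @export
group_binomial <- function(link_presence, p0, alpha = 0.05) {
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
  link_presence <- as.matrix(link_presence)
  if (nrow(link_presence) < 1) stop("need at least one subject")
  counts <- colSums(link_presence)
  p_tail <- pbinom(counts - 1, size = nrow(link_presence), prob = p0,
                   lower.tail = FALSE)
  out <- p_tail < alpha & counts > 0
  attr(out, "p_tail") <- p_tail
  out
}
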