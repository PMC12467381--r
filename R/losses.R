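#' Binary cross-entropy loss on logits
#'
#' Mean of `-[y log s(z) + (1 - y) log(1 - s(z))]` where `s` is the
#' sigmoid, computed in the numerically stable log-sum-exp form
#' `max(z, 0) - z y + log(1 + exp(-|z|))`, so saturated logits do not
#' overflow.
#'
#' @param logits numeric vector of raw model outputs.
#' @param labels binary vector (0/1) of the same length.
#' @return non-negative scalar.
#' @export
bce_sigmoid_loss <- function(logits, labels) {
  if (length(logits) == 0L) stop("empty batch: no logits")
  if (length(logits) != length(labels)) stop("logits and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

#' Triplet (contrastive) loss against a decoy set
#'
#' Mean over negatives of `max(0, d(a, p) - d(a, n) + margin)` with
#' Euclidean distance `d`: the anchor must sit closer to its positive
#' than to every decoy by at least the margin.
#'
#' @param anchor,positive numeric vectors (same dimension).
#' @param negatives list of numeric vectors, or a matrix with one decoy
#'   per row.
#' @param margin positive margin (default 1).
#' @return non-negative scalar (0 when the margin is satisfied
#'   everywhere).
#' @export
triplet_loss <- function(anchor, positive, negatives, margin = 1) {
  stopifnot(margin > 0)
  if (is.matrix(negatives)) {
    negatives <- lapply(seq_len(nrow(negatives)), function(i) negatives[i, ])
  }
  if (length(negatives) == 0L) stop("empty decoy set")
  d_ap <- sqrt(sum((anchor - positive)^2))
  terms <- vapply(negatives, function(n) {
    if (length(n) != length(anchor)) stop("decoy dimension mismatch")
    max(0, d_ap - sqrt(sum((anchor - n)^2)) + margin)
  }, numeric(1))
  mean(terms)
}
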