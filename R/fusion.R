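#' Fuse an ensemble of classifier outputs
#'
#' Implements the consensus-then-average integration rule for multi-model
#' land-cover classification. Where all models agree on a pixel's label,
#' that label is adopted directly (`method` = 1, consensus). Elsewhere the
#' per-model class-membership probability vectors are combined by a
#' weighted arithmetic mean — equal weights by default, otherwise
#' proportional to the supplied overall accuracies — and the fused label is
#' the argmax of the averaged posterior (`method` = 2). Exact ties are
#' broken deterministically towards the lowest class code and counted, so
#' arbitrary choices stay visible.
#'
#' @param outputs List of >= 2 co-registered [ClassifierOutput-class]
#'   objects sharing one class set.
#' @param weights Optional positive model weights (normalised internally).
#'   When omitted and every output carries an `accuracy`, accuracies are
#'   used; otherwise weights are equal.
#' @return A [FusionResult-class].
#' @examples
#' p1 <- array(c(0.5, 0.3, 0.2), c(1, 1, 3))
#' p2 <- array(c(0.2, 0.5, 0.3), c(1, 1, 3))
#' p3 <- array(c(0.3, 0.3, 0.4), c(1, 1, 3))
#' o <- lapply(list(p1, p2, p3), classifierOutput, classes = 1:3)
#' fuseClassifiers(o)@labels   # averaged posterior peaks on class 2
#' @export
fuseClassifiers <- function(outputs, weights = NULL) {
  if (length(outputs) < 2L)
    stop("at least 2 classifier outputs are required")
  ref <- outputs[[1L]]
  d <- dim(ref@probabilities)
  for (o in outputs) {
    if (!identical(dim(o@probabilities), d))
      stop("classifier outputs are not co-registered")
    if (!identical(o@classes, ref@classes))
      stop("classifier outputs use different legends")
  }
  nModels <- length(outputs)
  if (is.null(weights)) {
    accs <- vapply(outputs, function(o) o@accuracy, numeric(1L))
    weights <- if (!anyNA(accs)) accs else rep(1, nModels)
  }
  if (length(weights) != nModels || any(weights <= 0))
    stop("weights must be positive, one per model")
  weights <- weights / sum(weights)

  K <- d[3L]
  n <- d[1L] * d[2L]
  fused <- matrix(0, n, K)
  for (m in seq_len(nModels))
    fused <- fused + weights[m] * matrix(outputs[[m]]@probabilities, n, K)
  labelStack <- matrix(vapply(outputs, function(o) as.vector(o@labels),
                              integer(n)), nrow = n)
  consensus <- rowSums(labelStack == labelStack[, 1L]) == nModels

  # argmax over columns in ascending code order so that exact ties fall
  # to the lowest class code
  ord <- order(ref@classes)
  best <- ord[max.col(fused[, ord, drop = FALSE], ties.method = "first")]
  rowMax <- fused[cbind(seq_len(n), best)]
  nTied <- rowSums(fused == rowMax)
  ties <- sum(nTied > 1L & !consensus)

  labels <- ref@classes[best]
  labels[consensus] <- labelStack[consensus, 1L]
  method <- ifelse(consensus, 1L, 2L)
  new("FusionResult",
      labels = matrix(as.integer(labels), d[1L], d[2L]),
      probabilities = array(fused, d),
      method = matrix(as.integer(method), d[1L], d[2L]),
      classes = ref@classes, ties = as.integer(ties),
      weights = weights)
}
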