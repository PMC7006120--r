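#' Compare the top-N calls of two scored intron sets
#'
#' Given two methods' retained-intron sets, each with a ranking score (FPKM
#' for this tool, e.g. IRratio for an external caller), takes
#' \code{N = min(N1, N2)}, the smaller set size, and counts how many introns
#' the two top-N lists share (matched by intron identity).  Ties are broken
#' deterministically by (score descending, intron_id ascending).
#'
#' @param set_a,set_b Data.frames with columns \code{intron_id} and
#'   \code{score}.
#' @return A list with \code{n} (the common list length) and \code{shared}
#'   (size of the top-N intersection).
#' @export
top_n_compare <- function(set_a, set_b) {
  top <- function(s, n) {
    s <- s[order(-s$score, s$intron_id), , drop = FALSE]
    s$intron_id[seq_len(n)]
  }
  n <- min(nrow(set_a), nrow(set_b))
  list(n = n, shared = length(intersect(top(set_a, n), top(set_b, n))))
}

#' Precision and recall of a call set against a gold standard
#'
#' Precision is TP / (TP + FP), i.e. the fraction of calls that are in the
#' gold standard; recall is TP / |gold|.  With zero calls the precision is
#' undefined and returned as \code{NaN}.
#'
#' @param calls Character vector of called intron ids.
#' @param gold Non-empty character vector of gold-standard intron ids.
#' @return A list with \code{precision} and \code{recall}.
#' @export
precision_recall <- function(calls, gold) {
  if (length(gold) == 0L) stop("gold standard is empty")
  tp <- length(intersect(calls, gold))
  list(precision = if (length(calls)) tp / length(calls) else NaN,
       recall = tp / length(gold))
}

#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney rank statistic: the probability that a
#' random positive is scored above a random negative, with ties counted one
#' half.
#'
#' @param scores Numeric score vector (higher = more likely positive).
#' @param labels Logical (or 0/1) vector of true labels.
#' @return The AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    stop("roc_auc needs at least one positive and one negative label")
  }
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Integrate two retention scores on their common intron set
#'
#' Both raw score vectors (e.g. this tool's intron FPKM and an external
#' IRratio) are log2-transformed to tame their heavy tails, standardized to
#' zero mean and unit sample variance (\code{scale()} semantics, n-1
#' denominator), and averaged: \code{S = (S1 + S2) / 2}.  Only introns
#' scored by both methods are integrated; introns with a non-positive raw
#' score are excluded unless a positive \code{pseudocount} is supplied, in
#' which case it is added to both raw vectors before the log.
#'
#' @param raw1,raw2 Named numeric vectors of raw scores (names = intron
#'   ids).
#' @param pseudocount Offset added before the log2 transform.  Default 0
#'   (non-positive scores are dropped instead).
#' @return A data.frame with columns \code{intron_id}, \code{s1},
#'   \code{s2}, \code{s} where \code{s = (s1 + s2) / 2}.
#' @export
integrate_scores <- function(raw1, raw2, pseudocount = 0) {
  common <- intersect(names(raw1), names(raw2))
  x1 <- raw1[common] + pseudocount
  x2 <- raw2[common] + pseudocount
  ok <- x1 > 0 & x2 > 0
  if (!all(ok)) {
    warning(sum(!ok), " intron(s) with non-positive score excluded ",
            "from integration")
  }
  s1 <- as.numeric(scale(log2(x1[ok])))
  s2 <- as.numeric(scale(log2(x2[ok])))
  data.frame(intron_id = common[ok], s1 = s1, s2 = s2,
             s = (s1 + s2) / 2, stringsAsFactors = FALSE)
}

#' Performance improvement ratio of an integrated score
#'
#' \code{PIR = (AUC_integrated - AUC_mean) / AUC_mean}, where
#' \code{AUC_mean} is the mean AUC of the two component methods.  Negative
#' when integration hurts.
#'
#' @param auc_integrated AUC of the integrated score.
#' @param auc_method1,auc_method2 AUCs of the two component methods.
#' @return The PIR (dimensionless, may be negative).
#' @export
pir <- function(auc_integrated, auc_method1, auc_method2) {
  stopifnot(auc_integrated > 0, auc_integrated <= 1,
            auc_method1 > 0, auc_method1 <= 1,
            auc_method2 > 0, auc_method2 <= 1)
  auc_mean <- (auc_method1 + auc_method2) / 2
  (auc_integrated - auc_mean) / auc_mean
}

#' Gold standards restricted to the top-expressed positives
#'
#' Ranks the gold-standard positives by expression and builds, for each
#' requested fraction R, a gold standard keeping only the top
#' \code{ceiling(R * n)} positives (negatives are unchanged — they are
#' whatever is absent from the returned positive set).  \code{R = 1}
#' reproduces the input gold standard; smaller R values give nested
#' subsets.
#'
#' @param gold Character vector of gold-standard intron ids.
#' @param expression Named numeric vector of expression (FPKM) covering
#'   \code{gold}.
#' @param r Fractions to keep.  Default \code{c(0.2, 0.4, 0.6, 0.8, 1)}.
#' @return A named list (one element per R) of intron-id vectors.
#' @export
top_positive_subsets <- function(gold, expression,
                                 r = c(0.2, 0.4, 0.6, 0.8, 1)) {
  expr <- expression[gold]
  ord <- gold[order(-expr, gold)]
  out <- lapply(r, function(f) ord[seq_len(ceiling(f * length(ord)))])
  names(out) <- paste0("R", r * 100)
  out
}
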