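#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' `A = (#(pos > neg) + 0.5 * #(ties)) / (n_pos * n_neg)`, computed via
#' ranks. Equals the trapezoidal area under the empirical ROC curve.
#' Missing scores are dropped.
#'
#' @param scores_pos,scores_neg Scores of the positive (tumor) and
#'   negative (normal) samples.
#' @return The AUC in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(3, 2), c(1, 2.5))  # 0.75
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  if (!n_pos || !n_neg) stop("both score groups must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil standard error of an AUC
#'
#' The closed form
#' `se = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos * n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. Zero when
#' `A` is 0 or 1.
#'
#' @param auc AUC estimate(s) in \[0, 1\].
#' @param n_pos,n_neg Group sizes (>= 1).
#' @return Standard error(s), recycled over the inputs.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (any(auc < 0 | auc > 1)) stop("'auc' must lie in [0, 1]")
  if (any(n_pos < 1) || any(n_neg < 1)) stop("group sizes must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(pmax(v, 0))
}

#' One-sided significance of an AUC against 0.5
#'
#' `z = (A - 0.5) / se` with the Hanley-McNeil standard error evaluated
#' either at the observed AUC (`se_mode = "observed"`) or under the null
#' at `A = 0.5` (`se_mode = "null"`); the p-value is the upper normal tail
#' of `z`. `A = 0.5` gives `z = 0`, `p = 0.5`. A degenerate observed
#' standard error (`A` of exactly 0 or 1) yields `p = 0` and sets the
#' `degenerate` flag.
#'
#' @inheritParams hanley_mcneil_se
#' @param se_mode `"observed"` or `"null"`.
#' @return `data.frame` with columns `z`, `p`, `se`, `degenerate`.
#' @export
auc_p_value <- function(auc, n_pos, n_neg,
                        se_mode = c("observed", "null")) {
  se_mode <- match.arg(se_mode)
  se <- if (se_mode == "observed") hanley_mcneil_se(auc, n_pos, n_neg)
  else hanley_mcneil_se(rep(0.5, length(auc)), n_pos, n_neg)
  z <- ifelse(auc == 0.5, 0, (auc - 0.5) / se)
  degenerate <- se == 0 & auc != 0.5
  z[degenerate] <- sign(auc[degenerate] - 0.5) * Inf
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(z = z, p = p, se = se, degenerate = degenerate)
}

#' Evaluate miRNAs as tumor-versus-normal markers
#'
#' For each feature of an independent expression profile, computes the AUC
#' (positive class = tumor, scores used as-is), the Hanley-McNeil
#' standard error and the one-sided p-value against 0.5. Scores are not
#' reoriented automatically: a marker that falls in tumors yields an AUC
#' below 0.5, as in the original study's result table. Use `flip = TRUE`
#' to negate scores explicitly.
#'
#' @param es An [expression_set()].
#' @param features Feature ids to evaluate (default: all).
#' @param se_mode See [auc_p_value()].
#' @param flip Negate all scores before ranking.
#' @return `data.frame` with columns `feature_id`, `auc`, `se`, `z`, `p`,
#'   `n_pos`, `n_neg`.
#' @export
roc_markers <- function(es, features = NULL,
                        se_mode = c("observed", "null"), flip = FALSE) {
  se_mode <- match.arg(se_mode)
  if (is.null(features)) features <- rownames(es$values)
  missing_feat <- setdiff(features, rownames(es$values))
  if (length(missing_feat))
    stop("features absent from matrix: ",
         paste(missing_feat, collapse = ", "))
  cols <- intersect(colnames(es$values), names(es$labels))
  ind <- label_indicator(es$labels, cols)
  res <- lapply(features, function(f) {
    sc <- es$values[f, cols]
    if (flip) sc <- -sc
    pos <- sc[ind == 1]
    neg <- sc[ind == 0]
    a <- auc_mann_whitney(pos, neg)
    pv <- auc_p_value(a, sum(!is.na(pos)), sum(!is.na(neg)), se_mode)
    data.frame(feature_id = f, auc = a, se = pv$se, z = pv$z, p = pv$p,
               n_pos = sum(!is.na(pos)), n_neg = sum(!is.na(neg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
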