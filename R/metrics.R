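# Evaluation surface: confusion matrix, per-class sensitivity / positive
# predictive value / F1 with macro averages, and one-vs-rest ROC and
# precision-recall curves with AUC.

#' Confusion matrix of true versus predicted labels
#'
#' Rows are truth, columns predictions, in the order of `classes`.
#'
#' @param truth,pred Equal-length label vectors over `classes`.
#' @param classes Class set (default [ieeg_classes()]).
#' @return A `length(classes)` square count matrix.
#' @export
confusion_counts <- function(truth, pred, classes = ieeg_classes()) {
  check_that(length(truth) > 0, "`truth` must be non-empty")
  check_that(length(truth) == length(pred),
             "`truth` and `pred` must have equal length")
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  check_that(!anyNA(truth) && !anyNA(pred),
             "`truth`/`pred` contain labels outside the class set")
  tab <- table(truth = truth, pred = pred)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' Harmonic mean of precision and sensitivity
#'
#' @param ppv Positive predictive value (precision).
#' @param sen Sensitivity (recall).
#' @return `2 * ppv * sen / (ppv + sen)`; `NaN` when both are 0.
#' @export
f1_score <- function(ppv, sen) 2 * ppv * sen / (ppv + sen)

#' Per-class sensitivity, PPV and F1 from a confusion matrix
#'
#' For class c: `SEN = TP/(TP+FN)`, `PPV = TP/(TP+FP)`,
#' `F1 = 2*PPV*SEN/(PPV+SEN)`. Macro averages are unweighted means over
#' classes; zero-denominator metrics are reported as `NA` and excluded from
#' the macro average with a warning.
#'
#' @param conf Square count matrix (rows truth, columns predictions).
#' @return Object of class `metrics_report`: `confusion`, `per_class` (data
#'   frame with `sen`, `ppv`, `f1`), `macro` (list `sen`, `ppv`, `f1`), `n`.
#' @export
per_class_metrics <- function(conf) {
  conf <- as.matrix(conf)
  check_that(nrow(conf) == ncol(conf), "`conf` must be square")
  check_that(all(conf >= 0), "`conf` must hold non-negative counts")
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  sen <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  f1 <- ifelse(!is.na(sen) & !is.na(ppv) & (sen + ppv) > 0,
               f1_score(ppv, sen), NA_real_)
  if (anyNA(c(sen, ppv, f1)))
    warning("some metrics are undefined (zero denominator); ",
            "they are excluded from the macro averages", call. = FALSE)
  per_class <- data.frame(class = rownames(conf) %||% paste0("class", seq_along(tp)),
                          sen = sen, ppv = ppv, f1 = f1,
                          stringsAsFactors = FALSE)
  structure(list(confusion = conf, per_class = per_class,
                 macro = list(sen = mean(sen, na.rm = TRUE),
                              ppv = mean(ppv, na.rm = TRUE),
                              f1 = mean(f1, na.rm = TRUE)),
                 n = sum(conf)),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  print(round(cbind(x$per_class[, c("sen", "ppv", "f1")]), 4))
  cat(sprintf("macro: SEN %.4f  PPV %.4f  F1 %.4f\n",
              x$macro$sen, x$macro$ppv, x$macro$f1))
  invisible(x)
}

# Threshold sweep shared by both curves: descending unique scores, tied
# scores grouped at one threshold. Returns cumulative TP/FP per threshold.
sweep_thresholds <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  list(tp = tp, fp = fp, thresholds = s[last_of_group])
}

#' One-vs-rest receiver operating characteristic curve
#'
#' Thresholds sweep the unique scores (ties grouped); points are
#' `(FPR, TPR)`, starting at (0,0) and ending at (1,1); AUC by the trapezoid
#' rule, which equals the Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores Numeric class-membership scores (higher = more positive).
#' @param truth Logical (or 0/1) positive-class indicators; both classes must
#'   be present.
#' @return Object of class `eeg_curve` (`kind = "ROC"`): `points` data frame
#'   (`x` = FPR, `y` = TPR, `threshold`), `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  check_that(length(scores) == length(truth) && length(scores) > 0,
             "`scores` and `truth` must be equal-length and non-empty")
  P <- sum(truth); N <- sum(!truth)
  check_that(P > 0 && N > 0, "`truth` must contain both classes")
  sw <- sweep_thresholds(scores, truth)
  x <- c(0, sw$fp / N)
  y <- c(0, sw$tp / P)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(kind = "ROC",
                 points = data.frame(x = x, y = y,
                                     threshold = c(Inf, sw$thresholds)),
                 auc = auc),
            class = "eeg_curve")
}

#' One-vs-rest precision-recall curve
#'
#' Points are `(recall, precision)` over the swept thresholds, anchored at
#' recall 0 with the precision of the highest-score threshold. AUC uses the
#' step-wise (average precision) rule
#' `sum((R_i - R_{i-1}) * P_i)`, not trapezoids.
#'
#' @inheritParams roc_curve
#' @return Object of class `eeg_curve` (`kind = "PRC"`).
#' @export
prc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  check_that(length(scores) == length(truth) && length(scores) > 0,
             "`scores` and `truth` must be equal-length and non-empty")
  P <- sum(truth)
  check_that(P > 0, "`truth` must contain at least one positive")
  sw <- sweep_thresholds(scores, truth)
  rec <- sw$tp / P
  prec <- sw$tp / (sw$tp + sw$fp)
  auc <- sum(diff(c(0, rec)) * prec)
  structure(list(kind = "PRC",
                 points = data.frame(x = c(0, rec), y = c(prec[1], prec),
                                     threshold = c(Inf, sw$thresholds)),
                 auc = auc),
            class = "eeg_curve")
}

#' @export
print.eeg_curve <- function(x, ...) {
  cat(sprintf("<eeg_curve> %s, %d points, AUC = %.4f\n",
              x$kind, nrow(x$points), x$auc))
  invisible(x)
}

#' One-vs-rest ROC and PRC curves for every class
#'
#' @param probs `n x n_classes` matrix of class probabilities (columns named
#'   by class).
#' @param truth Length-n label vector.
#' @return Named list per class, each `list(roc =, prc =)`.
#' @export
class_curves <- function(probs, truth) {
  probs <- as.matrix(probs)
  cls <- colnames(probs) %||% ieeg_classes()[seq_len(ncol(probs))]
  truth <- as.character(truth)
  out <- lapply(seq_along(cls), function(j) {
    pos <- truth == cls[j]
    list(roc = roc_curve(probs[, j], pos), prc = prc_curve(probs[, j], pos))
  })
  stats::setNames(out, cls)
}

#' Plot ROC or PRC curves with the class-color convention
#'
#' Blue = physiological, red = pathological, green = artifact/noise.
#'
#' @param curves Result of [class_curves()].
#' @param kind `"roc"` or `"prc"`.
#' @param file Optional PNG path.
#' @return Invisibly, `file`.
#' @export
plot_class_curves <- function(curves, kind = c("roc", "prc"), file = NULL) {
  kind <- match.arg(kind)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  cols <- c(physiological = "blue", pathological = "red", artifact = "darkgreen")
  lab <- if (kind == "roc") c("false positive rate", "true positive rate")
         else c("recall", "precision")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = lab[1],
                 ylab = lab[2], main = toupper(kind))
  for (nm in names(curves)) {
    cv <- curves[[nm]][[kind]]
    graphics::lines(cv$points$x, cv$points$y,
                    col = cols[nm] %||% "black", lwd = 2,
                    type = if (kind == "prc") "s" else "l")
  }
  graphics::legend("bottomright" , bty = "n", lwd = 2, col = cols[names(curves)],
                   legend = sprintf("%s (AUC %.3f)", names(curves),
                                    vapply(curves, function(cv) cv[[kind]]$auc, 0)))
  invisible(file)
}
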