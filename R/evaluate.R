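# Accuracy of a segmentation against ground-truth labels.

#' Detection and overlap accuracy versus ground truth
#'
#' Greedily matches predicted to true labels by decreasing intersection-over-
#' union (one-to-one). A true nucleus counts as detected when its match
#' reaches `iou_threshold`. Precision is detected / predicted, recall is
#' detected / true, and `mean_iou` averages the IoU of the detected pairs.
#'
#' @param pred,truth integer 3D label arrays on the same grid.
#' @param iou_threshold minimum IoU for a detection (default 0.5).
#' @return list: precision, recall, mean_iou, n_pred, n_true, matches
#'   (data.frame pred, truth, iou).
#' @export
segmentation_accuracy <- function(pred, truth, iou_threshold = 0.5) {
  stopifnot(all(dim(pred) == dim(truth)))
  fp <- which(pred > 0L | truth > 0L)
  p <- pred[fp]
  t <- truth[fp]
  np <- tabulate(p[p > 0L])
  nt <- tabulate(t[t > 0L])
  both <- p > 0L & t > 0L
  ov <- if (any(both)) {
    tb <- as.data.frame(table(pred = p[both], truth = t[both]),
                        stringsAsFactors = FALSE)
    tb <- tb[tb$Freq > 0, ]
    data.frame(pred = as.integer(tb$pred), truth = as.integer(tb$truth),
               inter = as.integer(tb$Freq))
  } else data.frame(pred = integer(0), truth = integer(0), inter = integer(0))
  if (nrow(ov)) {
    ov$iou <- ov$inter / (np[ov$pred] + nt[ov$truth] - ov$inter)
    ov <- ov[order(-ov$iou), ]
  }
  used_p <- integer(0)
  used_t <- integer(0)
  matches <- ov[0, c("pred", "truth", "iou")]
  for (r in seq_len(nrow(ov))) {
    if (ov$pred[r] %in% used_p || ov$truth[r] %in% used_t) next
    if (ov$iou[r] < iou_threshold) break
    matches <- rbind(matches, ov[r, c("pred", "truth", "iou")])
    used_p <- c(used_p, ov$pred[r])
    used_t <- c(used_t, ov$truth[r])
  }
  n_pred <- sum(np > 0L)
  n_true <- sum(nt > 0L)
  list(precision = if (n_pred) nrow(matches) / n_pred else NA_real_,
       recall = if (n_true) nrow(matches) / n_true else NA_real_,
       mean_iou = if (nrow(matches)) mean(matches$iou) else NA_real_,
       n_pred = n_pred, n_true = n_true, matches = matches)
}
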