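# Independent AP reference: explicit greedy matcher plus a naive scan of the
# 101-point interpolated precision-recall curve. Same mathematical
# definition as the package implementation, entirely different code path.
ref_ap <- function(dets, gts, thr) {
  classes <- unique(gts$category)
  out <- numeric(0)
  for (cl in classes) {
    g <- gts[gts$category == cl, , drop = FALSE]
    d <- dets[dets$category == cl, , drop = FALSE]
    if (!nrow(d)) { out[cl] <- 0; next }
    d <- d[order(-d$score), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    tp <- integer(nrow(d)); fp <- integer(nrow(d))
    for (i in seq_len(nrow(d))) {
      best <- -1; bj <- 0
      for (j in seq_len(nrow(g))) {
        if (used[j] || g$image_id[j] != d$image_id[i]) next
        v <- iou(as.numeric(d[i, c("x", "y", "w", "h")]),
                 as.numeric(g[j, c("x", "y", "w", "h")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= thr) { tp[i] <- 1; used[bj] <- TRUE }
      else fp[i] <- 1
    }
    prec <- cumsum(tp) / (cumsum(tp) + cumsum(fp))
    rec <- cumsum(tp) / nrow(g)
    s <- 0
    for (r in 0:100 / 100) {
      pmax_ <- 0
      for (i in seq_along(rec))
        if (rec[i] >= r - 1e-12 && prec[i] > pmax_) pmax_ <- prec[i]
      s <- s + pmax_
    }
    out[cl] <- 100 * s / 101
  }
  mean(out)
}
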