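# shared fixture builders (all generated in code; no binary fixtures)

# vertical line object of `n` pixels with label `lab`
line_mask <- function(h, w, col, n, lab, top = 2L) {
  m <- matrix(0L, h, w)
  m[top:(top + n - 1L), col] <- lab
  m
}

# square donut: outer side `s`, hole side `hs`, centered
donut_mask <- function(h, w, s, hs, lab = 1L) {
  m <- matrix(0L, h, w)
  r0 <- (h - s) %/% 2 + 1L
  c0 <- (w - s) %/% 2 + 1L
  m[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- lab
  hr <- r0 + (s - hs) %/% 2
  hc <- c0 + (s - hs) %/% 2
  m[hr:(hr + hs - 1L), hc:(hc + hs - 1L)] <- 0L
  m
}

# random label raster for property-style tests
random_mask <- function(h = 30, w = 30, nlab = 4) {
  matrix(sample(0:nlab, h * w, replace = TRUE,
                prob = c(0.7, rep(0.3 / nlab, nlab))), h, w)
}

# overlap-based class agreement between a predicted mask and a ground-truth
# tile: each gt nucleus votes through the predicted label covering most of
# its pixels
class_agreement <- function(pred_mask, records, tile) {
  n <- max(tile$mask)
  agree <- 0L
  for (i in seq_len(n)) {
    px <- which(tile$mask == i)
    ov <- table(pred_mask[px])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) next
    j <- as.integer(names(ov)[which.max(ov)])
    cls <- as.character(records$class[records$id == j])
    if (length(cls) && cls == as.character(tile$classes[i]))
      agree <- agree + 1L
  }
  agree / n
}
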