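# independent fixed-point oracle: iterate the window's weighted centroid with
# a plainly-written loop until it stops moving
centroid_fixed_point <- function(pmap, w, iters = 200) {
  for (k in seq_len(iters)) {
    x0 <- max(0, round(w[1])); y0 <- max(0, round(w[2]))
    x1 <- min(ncol(pmap), round(w[1] + w[3])); y1 <- min(nrow(pmap), round(w[2] + w[4]))
    sub <- pmap[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    if (sum(sub) == 0) return(c(NA, NA))
    xs <- x0:(x1 - 1); ys <- y0:(y1 - 1)
    cx <- sum(colSums(sub) * xs) / sum(sub)
    cy <- sum(rowSums(sub) * ys) / sum(sub)
    nx <- min(max(cx - w[3] / 2 + 0.5, 0), ncol(pmap) - w[3])
    ny <- min(max(cy - w[4] / 2 + 0.5, 0), nrow(pmap) - w[4])
    if (abs(nx - w[1]) < 1e-9 && abs(ny - w[2]) < 1e-9) break
    w[1] <- nx; w[2] <- ny
  }
  c(cx, cy)
}
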