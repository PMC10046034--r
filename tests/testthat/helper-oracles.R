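# Naive breadth-first flood fill over 26-neighbours, threshold-strict: the
# slow reference implementation for region growing.
naive_flood_fill <- function(vol, seeds, threshold) {
  dims <- dim(vol)
  acc <- rep(FALSE, length(vol))
  queue <- seeds[vol[seeds] > threshold]
  acc[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    co <- arrayInd(cur, dims)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- co + c(dx, dy, dz)
      if (any(p < 1) || any(p > dims)) next
      j <- p[1] + dims[1] * (p[2] - 1) + dims[1] * dims[2] * (p[3] - 1)
      if (!acc[j] && vol[j] > threshold) {
        acc[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  array(acc, dims)
}
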