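# Independent brute-force oracles used to cross-check the implementation.

# flat-structuring-element grayscale morphology by explicit sliding window,
# clipped at the image border (same convention as the rolling-ball estimate)
bf_morph <- function(f, kern, fun) {
  r <- (nrow(kern) - 1) / 2
  H <- nrow(f); W <- ncol(f)
  out <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (kern[di + r + 1, dj + r + 1] > 0) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          vals <- c(vals, f[ii, jj])
      }
    }
    out[i, j] <- fun(vals)
  }
  out
}

bf_opening <- function(f, radius) {
  kern <- EBImage::makeBrush(2 * radius + 1, "disc")
  bf_morph(bf_morph(f, kern, min), kern, max)
}

# dense double-loop census: cells with zero counts on every set gene
bf_census <- function(dense, genes, gene_set) {
  rows <- match(gene_set, genes)
  rows <- rows[!is.na(rows)]
  n_zero <- 0L
  for (j in seq_len(ncol(dense))) {
    all0 <- TRUE
    for (r in rows) if (dense[r, j] > 0) { all0 <- FALSE; break }
    if (all0) n_zero <- n_zero + 1L
  }
  n_zero
}

# brute-force 8-connected labelling by repeated flood fill on a small mask
bf_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# tiny single-cell rendering shortcut used across image tests
tiny_config <- function(n_cells = 1, frac_capable = 1, seed = 1, ...) {
  spark_config(n_cells = n_cells, frac_capable = frac_capable,
               frac_pka_responsive = 1, hormone_panel = list(),
               frame_shape = c(128L, 128L), seed = seed, ...)
}

tiny_optics <- function(...) optics_config(frame_shape = c(128L, 128L), ...)
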