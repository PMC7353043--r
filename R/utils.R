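# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that simulation functions are
#' reproducible without clobbering the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up, unlike base round()'s round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# FNV-1a 32-bit hash of a character scalar; used to stamp stage outputs
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only, in double arithmetic (h can exceed 2^31)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply by 16777619 without overflow, via split words
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex digits from double arithmetic
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(x) {
  fnv1a32(paste(deparse(x, control = "all"), collapse = "\n"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)
is_frac <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1

#' Label 8-connected components of a sparse pixel set
#'
#' Union-find connected-component labelling on a set of foreground pixels
#' given as linear (column-major) indices into an `H x W` image. Two pixels
#' are connected when they are horizontal, vertical or diagonal neighbours.
#'
#' @param idx integer vector of linear pixel indices (1-based, column-major).
#' @param dim image dimensions `c(H, W)`.
#' @return Integer vector of component labels (1..K), parallel to `sort(idx)`;
#'   with attribute `"idx"` holding the sorted indices.
#' @keywords internal
#' @noRd
label_components8 <- function(idx, dim) {
  if (length(idx) == 0) {
    out <- integer(0)
    attr(out, "idx") <- integer(0)
    return(out)
  }
  H <- dim[1]
  ord <- sort(unique(as.integer(idx)))
  n <- length(ord)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row <- ((ord - 1L) %% H) + 1L
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
               c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (off in offs) {
    nb <- ord + off[1] + off[2] * H
    ok <- (row + off[1] >= 1L) & (row + off[1] <= H)
    j <- match(nb, ord)
    hit <- which(ok & !is.na(j))
    for (a in hit) {
      ra <- find(a); rb <- find(j[a])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  attr(labels, "idx") <- ord
  labels
}

# linear indices of pixels inside a disc, column-major into an H x W image
disc_pixels <- function(cx, cy, r, dim) {
  H <- dim[1]; W <- dim[2]
  xr <- max(1L, floor(cx - r)):min(H, ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(W, ceiling(cy + r))
  g <- expand.grid(x = xr, y = yr)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  as.integer(g$x[keep] + (g$y[keep] - 1L) * H)
}

# centered running mean (window w, odd); ends use truncated windows
running_mean <- function(x, w = 3) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# population standard deviation (divides by n, not n-1)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# longest run of TRUE and start index of the first run of length >= m
first_run_at_least <- function(flag, m) {
  if (!any(flag)) return(NA_integer_)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= m)
  if (length(ok) == 0) NA_integer_ else starts[ok[1]]
}
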