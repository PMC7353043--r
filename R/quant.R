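# Image-analysis core: rolling-ball background subtraction, segmentation,
# expression gating, droplet detection and the three droplet statistics.

#' Quantification parameters
#'
#' @param rolling_ball_radius flat-disc structuring-element radius (px) for
#'   background estimation. Must exceed the punctum footprint and stay below
#'   the cell radius, so that the opening reconstructs the cell body (which
#'   is then subtracted away) but not the puncta.
#' @param expression_threshold expression gate on the per-cell baseline
#'   brightness `B_c` (counts, fixed mode) or a percentile in (0, 100)
#'   (percentile mode). The fixed default of 140 counts corresponds, under
#'   the default optics (background 100, photon scale 1), to the expression
#'   level below which rendered droplets sink into the noise.
#' @param expression_mode `"fixed"` or `"percentile"`.
#' @param droplet_k robust-z cutoff: within a cell, droplet pixels are those
#'   whose background-subtracted intensity exceeds
#'   `median + droplet_k * MAD` of that cell's subtracted pixels.
#' @param min_droplet_area minimum 8-connected component area (px^2).
#' @param k_seg segmentation threshold: frame `median + k_seg * MAD`.
#' @param min_cell_area minimum connected-component area for a cell (px^2).
#' @param raw_droplet_k for the intensity-ratio statistic computed on raw
#'   frames: droplet pixels are those above `mean + raw_droplet_k * SD` of
#'   the cell's raw pixels.
#' @param edge_margin cell-boundary exclusion (px) for droplet detection:
#'   the rolling ball cannot perfectly reconstruct the jagged digital edge
#'   of a cell body, so a thin bright rim survives subtraction there;
#'   droplet pixels are only sought in the cell core, the mask eroded by
#'   this margin.
#' @param psf_sigma PSF sigma used only to validate the rolling-ball radius.
#' @return Object of class `quant_params`.
#' @export
quant_params <- function(rolling_ball_radius = 8, expression_threshold = 140,
                         expression_mode = c("fixed", "percentile"),
                         droplet_k = 6, min_droplet_area = 4,
                         k_seg = 5, min_cell_area = 200,
                         raw_droplet_k = 2, edge_margin = 2, psf_sigma = 1.5) {
  expression_mode <- match.arg(expression_mode)
  if (rolling_ball_radius < 2 * psf_sigma)
    stopf("rolling_ball_radius must be >= 2*psf_sigma = %g", 2 * psf_sigma)
  if (droplet_k <= 0) stopf("droplet_k must be > 0")
  if (expression_mode == "percentile" &&
      (expression_threshold <= 0 || expression_threshold >= 100))
    stopf("percentile expression_threshold must lie in (0, 100)")
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 expression_threshold = expression_threshold,
                 expression_mode = expression_mode,
                 droplet_k = droplet_k, min_droplet_area = min_droplet_area,
                 k_seg = k_seg, min_cell_area = min_cell_area,
                 raw_droplet_k = raw_droplet_k, edge_margin = edge_margin),
            class = "quant_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' frame with a flat disc structuring element of the given radius (the
#' classical rolling-ball estimate) and subtracts it. Structures narrower
#' than the disc — droplet puncta — survive the subtraction; wider smooth
#' structures (cell bodies, shading) are removed. The result is
#' non-negative everywhere because an opening never exceeds its input.
#'
#' @param frame numeric `H x W` matrix of intensities.
#' @param radius structuring-element radius in px (`>= 1`, at most
#'   `min(H, W) / 2`).
#' @return `H x W` matrix `frame - opening(frame)` with attributes
#'   `subtracted = TRUE` and `background` (the opening).
#' @export
#' @examples
#' f <- matrix(5, 32, 32); f[16, 16] <- 50
#' s <- rolling_ball_subtract(f, 6)
#' s[16, 16]
rolling_ball_subtract <- function(frame, radius) {
  if (!is.matrix(frame) || !is.numeric(frame)) stopf("frame must be a numeric matrix")
  if (radius < 1) stopf("radius must be >= 1")
  if (radius > min(dim(frame)) / 2)
    stopf("radius %g exceeds half the frame size", radius)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, "disc")
  # EBImage grayscale morphology clamps to [0, 1]; scale counts down and back
  scale <- max(2^16, max(frame), 1)
  bg <- EBImage::opening(frame / scale, kern) * scale
  out <- pmax(frame - bg, 0)
  attr(out, "subtracted") <- TRUE
  attr(out, "background") <- bg
  out
}

#' Segment cells on a baseline frame
#'
#' Global robust threshold (`median + k_seg * MAD` of the frame), hole
#' filling, connected components, and a minimum-area filter. The per-cell
#' baseline brightness `B_c` (the expression proxy used for gating) is the
#' mean raw intensity inside the label.
#'
#' @param baseline_frame the pre-stimulus frame, or a mean of baseline
#'   frames.
#' @param params a [quant_params()].
#' @return Object of class `cell_mask`: list with `labels` (`H x W` integer
#'   matrix, 0 = background) and `cells` (data frame: `label`, `area`,
#'   `cx`, `cy`, `b_mean`, `gated`). Labels are consecutive from 1.
#' @export
segment_cells <- function(baseline_frame, params = quant_params()) {
  f <- baseline_frame
  thr <- stats::median(f) + params$k_seg * stats::mad(f)
  bw <- EBImage::fillHull(f > thr)
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) stopf("no cells detected")
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_cell_area)
  if (length(keep) == 0) stopf("no cells detected")
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(f), ncol(f))
  nz <- lab > 0
  labels[nz] <- relab[lab[nz]]
  cells <- data.frame(label = seq_along(keep))
  idx_by <- split(which(labels > 0), labels[labels > 0])
  H <- nrow(f)
  cells$area <- vapply(idx_by, length, integer(1))
  cells$cx <- vapply(idx_by, function(i) mean(((i - 1) %% H) + 1), numeric(1))
  cells$cy <- vapply(idx_by, function(i) mean(((i - 1) %/% H) + 1), numeric(1))
  cells$b_mean <- vapply(idx_by, function(i) mean(f[i]), numeric(1))
  cells$gated <- NA
  # cell cores: mask eroded by edge_margin, where background subtraction is
  # free of cell-rim artefacts; used for droplet detection
  core_by <- idx_by
  if (params$edge_margin > 0) {
    er <- EBImage::erode(labels > 0,
                         EBImage::makeBrush(2 * params$edge_margin + 1,
                                            "disc"))
    core <- which(labels > 0 & er > 0)
    core_by <- split(core, labels[core])
    missing <- setdiff(names(idx_by), names(core_by))
    core_by[missing] <- idx_by[missing]
    core_by <- core_by[names(idx_by)]
  }
  structure(list(labels = labels, cells = cells, pixels = idx_by,
                 pixels_core = core_by),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  g <- x$cells$gated
  cat(sprintf("cell_mask: %d cells%s\n", nrow(x$cells),
              if (all(is.na(g))) " (not gated yet)"
              else sprintf(", %d gated", sum(g))))
  invisible(x)
}

#' Gate cells on biosensor expression
#'
#' Marks as gated the cells whose baseline brightness `B_c` exceeds the
#' threshold — only cells bright enough for droplet formation to be
#' detectable are analysed further. Gating is monotone: raising the
#' threshold never gains a gated cell.
#'
#' @param mask a [segment_cells()] result.
#' @param threshold gate value (counts) in fixed mode, percentile in
#'   percentile mode; defaults to the value in `params`.
#' @param params a [quant_params()] supplying mode (and default threshold).
#' @return The mask with `cells$gated` set.
#' @export
gate_expression <- function(mask, threshold = NULL, params = quant_params()) {
  stopifnot(inherits(mask, "cell_mask"))
  if (is.null(threshold)) threshold <- params$expression_threshold
  thr <- if (params$expression_mode == "percentile") {
    if (threshold <= 0 || threshold >= 100)
      stopf("percentile threshold must lie in (0, 100)")
    stats::quantile(mask$cells$b_mean, threshold / 100, names = FALSE)
  } else {
    if (threshold < 0) stopf("fixed threshold must be >= 0")
    threshold
  }
  mask$cells$gated <- mask$cells$b_mean > thr
  mask
}

#' Detect droplets within gated cells
#'
#' Operates on a background-subtracted frame. Within each gated cell,
#' droplet pixels are those whose intensity exceeds
#' `median + droplet_k * MAD`, where the median is taken over the cell's
#' pixels on the current subtracted frame (which keeps the cutoff invariant
#' to constant offsets) and the MAD is the cell's noise spread. By default
#' the MAD is computed on the same frame; when droplets cover an
#' appreciable part of the cell they contaminate that estimate, so
#' [build_traces()] estimates it once per cell on a droplet-free baseline
#' frame and passes it via `noise_mad`. 8-connected components with at
#' least `min_droplet_area` pixels become droplets.
#'
#' @param sub_frame a frame produced by [rolling_ball_subtract()] (detection
#'   on an unsubtracted frame is an error).
#' @param mask a gated [segment_cells()] result.
#' @param params a [quant_params()].
#' @param noise_mad optional named numeric vector (names = cell labels) of
#'   per-cell noise MADs estimated on a droplet-free subtracted frame.
#' @return Object of class `droplet_set`: data frame with one row per
#'   droplet (`label` of the owning cell, `droplet_id`, `area`,
#'   `intensity`), plus attribute `pixels` (list of linear-index vectors,
#'   one per droplet) and `subtracted = TRUE`.
#' @export
detect_droplets <- function(sub_frame, mask, params = quant_params(),
                            noise_mad = NULL) {
  if (!isTRUE(attr(sub_frame, "subtracted")))
    stopf("detect_droplets requires a background-subtracted frame (see rolling_ball_subtract)")
  stopifnot(inherits(mask, "cell_mask"))
  if (all(is.na(mask$cells$gated)))
    stopf("mask is not gated yet (see gate_expression)")
  dim_f <- dim(sub_frame)
  lab_v <- integer(0); area_v <- integer(0); int_v <- numeric(0)
  pix <- list()
  px_src <- if (!is.null(mask$pixels_core)) mask$pixels_core else mask$pixels
  for (ci in which(mask$cells$gated)) {
    lab <- mask$cells$label[ci]
    idx <- px_src[[as.character(lab)]]
    v <- sub_frame[idx]
    m_noise <- if (!is.null(noise_mad)) noise_mad[[as.character(lab)]]
    else stats::mad(v)
    cut <- stats::median(v) + params$droplet_k * m_noise
    hot <- idx[v > cut]
    if (length(hot) < params$min_droplet_area) next
    comp <- label_components8(hot, dim_f)
    cidx <- attr(comp, "idx")
    sizes <- tabulate(comp)
    for (k in which(sizes >= params$min_droplet_area)) {
      cpx <- cidx[comp == k]
      lab_v <- c(lab_v, lab)
      area_v <- c(area_v, length(cpx))
      int_v <- c(int_v, sum(sub_frame[cpx]))
      pix[[length(pix) + 1]] <- cpx
    }
  }
  out <- data.frame(label = lab_v,
                    droplet_id = seq_along(lab_v),
                    area = area_v, intensity = int_v)
  structure(out, pixels = pix, subtracted = TRUE,
            class = c("droplet_set", "data.frame"))
}

#' Droplet statistic 1: droplet/cell intensity ratio
#'
#' Sum of droplet-pixel intensities divided by the sum of all cell-pixel
#' intensities, on the raw (unsubtracted) frame. With `droplet_pixels =
#' NULL` the droplet pixels are defined on the raw frame itself as those
#' above `mean + raw_droplet_k * SD` of the cell's pixels — the simple
#' thresholding originally used with this biosensor, which gives the
#' statistic its nonzero resting baseline.
#'
#' @param frame raw frame.
#' @param cell_pixels linear indices of the cell's pixels.
#' @param droplet_pixels linear indices of droplet pixels, or `NULL`.
#' @param raw_droplet_k cutoff multiplier used when `droplet_pixels` is
#'   `NULL`.
#' @return Ratio in `[0, 1]`; 0 when there are no droplet pixels.
#' @export
spark_stat_intensity_ratio <- function(frame, cell_pixels,
                                       droplet_pixels = NULL,
                                       raw_droplet_k = 2) {
  v <- frame[cell_pixels]
  tot <- sum(v)
  if (tot <= 0) stopf("cell has zero total intensity")
  if (is.null(droplet_pixels)) {
    cut <- mean(v) + raw_droplet_k * pop_sd(v)
    return(sum(v[v > cut]) / tot)
  }
  if (length(droplet_pixels) == 0) return(0)
  if (!all(droplet_pixels %in% cell_pixels))
    stopf("droplet pixels must lie inside the cell")
  sum(frame[droplet_pixels]) / tot
}

#' Droplet statistic 2: within-cell intensity SD
#'
#' Population standard deviation of the raw intensities inside the cell
#' mask. Droplet formation concentrates intensity into puncta and inflates
#' the SD.
#'
#' @inheritParams spark_stat_intensity_ratio
#' @return SD in counts.
#' @export
spark_stat_sd <- function(frame, cell_pixels) {
  if (length(cell_pixels) == 0) stopf("empty cell mask")
  pop_sd(frame[cell_pixels])
}

#' Droplet statistic 3: total droplet area
#'
#' Sum of the areas of a cell's droplets on the background-subtracted frame;
#' 0 when the cell has none. Components never overlap, so this equals the
#' pixel count of their union.
#'
#' @param droplets a [detect_droplets()] result.
#' @param label cell label to total.
#' @return Area in px^2.
#' @export
spark_stat_area <- function(droplets, label) {
  stopifnot(inherits(droplets, "droplet_set"))
  sum(droplets$area[droplets$label == label])
}

#' Build per-cell statistic traces from a stack
#'
#' Segments cells on the mean pre-stimulus frame (unless a mask is given),
#' gates them on expression, then evaluates the chosen droplet statistic for
#' every gated cell on every frame. The raw frames feed the intensity-ratio
#' and SD statistics; rolling-ball-subtracted frames feed droplet detection
#' and the area statistic.
#'
#' @param stack an [render_stack()] / [read_stack()] stack.
#' @param params a [quant_params()].
#' @param statistic `"area"`, `"intensity_ratio"` or `"sd"`.
#' @param mask optional pre-computed gated [segment_cells()] mask.
#' @param keep_droplets if `TRUE`, attach the per-frame droplet tables
#'   (area statistic only).
#' @return Object of class `spark_traces`: list with `values` (gated-cells x
#'   frames matrix, rownames = cell labels), `timestamps`, `statistic`,
#'   `protocol`, `mask`, and optionally `droplets` (data frame with `frame`
#'   column).
#' @export
build_traces <- function(stack, params = quant_params(),
                         statistic = c("area", "intensity_ratio", "sd"),
                         mask = NULL, keep_droplets = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(mask)) {
    base_idx <- which(stack$timestamps < attr(stack$protocol, "baseline"))
    if (length(base_idx) == 0) base_idx <- 1L
    bf <- Reduce(`+`, stack$frames[base_idx]) / length(base_idx)
    mask <- segment_cells(bf, params)
    mask <- gate_expression(mask, params = params)
  }
  if (all(is.na(mask$cells$gated))) mask <- gate_expression(mask, params = params)
  gated <- mask$cells$label[mask$cells$gated]
  if (length(gated) == 0) stopf("no gated cells")
  Tn <- length(stack$frames)
  vals <- matrix(0, length(gated), Tn,
                 dimnames = list(as.character(gated), NULL))
  drop_tabs <- if (keep_droplets) vector("list", Tn) else NULL
  noise_mad <- NULL
  if (statistic == "area") {
    # per-cell noise spread from the first (droplet-free, pre-stimulus)
    # frame, so the droplet cutoff is not contaminated by droplets later on
    sub0 <- rolling_ball_subtract(stack$frames[[1]],
                                  params$rolling_ball_radius)
    px0 <- if (!is.null(mask$pixels_core)) mask$pixels_core else mask$pixels
    noise_mad <- vapply(as.character(gated), function(l)
      stats::mad(sub0[px0[[l]]]), numeric(1))
  }
  for (f in seq_len(Tn)) {
    fr <- stack$frames[[f]]
    if (statistic == "area") {
      sub <- rolling_ball_subtract(fr, params$rolling_ball_radius)
      dd <- detect_droplets(sub, mask, params, noise_mad = noise_mad)
      if (nrow(dd)) {
        tot <- rowsum(dd$area, dd$label)
        hit <- as.character(as.integer(rownames(tot)))
        vals[hit[hit %in% rownames(vals)], f] <-
          tot[hit %in% rownames(vals), 1]
      }
      if (keep_droplets)
        drop_tabs[[f]] <- if (nrow(dd)) cbind(frame = f, as.data.frame(dd))
    } else {
      for (g in seq_along(gated)) {
        idx <- mask$pixels[[as.character(gated[g])]]
        vals[g, f] <- if (statistic == "sd") spark_stat_sd(fr, idx)
        else spark_stat_intensity_ratio(fr, idx,
                                        raw_droplet_k = params$raw_droplet_k)
      }
    }
  }
  structure(list(values = vals, timestamps = stack$timestamps,
                 statistic = statistic, protocol = stack$protocol,
                 mask = mask,
                 droplets = if (keep_droplets)
                   do.call(rbind, drop_tabs[!vapply(drop_tabs, is.null,
                                                    logical(1))])),
            class = "spark_traces")
}

#' @export
print.spark_traces <- function(x, ...) {
  cat(sprintf("spark_traces: statistic '%s', %d gated cells x %d frames\n",
              x$statistic, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
plot.spark_traces <- function(x, cells = NULL, ...) {
  v <- x$values
  if (!is.null(cells)) v <- v[as.character(cells), , drop = FALSE]
  graphics::matplot(x$timestamps, t(v), type = "l", lty = 1,
                    xlab = "time (min)", ylab = x$statistic, ...)
  stim <- x$protocol$time[x$protocol$kind != "wash"]
  graphics::abline(v = stim, col = "grey40", lty = 2)
  invisible(x)
}

#' Normalize a statistic trace
#'
#' `to_max` divides by the trace maximum (values in `[0, 1]`); `to_t0`
#' divides by the first time point plus `eps`, giving a fold-change whose
#' maximum is the trace's contrast. A zero starting level with `eps = 0` is
#' an error — which is exactly why a floor is needed before fold-change
#' comparisons of the (zero-baseline) area statistic.
#'
#' @param x numeric trace vector.
#' @param mode `"to_max"` or `"to_t0"`.
#' @param eps baseline floor added to the `to_t0` denominator.
#' @return Normalized numeric vector.
#' @export
#' @examples
#' normalize_trace(c(2, 4, 8), "to_t0")
normalize_trace <- function(x, mode = c("to_max", "to_t0"), eps = 0) {
  mode <- match.arg(mode)
  if (mode == "to_max") {
    m <- max(x)
    if (m <= 0) stopf("to_max normalization needs a positive maximum")
    return(x / m)
  }
  d <- x[1] + eps
  if (d <= 0) stopf("to_t0 normalization needs a positive starting level (consider eps)")
  x / d
}

#' Contrast of a trace (max fold-change over its starting level)
#'
#' @inheritParams normalize_trace
#' @return `max(x) / (x[1] + eps)`.
#' @export
trace_contrast <- function(x, eps = 0) {
  max(normalize_trace(x, "to_t0", eps = eps))
}

#' Match segmented cells to roster ground truth
#'
#' Nearest-centroid assignment used to compare pipeline output with the
#' simulated truth in tests and diagnostics.
#'
#' @param mask a [segment_cells()] result.
#' @param roster the generating [simulate_roster()] roster.
#' @param max_dist maximum centre distance (px) for a match.
#' @return Integer vector: for each mask label the matched roster
#'   `cell_id` (or `NA`).
#' @export
match_cells <- function(mask, roster, max_dist = 10) {
  vapply(seq_len(nrow(mask$cells)), function(i) {
    d2 <- (roster$x - mask$cells$cx[i])^2 + (roster$y - mask$cells$cy[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist) roster$cell_id[j] else NA_integer_
  }, integer(1))
}
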