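# Rendering the latent population state into 16-bit time-lapse stacks.

#' Optics and rendering configuration
#'
#' @param frame_shape `c(H, W)` in pixels, or `NULL` to inherit the roster's.
#' @param psf_sigma Gaussian point-spread sigma (px).
#' @param background_level camera background (counts).
#' @param read_noise_sd Gaussian read noise SD per pixel (counts).
#' @param photon_scale counts per biosensor expression unit (cell body
#'   brightness is `expression * photon_scale` above background).
#' @param droplet_unit_area nominal droplet area (px^2): each rendered
#'   punctum is a flat disc of this area convolved with the PSF.
#' @param droplet_intensity_gain punctum peak brightness per expression unit
#'   — droplet brightness scales with the cell's biosensor level, which is
#'   what makes dim cells' droplets indistinguishable from noise.
#' @param droplet_mass_per_punctum droplet-mass units per rendered punctum;
#'   per frame each cell shows `N ~ Poisson(mass / this)` puncta.
#' @param frame_interval acquisition interval (min).
#' @param bit_depth sensor bit depth (rendered counts are clipped to
#'   `[0, 2^bit_depth - 1]`).
#' @param seed integer seed for punctum placement and noise.
#' @return Object of class `optics_config`.
#' @export
optics_config <- function(frame_shape = NULL, psf_sigma = 1.5,
                          background_level = 100, read_noise_sd = 3,
                          photon_scale = 1, droplet_unit_area = 6,
                          droplet_intensity_gain = 1,
                          droplet_mass_per_punctum = 1,
                          frame_interval = 1, bit_depth = 16L, seed = 1L) {
  vals <- c(psf_sigma = psf_sigma, background_level = background_level,
            photon_scale = photon_scale, droplet_unit_area = droplet_unit_area,
            droplet_intensity_gain = droplet_intensity_gain,
            droplet_mass_per_punctum = droplet_mass_per_punctum,
            frame_interval = frame_interval)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all optics parameters must be finite and positive")
  if (read_noise_sd < 0) stopf("read_noise_sd must be >= 0")
  structure(list(frame_shape = if (is.null(frame_shape)) NULL
                 else as.integer(frame_shape),
                 psf_sigma = psf_sigma, background_level = background_level,
                 read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 droplet_unit_area = droplet_unit_area,
                 droplet_intensity_gain = droplet_intensity_gain,
                 droplet_mass_per_punctum = droplet_mass_per_punctum,
                 frame_interval = frame_interval,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "optics_config")
}

# punctum kernel: flat disc of area `unit_area` convolved with a Gaussian
# PSF, peak-normalised to 1; computed on a (2*hw+1)^2 pixel grid with 4x
# supersampling
punctum_kernel <- function(psf_sigma, unit_area) {
  rd <- sqrt(unit_area / pi)
  hw <- ceiling(3 * psf_sigma + rd)
  ax <- -hw:hw
  ss <- 4
  sub <- seq(-0.5 + 1 / (2 * ss), 0.5 - 1 / (2 * ss), length.out = ss)
  grid <- expand.grid(dx = sub, dy = sub)
  acc <- matrix(0, length(ax), length(ax))
  gx <- outer(ax, ax, function(i, j) i)
  gy <- outer(ax, ax, function(i, j) j)
  # disc indicator convolved with gaussian = sum over disc area; approximate
  # by integrating the gaussian-blurred disc at supersampled offsets
  ds <- seq(-rd, rd, length.out = 9)
  dg <- expand.grid(ux = ds, uy = ds)
  dg <- dg[dg$ux^2 + dg$uy^2 <= rd^2, ]
  w <- 1 / nrow(dg)
  for (k in seq_len(nrow(dg))) {
    acc <- acc + w * exp(-((gx - dg$ux[k])^2 + (gy - dg$uy[k])^2) /
                           (2 * psf_sigma^2))
  }
  acc / max(acc)
}

#' Render an image stack from a roster and latent traces
#'
#' Each cell is a uniform disc of brightness
#' `background + expression * photon_scale`; per frame it additionally shows
#' `N ~ Poisson(mass / droplet_mass_per_punctum)` puncta at fixed, seeded
#' positions inside the disc. Puncta appear and disappear in seniority order
#' (frame `t` shows the first `N_t` of the cell's position pool), so droplet
#' patterns are temporally coherent. Punctum peak brightness is
#' `expression * droplet_intensity_gain`. Gaussian read noise is added per
#' pixel and frames are rounded and clipped to the sensor range.
#'
#' @param roster a [simulate_roster()] result.
#' @param traces matching [simulate_activity()] result.
#' @param optics an [optics_config()].
#' @return Object of class `image_stack`: list with `frames` (list of
#'   integer `H x W` matrices), `timestamps` (min), `protocol`, `optics`.
#' @export
#' @examples
#' r <- simulate_roster(spark_config(n_cells = 8, frame_shape = c(160, 160)))
#' a <- simulate_activity(r, protocol_forskolin(), kinetic_params())
#' st <- render_stack(r, a, optics_config(frame_shape = c(160, 160)))
#' length(st$frames)
render_stack <- function(roster, traces, optics) {
  stopifnot(inherits(roster, "cell_roster"),
            inherits(traces, "activity_traces"),
            inherits(optics, "optics_config"))
  shape <- optics$frame_shape
  if (is.null(shape)) shape <- attr(roster, "config")$frame_shape
  if (is.null(shape)) stopf("no frame_shape in optics or roster config")
  H <- shape[1]; W <- shape[2]
  if (any(roster$x - roster$radius < 1 | roster$x + roster$radius > H |
          roster$y - roster$radius < 1 | roster$y + roster$radius > W))
    stopf("cell disc outside the %dx%d frame", H, W)

  dur <- attr(traces$protocol, "duration")
  timestamps <- seq(0, dur, by = optics$frame_interval)
  massT <- sample_mass(traces, timestamps)
  n <- nrow(roster); Tn <- length(timestamps)

  masks <- roster_masks(roster, shape)
  base <- matrix(optics$background_level, H, W)
  for (i in seq_len(n))
    base[masks[[i]]] <- optics$background_level +
      roster$expression[i] * optics$photon_scale

  kern <- punctum_kernel(optics$psf_sigma, optics$droplet_unit_area)
  hw <- (nrow(kern) - 1L) %/% 2L
  koff <- as.vector(outer(-hw:hw, -hw:hw, function(i, j) i + j * H))
  kval <- as.vector(kern)
  krow <- as.vector(outer(-hw:hw, -hw:hw, function(i, j) i))
  kcol <- as.vector(outer(-hw:hw, -hw:hw, function(i, j) j))

  cap <- 2^optics$bit_depth - 1
  frames <- vector("list", Tn)
  with_seed(optics$seed, {
    # fixed per-cell punctum position pools and per-frame punctum counts
    Ncounts <- matrix(stats::rpois(n * Tn,
                                   massT / optics$droplet_mass_per_punctum),
                      n, Tn)
    pool <- vector("list", n)
    pos_margin <- 3
    for (i in seq_len(n)) {
      K <- max(Ncounts[i, ])
      if (K == 0) { pool[[i]] <- NULL; next }
      rmax <- max(roster$radius[i] - pos_margin, 1)
      rr <- rmax * sqrt(stats::runif(K))
      th <- stats::runif(K, 0, 2 * pi)
      pool[[i]] <- cbind(round(roster$x[i] + rr * cos(th)),
                         round(roster$y[i] + rr * sin(th)))
    }
    for (f in seq_len(Tn)) {
      fr <- base
      px_all <- integer(0); val_all <- numeric(0)
      for (i in seq_len(n)) {
        Np <- Ncounts[i, f]
        if (Np == 0) next
        amp <- roster$expression[i] * optics$droplet_intensity_gain
        ctr <- pool[[i]][seq_len(Np), , drop = FALSE]
        cx <- rep(ctr[, 1], each = length(koff)) + krow
        cy <- rep(ctr[, 2], each = length(koff)) + kcol
        ok <- cx >= 1 & cx <= H & cy >= 1 & cy <= W
        px_all <- c(px_all, (cx[ok] + (cy[ok] - 1L) * H))
        val_all <- c(val_all, (amp * rep(kval, Np))[ok])
      }
      if (length(px_all)) {
        agg <- rowsum(val_all, px_all)
        fr[as.integer(rownames(agg))] <- fr[as.integer(rownames(agg))] + agg[, 1]
      }
      if (optics$read_noise_sd > 0)
        fr <- fr + stats::rnorm(H * W, 0, optics$read_noise_sd)
      frames[[f]] <- matrix(as.integer(pmin(pmax(round(fr), 0), cap)), H, W)
    }
  })
  structure(list(frames = frames, timestamps = timestamps,
                 protocol = traces$protocol, optics = optics),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frames of %dx%d px, %g min interval\n",
              length(x$frames), d[1], d[2], x$optics$frame_interval))
  cat(sprintf("  protocol: %s\n",
              paste(sprintf("%s@%gmin", x$protocol$agent, x$protocol$time),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus sidecar JSON
#'
#' The TIFF holds one 16-bit page per frame; the sidecar records schema
#' version, seed, configuration hash, timestamps, protocol and optics, so a
#' stack round-trips losslessly.
#'
#' @param stack an `image_stack`.
#' @param tiff_path TIFF file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_stack` returns `tiff_path` invisibly; `read_stack` an
#'   `image_stack`.
#' @export
write_stack <- function(stack, tiff_path) {
  stopifnot(inherits(stack, "image_stack"))
  cap <- 2^stack$optics$bit_depth - 1
  pages <- lapply(stack$frames, function(m) m / cap)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  side <- list(
    schema = "sparkdrop_stack_v1",
    seed = stack$optics$seed,
    config_hash = config_hash(unclass(stack$optics)),
    bit_depth = stack$optics$bit_depth,
    timestamps = stack$timestamps,
    protocol = list(events = as.data.frame(stack$protocol),
                    duration = attr(stack$protocol, "duration"),
                    baseline = attr(stack$protocol, "baseline")),
    optics = unclass(stack$optics)
  )
  jsonlite::write_json(side, paste0(tiff_path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(tiff_path)
}

#' @rdname write_stack
#' @param tiff_path path of a stack written by `write_stack`.
#' @export
read_stack <- function(tiff_path) {
  side <- jsonlite::read_json(paste0(tiff_path, ".json"), simplifyVector = TRUE)
  if (!identical(side$schema, "sparkdrop_stack_v1"))
    stopf("unrecognised stack sidecar schema: %s", side$schema)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  cap <- 2^side$bit_depth - 1
  frames <- lapply(pages, function(p) {
    m <- round(p * cap)
    matrix(as.integer(m), nrow(m), ncol(m))
  })
  ev <- side$protocol$events
  prot <- stim_protocol(ev$time, ev$agent, ev$kind,
                        duration = side$protocol$duration,
                        baseline = side$protocol$baseline)
  oc <- side$optics
  optics <- optics_config(frame_shape = oc$frame_shape,
                          psf_sigma = oc$psf_sigma,
                          background_level = oc$background_level,
                          read_noise_sd = oc$read_noise_sd,
                          photon_scale = oc$photon_scale,
                          droplet_unit_area = oc$droplet_unit_area,
                          droplet_intensity_gain = oc$droplet_intensity_gain,
                          droplet_mass_per_punctum = oc$droplet_mass_per_punctum,
                          frame_interval = oc$frame_interval,
                          bit_depth = oc$bit_depth, seed = oc$seed)
  structure(list(frames = frames, timestamps = side$timestamps,
                 protocol = prot, optics = optics),
            class = "image_stack")
}
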