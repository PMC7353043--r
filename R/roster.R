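# Ground-truth cell roster: placement, expression, capability and
# hormone-specific responder structure.

#' Simulate a ground-truth cell roster
#'
#' Draws a field of non-overlapping cell discs with log-normal biosensor
#' expression and deterministic responder-set sizes: exactly
#' `round(n_cells * frac)` cells (round-half-up) belong to each subset, so
#' population shares are exact at roster level and all sampling noise enters
#' later, through imaging. Subsets are prefixes of one seeded permutation:
#' the capable set first, the PKA-responsive set as its superset (when
#' `frac_pka_responsive >= frac_capable`), and in nested mode each hormone's
#' responder set as a prefix of the capable ordering, largest hormone first,
#' so all hormone sets form a nested chain inside the capable set. In
#' independent mode each hormone set is an independent draw from the capable
#' pool.
#'
#' @param config a [spark_config()].
#' @return A data frame of class `cell_roster`: one row per cell with
#'   `cell_id`, disc centre `x`, `y` (pixels, row/column), `radius`,
#'   `expression`, logical `capable` and `pka_responsive`, the activator
#'   response amplitude `amp_activator`, and per hormone `h` the columns
#'   `resp_h` (membership), `arch_h` (archetype) and `amp_h` (amplitude).
#'   Attributes: `hormones`, `config`.
#' @export
#' @examples
#' r <- simulate_roster(spark_config(n_cells = 40, seed = 7))
#' sum(r$capable)
simulate_roster <- function(config) {
  stopifnot(inherits(config, "spark_config"))
  n <- config$n_cells
  with_seed(config$seed, {
    pos <- place_discs(n, config$frame_shape, config$cell_radius,
                       config$placement_gap)
    expr <- stats::rlnorm(n, config$expression_law[["meanlog"]],
                          config$expression_law[["sdlog"]])
    perm <- sample.int(n)
    k_cap <- round_half_up(n * config$frac_capable)
    k_pka <- round_half_up(n * config$frac_pka_responsive)
    capable <- logical(n); capable[perm[seq_len(k_cap)]] <- TRUE
    pka <- logical(n); pka[perm[seq_len(k_pka)]] <- TRUE

    roster <- data.frame(
      cell_id = seq_len(n), x = pos$x, y = pos$y,
      radius = config$cell_radius, expression = expr,
      capable = capable, pka_responsive = pka,
      amp_activator = rlnorm_mean(n, config$activator_amplitude_mean,
                                  config$activator_amplitude_cv)
    )

    panel <- config$hormone_panel
    ord <- order(vapply(panel, `[[`, numeric(1), "responder_frac"),
                 decreasing = TRUE)
    hormones <- names(panel)[ord]
    largest_k <- if (length(hormones)) {
      round_half_up(n * panel[[hormones[1]]]$responder_frac)
    } else 0L
    for (h in hormones) {
      e <- panel[[h]]
      k <- round_half_up(n * e$responder_frac)
      if (k > k_cap)
        stopf("responder set of %s (%d cells) cannot exceed the capable set (%d)",
              h, k, k_cap)
      member_ids <- if (config$overlap_mode == "nested") {
        ids <- perm[seq_len(k)]
        k_eps <- round_half_up(k * config$nested_epsilon)
        if (k_eps > 0 && h != hormones[1] && largest_k < k_cap) {
          outside <- perm[(largest_k + 1):k_cap]
          swap <- outside[seq_len(min(k_eps, length(outside)))]
          ids <- c(ids[seq_len(k - length(swap))], swap)
        }
        ids
      } else {
        sample(perm[seq_len(k_cap)], k)
      }
      memb <- logical(n); memb[member_ids] <- TRUE
      arch <- rep(NA_character_, n)
      w <- e$archetype_weights[c("transient", "sustained", "dissolving")]
      arch[member_ids] <- sample(names(w), length(member_ids),
                                 replace = TRUE, prob = w)
      amp <- rep(NA_real_, n)
      amp[member_ids] <- rlnorm_mean(length(member_ids), e$amplitude_mean,
                                     e$amplitude_cv)
      sus <- !is.na(arch) & arch == "sustained"
      amp[sus] <- amp[sus] * config$sustained_amp_factor
      roster[[paste0("resp_", h)]] <- memb
      roster[[paste0("arch_", h)]] <- arch
      roster[[paste0("amp_", h)]] <- amp
    }
  })
  structure(roster, hormones = names(config$hormone_panel), config = config,
            class = c("cell_roster", "data.frame"))
}

# log-normal draw parameterised by mean and coefficient of variation
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# rejection-sampled non-overlapping disc centres, fully inside the frame
place_discs <- function(n, frame_shape, radius, gap, max_tries = 500L) {
  H <- frame_shape[1]; W <- frame_shape[2]
  margin <- radius + 1
  if (H - 2 * margin < 1 || W - 2 * margin < 1)
    stopf("frame %dx%d too small for cells of radius %g", H, W, radius)
  min_d2 <- (2 * radius + gap)^2
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      px <- stats::runif(1, margin, H - margin)
      py <- stats::runif(1, margin, W - margin)
      if (i == 1 || all((x[seq_len(i - 1)] - px)^2 +
                        (y[seq_len(i - 1)] - py)^2 >= min_d2)) {
        x[i] <- px; y[i] <- py; placed <- TRUE; break
      }
    }
    if (!placed)
      stopf("could not place %d non-overlapping cells of radius %g in a %dx%d frame",
            n, radius, H, W)
  }
  list(x = x, y = y)
}

#' @export
print.cell_roster <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("cell_roster: %d cells (%d capable, %d PKA-responsive)\n",
              nrow(x), sum(x$capable), sum(x$pka_responsive)))
  for (h in attr(x, "hormones"))
    cat(sprintf("  %-14s %d responders\n", h, sum(x[[paste0("resp_", h)]])))
  if (!is.null(cfg))
    cat(sprintf("  frame %dx%d, seed %d\n", cfg$frame_shape[1],
                cfg$frame_shape[2], cfg$seed))
  invisible(x)
}

#' Pixel masks of the roster's cell discs
#'
#' @param roster a [simulate_roster()] result.
#' @param frame_shape `c(H, W)`; defaults to the roster's configured frame.
#' @return List of integer vectors of linear (column-major) pixel indices,
#'   one per cell.
#' @export
roster_masks <- function(roster, frame_shape = NULL) {
  if (is.null(frame_shape)) frame_shape <- attr(roster, "config")$frame_shape
  lapply(seq_len(nrow(roster)), function(i)
    disc_pixels(roster$x[i], roster$y[i], roster$radius[i], frame_shape))
}

#' Write / read a roster as CSV
#'
#' The CSV carries `#`-prefixed header lines with the schema version, seed
#' and configuration hash, then one row per cell.
#'
#' @param roster a `cell_roster`.
#' @param path file path.
#' @return `write_roster` returns `path` invisibly; `read_roster` the
#'   roster data frame (without the original config attribute).
#' @export
write_roster <- function(roster, path) {
  cfg <- attr(roster, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sparkdrop_schema: 1",
               sprintf("# seed: %d", if (is.null(cfg)) NA_integer_ else cfg$seed),
               sprintf("# config_hash: %s",
                       if (is.null(cfg)) "" else config_hash(unclass(cfg))),
               sprintf("# hormones: %s",
                       paste(attr(roster, "hormones"), collapse = ","))), con)
  utils::write.csv(as.data.frame(roster), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  head <- readLines(path, n = 10)
  hz <- sub("^# hormones: ?", "", grep("^# hormones:", head, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(df,
            hormones = if (length(hz) && nzchar(hz))
              strsplit(hz, ",")[[1]] else character(0),
            class = c("cell_roster", "data.frame"))
}
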