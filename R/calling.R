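# Responder calling, population shares, sequential overlap and clone
# summaries.

#' Response-calling parameters
#'
#' A cell is called a responder to a stimulus when its statistic exceeds its
#' pre-stimulus baseline by `max(abs_min_rise, k_resp * baseline SD)` for at
#' least `m_frames` consecutive frames. The baseline window is re-anchored
#' immediately before each stimulus, because droplets persist: after a
#' first stimulus the absolute level stays high, and only a further rise
#' counts as a new response. A dissolving call (net droplet loss) requires a
#' pre-existing signal (`baseline > abs_min_rise`) and a *rapid* fractional
#' drop: the statistic must fall below `diss_frac * baseline` within
#' `t_diss` minutes of the stimulus. The rate requirement separates
#' Gi-driven dissolution from the slow passive droplet disassembly that any
#' persisting cell shows.
#'
#' @param k_resp multiplier on the baseline-window SD.
#' @param m_frames consecutive frames required above (below) the margin.
#' @param abs_min_rise absolute minimum rise, in statistic units (px^2 for
#'   the default area statistic) — the working criterion when the baseline
#'   is exactly zero, as it typically is for droplet area.
#' @param b_win baseline window length (min) before each stimulus.
#' @param t_trans archetype window (min): a responder whose (smoothed) trace
#'   falls back below half-amplitude within `t_trans` of its peak is
#'   transient, one that stays above is sustained.
#' @param smooth_w running-mean window (frames) used for archetype timing.
#' @param diss_frac,t_diss dissolution call: statistic below
#'   `diss_frac * baseline` within `t_diss` min of the stimulus.
#' @return Object of class `call_params`.
#' @export
call_params <- function(k_resp = 5, m_frames = 3, abs_min_rise = 8,
                        b_win = 5, t_trans = 18, smooth_w = 3,
                        diss_frac = 0.35, t_diss = 8) {
  if (k_resp < 0 || abs_min_rise < 0) stopf("margins must be >= 0")
  if (!is_count(m_frames)) stopf("m_frames must be a positive integer")
  if (!is_frac(diss_frac)) stopf("diss_frac must lie in [0, 1]")
  structure(list(k_resp = k_resp, m_frames = as.integer(m_frames),
                 abs_min_rise = abs_min_rise, b_win = b_win,
                 t_trans = t_trans, smooth_w = smooth_w,
                 diss_frac = diss_frac, t_diss = t_diss),
            class = "call_params")
}

#' Call responses for every gated cell and stimulus
#'
#' @param traces a [build_traces()] result.
#' @param params a [call_params()].
#' @return Data frame of class `response_calls`: one row per gated cell and
#'   non-wash stimulus with `cell` (mask label), `stimulus`, `stim_time`,
#'   `responder`, `amplitude` (max post-stimulus value minus baseline;
#'   negative for dissolving calls), `onset_frame`, `duration` (min above
#'   half-amplitude) and `archetype` (`transient`, `sustained`,
#'   `dissolving` or `nonresponder`). Dissolving calls are responders with
#'   `archetype = "dissolving"`; only droplet-forming responders enter
#'   [population_share()].
#' @export
call_responses <- function(traces, params = call_params()) {
  stopifnot(inherits(traces, "spark_traces"))
  prot <- traces$protocol
  stim <- prot[prot$kind != "wash", , drop = FALSE]
  ts <- traces$timestamps
  out <- list()
  for (s in seq_len(nrow(stim))) {
    t_k <- stim$time[s]
    later <- stim$time[stim$time > t_k]
    t_next <- if (length(later)) min(later) else Inf
    base_idx <- which(ts >= t_k - params$b_win & ts < t_k)
    if (length(base_idx) < 2)
      stopf("baseline window before stimulus at %g min has fewer than 2 frames", t_k)
    post_idx <- which(ts >= t_k & ts < t_next)
    for (ci in seq_len(nrow(traces$values))) {
      v <- traces$values[ci, ]
      call <- call_one(v, base_idx, post_idx, ts, params)
      out[[length(out) + 1]] <- data.frame(
        cell = as.integer(rownames(traces$values)[ci]),
        stimulus = stim$agent[s], stim_time = t_k,
        responder = call$responder, amplitude = call$amplitude,
        onset_frame = call$onset_frame, duration = call$duration,
        archetype = call$archetype, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), statistic = traces$statistic,
            class = c("response_calls", "data.frame"))
}

call_one <- function(v, base_idx, post_idx, ts, params) {
  base <- mean(v[base_idx])
  bsd <- stats::sd(v[base_idx])
  margin <- max(params$abs_min_rise, params$k_resp * bsd)
  post <- v[post_idx]
  up <- post > base + margin
  onset_rel <- first_run_at_least(up, params$m_frames)
  if (!is.na(onset_rel)) {
    amplitude <- max(post) - base
    half <- base + amplitude / 2
    dur <- sum(post > half) * (ts[2] - ts[1])
    arch <- classify_archetype(post, ts[post_idx], base, params)
    return(list(responder = TRUE, amplitude = amplitude,
                onset_frame = post_idx[onset_rel], duration = dur,
                archetype = arch))
  }
  if (base > params$abs_min_rise) {
    early <- ts[post_idx] <= ts[post_idx][1] + params$t_diss
    down <- early & post < params$diss_frac * base
    d_rel <- first_run_at_least(down, params$m_frames)
    if (!is.na(d_rel)) {
      return(list(responder = TRUE, amplitude = min(post) - base,
                  onset_frame = post_idx[d_rel],
                  duration = 0, archetype = "dissolving"))
    }
  }
  list(responder = FALSE, amplitude = max(post) - base,
       onset_frame = NA_integer_, duration = 0, archetype = "nonresponder")
}

#' Classify a responding trace as transient or sustained
#'
#' Works on the post-stimulus window of the trace, smoothed with a short
#' running mean to tame the punctum-count noise of the area statistic. The
#' peak is the smoothed maximum; the response is transient when the
#' smoothed trace has returned below `baseline + amplitude/2` by `t_trans`
#' minutes after the peak (assessed as the mean of the smoothed values in
#' the last two minutes of that window, so that single noisy dips of a
#' plateauing trace do not masquerade as decay), otherwise sustained. A
#' peak too close to the end of the movie to be assessed (the trace is
#' still rising at the last frames) is sustained.
#'
#' @param post post-stimulus statistic values.
#' @param times their timestamps (min).
#' @param baseline pre-stimulus baseline level.
#' @param params a [call_params()].
#' @return `"transient"` or `"sustained"`.
#' @export
classify_archetype <- function(post, times, baseline, params = call_params()) {
  sm <- running_mean(post, params$smooth_w)
  # peak time = last point of the 90%-of-maximum plateau; the plain argmax
  # of a noisy trace is a poor anchor for decay timing. The peak *level* is
  # the plateau mean, not the noisy maximum, so that `half` is not inflated
  # by a single overshooting frame.
  pk <- max(which(sm >= baseline + 0.9 * (max(sm) - baseline)))
  plateau <- mean(sm[max(1, pk - 3):pk])
  half <- baseline + (plateau - baseline) / 2
  t_end <- min(times[pk] + params$t_trans, max(times))
  probe <- which(times > t_end - 3 & times <= t_end)
  if (length(probe) == 0) probe <- length(times)
  if (mean(sm[probe]) <= half) "transient" else "sustained"
}

#' Population share of responding cells
#'
#' The share per replicate unit (imaging field, experiment) is
#' `100 * n_responding / n_gated`, counting droplet-forming responders
#' (archetypes transient and sustained); the reported share is the mean
#' across replicates with its standard error (`SD / sqrt(R)`; 0 for a
#' single replicate). With several stimuli, shares are reported per
#' stimulus.
#'
#' @param calls a [call_responses()] result, or several row-bound together.
#' @param replicate replicate labels, one per row of `calls` (a single
#'   label is recycled).
#' @return Object of class `population_summary`: data frame with one row
#'   per stimulus (`stimulus`, `n_gated`, `n_responding`, `share`, `se`,
#'   `n_replicates`), with attribute `per_replicate`.
#' @export
population_share <- function(calls, replicate = "field1") {
  stopifnot(inherits(calls, "data.frame"))
  if (length(replicate) == 1) replicate <- rep(replicate, nrow(calls))
  if (length(replicate) != nrow(calls))
    stopf("replicate labels must match rows of calls")
  forming <- calls$responder & calls$archetype %in% c("transient", "sustained")
  key <- interaction(replicate, calls$stimulus, drop = TRUE)
  per <- do.call(rbind, lapply(split(seq_len(nrow(calls)), key), function(i) {
    data.frame(replicate = replicate[i[1]], stimulus = calls$stimulus[i[1]],
               n_gated = length(i), n_responding = sum(forming[i]),
               stringsAsFactors = FALSE)
  }))
  empty <- per$n_gated == 0
  if (any(empty)) {
    warnf("excluding %d replicate(s) with no gated cells", sum(empty))
    per <- per[!empty, , drop = FALSE]
  }
  if (nrow(per) == 0) stopf("no replicates with gated cells")
  per$share <- 100 * per$n_responding / per$n_gated
  summ <- do.call(rbind, lapply(split(per, per$stimulus), function(p) {
    R <- nrow(p)
    data.frame(stimulus = p$stimulus[1],
               n_gated = sum(p$n_gated), n_responding = sum(p$n_responding),
               share = mean(p$share),
               se = if (R > 1) stats::sd(p$share) / sqrt(R) else 0,
               n_replicates = R, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(summ, per_replicate = per,
            class = c("population_summary", "data.frame"))
}

#' @export
print.population_summary <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-16s %5.1f %% responding (SE %.2f, %d/%d cells, %d replicate%s)\n",
                x$stimulus[i], x$share[i], x$se[i], x$n_responding[i],
                x$n_gated[i], x$n_replicates[i],
                if (x$n_replicates[i] > 1) "s" else ""))
  invisible(x)
}

#' Overlap structure of sequential stimulations
#'
#' For each stimulus in protocol order: how many gated cells responded
#' (droplet formation), how many were *new* responders (not responders to
#' any earlier stimulus), and the cumulative union share.
#'
#' @param calls a [call_responses()] result covering >= 2 stimuli on the
#'   same cells.
#' @return Data frame with `stimulus`, `stim_time`, `n_responders`, `n_new`,
#'   `union_n`, `union_share` (percent of gated cells).
#' @export
sequential_overlap <- function(calls) {
  stopifnot(inherits(calls, "data.frame"))
  stims <- unique(calls[, c("stimulus", "stim_time")])
  stims <- stims[order(stims$stim_time), , drop = FALSE]
  if (nrow(stims) < 2) stopf("sequential_overlap needs >= 2 stimuli")
  sets <- lapply(seq_len(nrow(stims)), function(s) {
    rows <- calls$stimulus == stims$stimulus[s] &
      calls$stim_time == stims$stim_time[s]
    list(cells = unique(calls$cell[rows]),
         resp = unique(calls$cell[rows & calls$responder &
                                    calls$archetype %in% c("transient", "sustained")]))
  })
  common <- Reduce(intersect, lapply(sets, `[[`, "cells"))
  if (length(common) == 0) stopf("stimuli were applied to disjoint cell sets")
  n_gated <- length(unique(calls$cell))
  seen <- integer(0)
  out <- list()
  for (s in seq_along(sets)) {
    r <- sets[[s]]$resp
    out[[s]] <- data.frame(stimulus = stims$stimulus[s],
                           stim_time = stims$stim_time[s],
                           n_responders = length(r),
                           n_new = length(setdiff(r, seen)),
                           union_n = length(union(seen, r)),
                           stringsAsFactors = FALSE)
    seen <- union(seen, r)
  }
  out <- do.call(rbind, out)
  out$union_share <- 100 * out$union_n / n_gated
  out
}

#' Clone-level share summary
#'
#' Treats each single-cell-derived clone as a replicate unit: the share of
#' responding cells per clone, and the grand mean with its standard error
#' across clones. Clones without gated cells are excluded with a warning.
#'
#' @param calls row-bound [call_responses()] results across clones.
#' @param clone clone labels, one per row of `calls`.
#' @return List of class `clone_summary`: `per_clone` data frame
#'   (`clone`, `n_gated`, `n_responding`, `share`), `grand_mean`, `se`,
#'   `n_clones`.
#' @export
clone_summary <- function(calls, clone) {
  if (length(clone) != nrow(calls))
    stopf("clone labels must match rows of calls")
  if (length(unique(clone)) < 2) stopf("clone_summary needs >= 2 clones")
  ps <- population_share(calls, replicate = clone)
  per <- attr(ps, "per_replicate")
  per <- data.frame(clone = per$replicate, n_gated = per$n_gated,
                    n_responding = per$n_responding, share = per$share,
                    stringsAsFactors = FALSE)
  structure(list(per_clone = per, grand_mean = mean(per$share),
                 se = stats::sd(per$share) / sqrt(nrow(per)),
                 n_clones = nrow(per)),
            class = "clone_summary")
}

#' @export
print.clone_summary <- function(x, ...) {
  cat(sprintf("clone_summary: %d clones, grand mean share %.1f %% (SE %.1f)\n",
              x$n_clones, x$grand_mean, x$se))
  invisible(x)
}
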