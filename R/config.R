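# Configuration objects for the synthetic population, stimulation protocols
# and droplet kinetics.

#' Default hormone panel
#'
#' Responder fractions and response archetypes for the five Gs-coupled
#' agonists studied with the biosensor: adenosine, noradrenaline and dopamine
#' elicit strong transient responses, serotonin and histamine long but weak
#' (sustained) ones. Responder fractions are the reported population shares
#' (37.0, 34.7, 25.2, 16.6 and 4.2 percent).
#'
#' @param amplitude_mean mean peak PKA activity (arbitrary units) of a
#'   transient response; sustained responses are scaled down by the
#'   `sustained_amp_factor` of [spark_config()].
#' @param amplitude_cv coefficient of variation of per-cell amplitudes
#'   (log-normal).
#' @return Named list mapping hormone name to its panel entry
#'   (`responder_frac`, `archetype_weights`, `amplitude_mean`, `amplitude_cv`).
#' @export
#' @examples
#' names(default_hormone_panel())
default_hormone_panel <- function(amplitude_mean = 1, amplitude_cv = 0.3) {
  arch <- function(tr, su, di) c(transient = tr, sustained = su, dissolving = di)
  entry <- function(frac, w) list(responder_frac = frac, archetype_weights = w,
                                  amplitude_mean = amplitude_mean,
                                  amplitude_cv = amplitude_cv)
  list(
    adenosine     = entry(0.370, arch(1, 0, 0)),
    noradrenaline = entry(0.347, arch(1, 0, 0)),
    dopamine      = entry(0.252, arch(1, 0, 0)),
    serotonin     = entry(0.166, arch(0, 1, 0)),
    histamine     = entry(0.042, arch(0, 1, 0))
  )
}

#' Synthetic population configuration
#'
#' Describes the ground-truth structure of a simulated field of biosensor
#' expressing cells: how many cells, which fraction can activate the
#' cAMP/PKA axis at all (i.e. possess adenylyl cyclase), which fraction
#' responds to a direct PKA activator, and the hormone-specific responder
#' subsets. In `"nested"` overlap mode the hormone responder sets are drawn
#' as prefixes of one seeded ordering of the capable set, largest set first,
#' so that smaller sets are subsets of larger ones and all are subsets of
#' the capable set — the population structure in which a second hormone
#' activates (almost) only cells the first one already activated.
#'
#' @param n_cells number of cells in the field.
#' @param frac_capable fraction of cells able to activate cAMP/PKA signalling
#'   (responders to receptor agonists and to an adenylyl cyclase activator
#'   such as forskolin).
#' @param frac_pka_responsive fraction of cells responding to a direct PKA
#'   activator (e.g. 6-Bnz-cAMP); PKA itself is near-uniformly present, so
#'   this is close to 1. Drawn from the same seeded ordering as the capable
#'   set, hence a superset of it whenever
#'   `frac_pka_responsive >= frac_capable`.
#' @param hormone_panel named list as produced by [default_hormone_panel()].
#' @param overlap_mode `"nested"` (default) or `"independent"`.
#' @param nested_epsilon in nested mode, fraction of each hormone set drawn
#'   from capable cells outside the largest hormone set (the "small
#'   addition" of fresh responders to a later hormone); default 0.
#' @param expression_law log-normal parameters `c(meanlog, sdlog)` of the
#'   per-cell biosensor expression level (arbitrary fluorescence units).
#' @param detection_floor expression level below which rendered droplets are
#'   too dim to distinguish from noise; used to calibrate the default
#'   expression gate.
#' @param activator_amplitude_mean,activator_amplitude_cv amplitude law of
#'   the response to forskolin / direct PKA activation (transient archetype).
#' @param sustained_amp_factor multiplier applied to sustained-archetype
#'   activity amplitudes (long responses have much lower amplitude). Droplet
#'   mass integrates activity, so a sustained response accumulates mass far
#'   more efficiently than a transient burst of equal activity amplitude;
#'   0.2 keeps the observed droplet-statistic amplitude of sustained
#'   responses well below the transient one while staying detectable.
#' @param frame_shape `c(H, W)` of the imaging field in pixels; cell
#'   placement is confined to it.
#' @param cell_radius cell disc radius in pixels.
#' @param placement_gap minimum edge-to-edge gap between cell discs (px).
#' @param seed integer seed controlling the roster draw.
#' @return An object of class `spark_config`.
#' @export
#' @examples
#' cfg <- spark_config(n_cells = 50, seed = 1)
#' cfg$frac_capable
spark_config <- function(n_cells = 60,
                         frac_capable = 0.482,
                         frac_pka_responsive = 0.95,
                         hormone_panel = default_hormone_panel(),
                         overlap_mode = c("nested", "independent"),
                         nested_epsilon = 0,
                         expression_law = c(meanlog = log(100), sdlog = 0.5),
                         detection_floor = 40,
                         activator_amplitude_mean = 1,
                         activator_amplitude_cv = 0.3,
                         sustained_amp_factor = 0.2,
                         frame_shape = c(512L, 512L),
                         cell_radius = 15,
                         placement_gap = 4,
                         seed = 1L) {
  overlap_mode <- match.arg(overlap_mode)
  if (!is_count(n_cells)) stopf("n_cells must be a positive integer")
  for (nm in c("frac_capable", "frac_pka_responsive", "nested_epsilon")) {
    v <- get(nm)
    if (!is_frac(v)) stopf("%s must lie in [0, 1]", nm)
  }
  if (!is.list(hormone_panel) ||
      (length(hormone_panel) > 0 && is.null(names(hormone_panel))))
    stopf("hormone_panel must be a named list")
  for (h in names(hormone_panel)) {
    e <- hormone_panel[[h]]
    if (!is_frac(e$responder_frac))
      stopf("responder_frac of %s must lie in [0, 1]", h)
    w <- e$archetype_weights
    if (!all(c("transient", "sustained", "dissolving") %in% names(w)))
      stopf("archetype_weights of %s must name transient/sustained/dissolving", h)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stopf("archetype_weights of %s must be non-negative and sum to 1", h)
    if (overlap_mode == "nested" && e$responder_frac > frac_capable)
      stopf("nested overlap: responder_frac of %s (%.3f) exceeds frac_capable (%.3f)",
            h, e$responder_frac, frac_capable)
  }
  if (length(frame_shape) != 2 || any(frame_shape < 32))
    stopf("frame_shape must be c(H, W) with both >= 32")
  if (expression_law[["sdlog"]] < 0) stopf("expression sdlog must be >= 0")
  structure(list(
    n_cells = as.integer(n_cells),
    frac_capable = frac_capable,
    frac_pka_responsive = frac_pka_responsive,
    hormone_panel = hormone_panel,
    overlap_mode = overlap_mode,
    nested_epsilon = nested_epsilon,
    expression_law = expression_law,
    detection_floor = detection_floor,
    activator_amplitude_mean = activator_amplitude_mean,
    activator_amplitude_cv = activator_amplitude_cv,
    sustained_amp_factor = sustained_amp_factor,
    frame_shape = as.integer(frame_shape),
    cell_radius = cell_radius,
    placement_gap = placement_gap,
    seed = as.integer(seed)
  ), class = "spark_config")
}

#' @export
print.spark_config <- function(x, ...) {
  cat(sprintf("spark_config: %d cells, %.1f%% capable, %.1f%% PKA-responsive, %s overlap\n",
              x$n_cells, 100 * x$frac_capable, 100 * x$frac_pka_responsive,
              x$overlap_mode))
  cat(sprintf("  hormones: %s\n", paste(names(x$hormone_panel), collapse = ", ")))
  cat(sprintf("  frame %dx%d px, cell radius %g px, seed %d\n",
              x$frame_shape[1], x$frame_shape[2], x$cell_radius, x$seed))
  invisible(x)
}

stim_kinds <- c("receptor_agonist", "adenylyl_cyclase_activator",
                "direct_pka_activator", "wash")

#' Stimulation protocol
#'
#' An ordered series of bath-application events. Event kinds are
#' `receptor_agonist` (hormone acting through its receptor on member cells),
#' `adenylyl_cyclase_activator` (forskolin: every cAMP-capable cell),
#' `direct_pka_activator` (6-Bnz-cAMP: every PKA-responsive cell) and
#' `wash` (activity returns to zero; droplets are left to disassemble
#' passively).
#'
#' @param time event times in minutes, strictly increasing; the first event
#'   must not precede `baseline` minutes of unstimulated recording.
#' @param agent agent names (e.g. `"adenosine"`; must match a hormone-panel
#'   entry for receptor agonists).
#' @param kind event kinds, see above.
#' @param duration total recording duration (min).
#' @param baseline required unstimulated lead-in (min).
#' @return Data frame of class `stim_protocol` with attributes `duration`
#'   and `baseline`.
#' @export
#' @examples
#' stim_protocol(10, "forskolin", "adenylyl_cyclase_activator")
stim_protocol <- function(time, agent, kind, duration = 40, baseline = 10) {
  kind <- match.arg(kind, stim_kinds, several.ok = TRUE)
  if (length(kind) == 1) kind <- rep(kind, length(time))
  if (length(agent) == 1) agent <- rep(agent, length(time))
  if (length(time) == 0) stopf("protocol needs at least one event")
  if (any(diff(time) <= 0)) stopf("event times must be strictly increasing")
  if (time[1] < baseline)
    stopf("first event at %g min precedes the %g min baseline", time[1], baseline)
  if (max(time) >= duration) stopf("events must occur before `duration`")
  structure(data.frame(time = time, agent = agent, kind = kind,
                       stringsAsFactors = FALSE),
            duration = duration, baseline = baseline,
            class = c("stim_protocol", "data.frame"))
}

#' @rdname stim_protocol
#' @param agent_name agent for the single-stimulus helpers.
#' @param t_stim stimulation time (min).
#' @export
protocol_forskolin <- function(t_stim = 10, duration = 40, baseline = 10,
                               agent_name = "forskolin") {
  stim_protocol(t_stim, agent_name, "adenylyl_cyclase_activator",
                duration = duration, baseline = baseline)
}

#' @rdname stim_protocol
#' @export
protocol_direct_pka <- function(t_stim = 10, duration = 40, baseline = 10,
                                agent_name = "6-Bnz-cAMP") {
  stim_protocol(t_stim, agent_name, "direct_pka_activator",
                duration = duration, baseline = baseline)
}

#' @rdname stim_protocol
#' @export
protocol_hormone <- function(agent_name, t_stim = 10, duration = 40,
                             baseline = 10) {
  stim_protocol(t_stim, agent_name, "receptor_agonist",
                duration = duration, baseline = baseline)
}

#' @rdname stim_protocol
#' @param agents character vector of hormones applied sequentially.
#' @param dwell minutes each hormone is observed before the wash.
#' @param wash_gap minutes between a wash and the next hormone.
#' @export
protocol_sequential <- function(agents, t_stim = 10, dwell = 20, wash_gap = 5,
                                baseline = 10) {
  times <- c(); ag <- c(); kd <- c()
  t <- t_stim
  for (i in seq_along(agents)) {
    times <- c(times, t); ag <- c(ag, agents[i]); kd <- c(kd, "receptor_agonist")
    if (i < length(agents)) {
      times <- c(times, t + dwell); ag <- c(ag, "wash"); kd <- c(kd, "wash")
      t <- t + dwell + wash_gap
    }
  }
  stim_protocol(times, ag, kd, duration = t + dwell + 5, baseline = baseline)
}

#' Droplet-mass kinetic parameters
#'
#' Parameters of the latent activity and droplet-mass laws. PKA activity
#' follows the per-archetype law (transient: difference of exponentials with
#' rise `tau_rise` and decay `tau_decay`; sustained: saturating rise with
#' `tau_rise_sustained`); droplet mass integrates
#' `dD/dt = k_on * max(a - theta_nuc, 0) - k_off * D` by forward Euler at
#' step `dt`, with an extra `k_diss` disassembly rate for dissolving
#' responses. The default `k_off = log(2)/10` gives a 10-minute droplet
#' half-life: transitory responses visibly decay within the
#' archetype-classification window while part of the droplet mass (about
#' 12 percent) still remains 30 minutes after a wash.
#'
#' @param tau_rise,tau_decay transient-archetype rise/decay times (min).
#' @param tau_rise_sustained sustained-archetype rise time (min).
#' @param k_on droplet-mass units formed per activity-minute above threshold.
#' @param k_off passive droplet disassembly rate (1/min).
#' @param k_diss Gi-driven droplet dissolution rate (1/min).
#' @param theta_nuc nucleation threshold on activity.
#' @param dt forward-Euler step (min); must not exceed `tau_rise / 2`.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(tau_rise = 0.5, tau_decay = 5,
                           tau_rise_sustained = 3,
                           k_on = 2.5, k_off = log(2) / 10, k_diss = 0.5,
                           theta_nuc = 0.1, dt = 0.1) {
  vals <- c(tau_rise = tau_rise, tau_decay = tau_decay,
            tau_rise_sustained = tau_rise_sustained, k_on = k_on,
            k_off = k_off, k_diss = k_diss, theta_nuc = theta_nuc)
  if (any(!is.finite(vals)) || any(vals < 0))
    stopf("all kinetic rates and times must be finite and >= 0")
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be > 0")
  if (dt > tau_rise / 2)
    stopf("dt = %g is too coarse: must be <= tau_rise/2 = %g", dt, tau_rise / 2)
  structure(as.list(c(vals, dt = dt)), class = "kinetic_params")
}
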