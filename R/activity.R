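# Latent per-cell PKA activity and droplet-mass kinetics under a protocol.

#' Simulate latent activity and droplet mass
#'
#' Builds each cell's PKA activity trace from the stimulation protocol and
#' the roster's responder structure, then integrates droplet mass by forward
#' Euler:
#' `dD/dt = k_on * max(a - theta_nuc, 0) - k_off * D`, clipped at zero.
#' Transient responses follow a difference of exponentials
#' `A * (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise))`, sustained
#' responses a saturating rise `A * (1 - exp(-(t - t0)/tau_rise_sustained))`.
#' A wash zeroes all activity (droplets keep decaying at `k_off`); a
#' dissolving response contributes no activity but adds a `k_diss`
#' disassembly rate from its stimulus onward. Cells without adenylyl cyclase
#' (`capable = FALSE`) ignore receptor agonists and forskolin but respond to
#' a direct PKA activator when `pka_responsive`.
#'
#' @param roster a [simulate_roster()] result.
#' @param protocol a [stim_protocol()].
#' @param kinetics a [kinetic_params()].
#' @return Object of class `activity_traces`: list with `time` (the Euler
#'   grid, min), matrices `activity` and `mass` (`n_cells x length(time)`),
#'   and the protocol.
#' @export
#' @examples
#' r <- simulate_roster(spark_config(n_cells = 20, seed = 1))
#' a <- simulate_activity(r, protocol_forskolin(), kinetic_params())
#' range(a$mass)
simulate_activity <- function(roster, protocol, kinetics) {
  stopifnot(inherits(roster, "cell_roster"), inherits(protocol, "stim_protocol"),
            inherits(kinetics, "kinetic_params"))
  n <- nrow(roster)
  dur <- attr(protocol, "duration")
  dt <- kinetics$dt
  tt <- seq(0, dur, by = dt)
  nt <- length(tt)
  A <- matrix(0, n, nt)
  diss_from <- rep(Inf, n)

  wash_times <- protocol$time[protocol$kind == "wash"]
  next_wash <- function(t0) {
    w <- wash_times[wash_times > t0]
    if (length(w)) min(w) else Inf
  }

  for (ev in seq_len(nrow(protocol))) {
    kind <- protocol$kind[ev]
    if (kind == "wash") next
    t0 <- protocol$time[ev]
    tw <- next_wash(t0)
    if (kind == "receptor_agonist") {
      h <- protocol$agent[ev]
      rcol <- paste0("resp_", h)
      if (is.null(roster[[rcol]]))
        stopf("agent '%s' is not in the roster's hormone panel", h)
      members <- which(roster[[rcol]])
      arch <- roster[[paste0("arch_", h)]][members]
      amp <- roster[[paste0("amp_", h)]][members]
    } else if (kind == "adenylyl_cyclase_activator") {
      members <- which(roster$capable)
      arch <- rep("transient", length(members))
      amp <- roster$amp_activator[members]
    } else { # direct_pka_activator
      members <- which(roster$pka_responsive)
      arch <- rep("transient", length(members))
      amp <- roster$amp_activator[members]
    }
    if (!length(members)) next
    live <- tt >= t0 & tt < tw
    tl <- tt[live] - t0
    tr_shape <- exp(-tl / kinetics$tau_decay) - exp(-tl / kinetics$tau_rise)
    su_shape <- 1 - exp(-tl / kinetics$tau_rise_sustained)
    for (k in seq_along(members)) {
      i <- members[k]
      if (arch[k] == "transient") {
        A[i, live] <- A[i, live] + amp[k] * tr_shape
      } else if (arch[k] == "sustained") {
        A[i, live] <- A[i, live] + amp[k] * su_shape
      } else { # dissolving
        diss_from[i] <- min(diss_from[i], t0)
      }
    }
  }

  D <- matrix(0, n, nt)
  drive <- pmax(A - kinetics$theta_nuc, 0)
  for (j in seq_len(nt - 1)) {
    koff <- kinetics$k_off + kinetics$k_diss * (tt[j] >= diss_from)
    D[, j + 1] <- pmax(D[, j] + dt * (kinetics$k_on * drive[, j] - koff * D[, j]), 0)
  }
  structure(list(time = tt, activity = A, mass = D, protocol = protocol,
                 kinetics = kinetics),
            class = "activity_traces")
}

#' Sample latent droplet mass at given timestamps
#'
#' @param traces an [simulate_activity()] result.
#' @param timestamps times (min) at which to sample; must lie on `traces$time`
#'   up to rounding.
#' @return `n_cells x length(timestamps)` matrix of droplet mass.
#' @export
sample_mass <- function(traces, timestamps) {
  stopifnot(inherits(traces, "activity_traces"))
  dt <- traces$time[2] - traces$time[1]
  j <- round(timestamps / dt) + 1
  if (any(j < 1 | j > length(traces$time)))
    stopf("timestamps outside the simulated range")
  traces$mass[, j, drop = FALSE]
}

#' @export
print.activity_traces <- function(x, ...) {
  cat(sprintf("activity_traces: %d cells, %.0f min at dt = %g min\n",
              nrow(x$mass), max(x$time), x$time[2] - x$time[1]))
  cat(sprintf("  peak droplet mass %.2f, %d cells ever above zero\n",
              max(x$mass), sum(apply(x$mass, 1, max) > 0)))
  invisible(x)
}
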