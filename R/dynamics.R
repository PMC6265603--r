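#' Simulation settings
#'
#' Settings for continuous time-course integration. Time is in the
#' dimensionless "time units" of the model; the default horizon of 100
#' units with 201 grid points spans the transient and the quasi-steady
#' tail used for fold-change readouts.
#'
#' @param t_end simulation horizon (> 0).
#' @param n_points number of equally spaced output points (>= 2), including
#'   t = 0.
#' @param rel_tol,abs_tol integrator tolerances (> 0).
#' @param inhibition_steepness Hill steepness h of the smooth inhibition
#'   gate \eqn{g(m, w) = w^h / (w^h + m^h)}; larger h approaches the hard
#'   threshold "firing stops once the inhibitor reaches the arc weight".
#' @param hard_gate if `TRUE`, use the discontinuous gate
#'   \eqn{g = 1} for m < w, else 0 (semantics checks only; the smooth gate
#'   is the default because it keeps the right-hand side continuous for the
#'   stiff solver).
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(t_end = 100, n_points = 201,
                         rel_tol = 1e-8, abs_tol = 1e-9,
                         inhibition_steepness = 4, hard_gate = FALSE) {
  if (!is.numeric(t_end) || length(t_end) != 1 || !is.finite(t_end) ||
      t_end <= 0) {
    pn_stop("t_end must be a positive number", "ogtpn_settings_error")
  }
  if (!is.numeric(n_points) || n_points < 2 || n_points != round(n_points)) {
    pn_stop("n_points must be an integer >= 2", "ogtpn_settings_error")
  }
  if (rel_tol <= 0 || abs_tol <= 0 || inhibition_steepness <= 0) {
    pn_stop("tolerances and inhibition_steepness must be positive",
            "ogtpn_settings_error")
  }
  structure(list(t_end = t_end, n_points = as.integer(n_points),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 inhibition_steepness = inhibition_steepness,
                 hard_gate = isTRUE(hard_gate)),
            class = "sim_settings")
}

inhibition_gate <- function(m, w, steepness, hard) {
  if (hard) {
    as.numeric(m < w)
  } else {
    wh <- w^steepness
    wh / (wh + pmax(m, 0)^steepness)
  }
}

# Precompute per-transition index structure for fast rate evaluation.
compile_net <- function(net) {
  p_ids <- net$places$id
  t_ids <- net$transitions$id
  a <- net$arcs
  std_in <- a$arc_type == "standard" & a$source %in% p_ids
  inh_in <- a$arc_type == "inhibitory"
  trans <- lapply(seq_along(t_ids), function(j) {
    tid <- t_ids[j]
    si <- which(std_in & a$target == tid)
    ii <- which(inh_in & a$target == tid)
    list(k = net$transitions$rate_constant[j],
         in_idx = match(a$source[si], p_ids),
         in_w = a$weight[si],
         inh_idx = match(a$source[ii], p_ids),
         inh_w = a$weight[ii])
  })
  list(C = incidence_matrix(net), trans = trans, p_ids = p_ids,
       t_ids = t_ids)
}

rate_vector <- function(compiled, m, steepness, hard) {
  vapply(compiled$trans, function(tr) {
    r <- tr$k
    if (length(tr$in_idx) > 0) {
      r <- r * prod(pmax(m[tr$in_idx], 0)^tr$in_w)
    }
    if (length(tr$inh_idx) > 0) {
      r <- r * prod(inhibition_gate(m[tr$inh_idx], tr$inh_w, steepness, hard))
    }
    r
  }, numeric(1))
}

#' Continuous firing rate of one transition
#'
#' Mass-action rate law: the transition's rate constant times the product
#' of its standard input-place markings raised to the arc weights (kinetic
#' order = weight), times the inhibition gate of each inhibitory input.
#' Source transitions (no inputs) fire at their rate constant.
#'
#' @param net a valid `petri_net`.
#' @param marking named numeric marking covering the net's places.
#' @param transition_id id of the transition.
#' @param settings a [sim_settings()] object (supplies the inhibition gate
#'   shape).
#' @return Nonnegative scalar rate.
#' @export
transition_rate <- function(net, marking, transition_id,
                            settings = sim_settings()) {
  m <- check_marking(net, marking)
  j <- match(transition_id, net$transitions$id)
  if (is.na(j)) {
    pn_stop(sprintf("unknown transition '%s'", transition_id),
            "ogtpn_unknown_transition")
  }
  compiled <- compile_net(net)
  rate_vector(compiled, m, settings$inhibition_steepness,
              settings$hard_gate)[j]
}

#' Token-flow derivative of a marking
#'
#' The induced ODE system: d m/dt = C r(m), with C the incidence matrix
#' and r the vector of transition rates. Inhibitory arcs gate rates but
#' never move tokens.
#'
#' @inheritParams transition_rate
#' @return Named derivative vector over places.
#' @export
ode_rhs <- function(net, marking, settings = sim_settings()) {
  m <- check_marking(net, marking)
  compiled <- compile_net(net)
  r <- rate_vector(compiled, m, settings$inhibition_steepness,
                   settings$hard_gate)
  drop(compiled$C %*% r)
}

#' Simulate a continuous Petri net
#'
#' Integrates the mass-action ODE system with a stiff-capable adaptive
#' solver (`deSolve::lsoda`) and samples the solution on a uniform grid.
#' The run is deterministic given (net, settings). Small negative
#' excursions (|value| below 100 * `abs_tol`) are clipped to zero; larger
#' ones raise an error naming the first offending time, since they signal
#' a modelling or tolerance problem rather than round-off.
#'
#' @param net a valid `petri_net`.
#' @param settings a [sim_settings()] object.
#' @return An object of class `pn_trajectory`: list with `times` (length
#'   `n_points`), `markings` (matrix, rows = times, columns = places) and
#'   `net_name`.
#' @export
simulate_net <- function(net, settings = sim_settings()) {
  assert_valid(net)
  compiled <- compile_net(net)
  y0 <- initial_marking(net)
  times <- seq(0, settings$t_end, length.out = settings$n_points)
  steep <- settings$inhibition_steepness
  hard <- settings$hard_gate
  C <- compiled$C
  rhs <- function(t, y, parms) {
    r <- rate_vector(compiled, y, steep, hard)
    list(drop(C %*% r))
  }
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                   rtol = settings$rel_tol, atol = settings$abs_tol),
    warning = function(w) {
      pn_stop(sprintf("integration of '%s' failed: %s", net$name,
                      conditionMessage(w)), "ogtpn_integration_error")
    })
  if (nrow(sol) < settings$n_points) {
    pn_stop(sprintf("integration of '%s' stopped at t = %g", net$name,
                    sol[nrow(sol), "time"]), "ogtpn_integration_error")
  }
  mk <- unname(sol[, -1, drop = FALSE])
  colnames(mk) <- compiled$p_ids
  neg_lim <- -100 * settings$abs_tol
  worst <- min(mk)
  if (worst < neg_lim) {
    bad <- which(mk < neg_lim, arr.ind = TRUE)[1, ]
    pn_stop(sprintf("negative marking %.3g for place '%s' at t = %g",
                    worst, compiled$p_ids[bad[2]], times[bad[1]]),
            "ogtpn_negativity_error")
  }
  mk[mk < 0] <- 0
  structure(list(times = times, markings = mk, net_name = net$name),
            class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat(sprintf("<pn_trajectory> %s: %d places over t in [0, %g] (%d points)\n",
              x$net_name, ncol(x$markings), max(x$times), length(x$times)))
  invisible(x)
}

#' @export
as.data.frame.pn_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$markings, check.names = FALSE)
}

#' Scalar readout of a trajectory
#'
#' Summarises one place's time course. `mean_tail` (the default used for
#' fold-change reporting) averages the last 20% of the time grid, damping
#' transients; `final` takes the last point; `max` the maximum.
#'
#' @param traj a `pn_trajectory`.
#' @param place_id place to read.
#' @param mode one of `mean_tail`, `final`, `max`.
#' @return Scalar readout in relative activity units.
#' @export
readout <- function(traj, place_id,
                    mode = c("mean_tail", "final", "max")) {
  mode <- match.arg(mode)
  if (!(place_id %in% colnames(traj$markings))) {
    pn_stop(sprintf("unknown place '%s' in trajectory", place_id),
            "ogtpn_unknown_place")
  }
  y <- traj$markings[, place_id]
  switch(mode,
         final = y[length(y)],
         max = max(y),
         mean_tail = {
           n <- length(y)
           from <- n - max(1, ceiling(0.2 * n)) + 1
           mean(y[from:n])
         })
}

#' Write a trajectory as CSV
#'
#' Header `time,<place_id>,...`, one row per grid point, full precision.
#'
#' @param traj a `pn_trajectory`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
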