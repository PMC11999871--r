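#' Quasistatic continuation along a control-parameter path
#'
#' Follows waypoints in (v, sigma), obtaining the state at waypoint k by
#' local relaxation initialized at the state of waypoint k-1 — history
#' dependence (and therefore hysteresis) arises by construction. When the
#' current basin of attraction has vanished, the relaxation falls into
#' another basin: the quasistatic snap-through event.
#'
#' @param waypoints data.frame with columns `v` and `sigma` (the intrinsic
#'   tension when a mechanosensitive `law` is given, otherwise sigma_c)
#' @param model an [organoid_model()]
#' @param law optional [mechano_law()]; its sigma field is replaced by the
#'   waypoint value at every step
#' @param init initial state: an `organoid_shape`, or one of `"best"`,
#'   `"open"`, `"closed"` (branch choice at waypoint 1)
#' @param snap_threshold per-step opening change that counts as a snap
#' @return object of class `crypt_trajectory`: data.frame with one row per
#'   waypoint (step, v, sigma, sigma_c, theta_c, theta_v, opening, h_c,
#'   r_c, p, energy); attribute `"events"` holds detected snap events
#' @export
continue_path <- function(waypoints, model = organoid_model(), law = NULL,
                          init = "best", snap_threshold = 0.2) {
  stopifnot(is.data.frame(waypoints),
            all(c("v", "sigma") %in% names(waypoints)),
            nrow(waypoints) >= 1)
  law_at <- function(s) if (is.null(law)) NULL else
    mechano_law(s, law$n, law$r0_ref)
  state <- if (is.character(init)) {
    if (!init %in% c("best", "open", "closed"))
      stop("unknown init keyword", call. = FALSE)
    equilibrium_shape(waypoints$v[1], waypoints$sigma[1],
                      law = law_at(waypoints$sigma[1]), model = model,
                      prefer = init)
  } else {
    stopifnot(inherits(init, "organoid_shape"))
    init
  }
  out <- NULL
  for (k in seq_len(nrow(waypoints))) {
    s <- waypoints$sigma[k]; v <- waypoints$v[k]
    state <- tryCatch(
      equilibrium_shape(v, s, init = state, law = law_at(s), model = model),
      error = function(e)
        stop(sprintf("infeasible waypoint %d (v=%.4g, sigma=%.4g): %s",
                     k, v, s, conditionMessage(e)), call. = FALSE))
    out <- rbind(out, data.frame(
      step = k, v = v, sigma = s,
      sigma_c = attr(state, "sigma_c"),
      theta_c = state$theta_c, theta_v = state$theta_v,
      opening = state$opening, h_c = state$h_c, r_c = state$r_c,
      p = attr(state, "pressure"),
      energy = attr(state, "energy")))
  }
  ev <- detect_snap(out$opening, snap_threshold)
  structure(out, events = ev, final_state = state,
            class = c("crypt_trajectory", "data.frame"))
}

#' Detect abrupt opening changes along a series
#'
#' @param series numeric vector of degree-of-opening values per step
#' @param threshold minimum per-step |change| that counts as a snap (> 0)
#' @return data.frame with columns `index` (position of the step's new
#'   value) and `delta` (signed change)
#' @export
detect_snap <- function(series, threshold = 0.2) {
  stopifnot(length(series) >= 2, threshold > 0)
  d <- diff(series)
  i <- which(abs(d) > threshold)
  data.frame(index = i + 1L, delta = d[i])
}

#' Forward/backward control sweep and hysteresis loop area
#'
#' Sweeps one control (`sigma` or `v`) from range[1] to range[2] and back,
#' continuing the state quasistatically, and integrates the area enclosed
#' between the forward and backward opening curves. The area is positive
#' exactly when the sweep crosses a bistable window.
#'
#' @param axis `"sigma"` or `"v"`
#' @param range length-2 numeric
#' @param steps number of steps per direction
#' @param v fixed volume (for sigma sweeps)
#' @param sigma fixed tension (for v sweeps)
#' @param model,law as in [continue_path()]
#' @param init initial branch at the first waypoint
#' @return list with `forward`, `backward` (crypt_trajectory) and `area`
#' @export
hysteresis_sweep <- function(axis = c("sigma", "v"), range, steps = 60,
                             v = NULL, sigma = NULL,
                             model = organoid_model(), law = NULL,
                             init = "best") {
  axis <- match.arg(axis)
  grid <- seq(range[1], range[2], length.out = steps)
  wp_f <- if (axis == "sigma")
    data.frame(v = v, sigma = grid) else data.frame(v = grid, sigma = sigma)
  wp_b <- wp_f[rev(seq_len(steps)), ]
  fw <- continue_path(wp_f, model, law, init = init)
  bw <- continue_path(wp_b, model, law, init = attr(fw, "final_state"))
  gap <- fw$opening - rev(bw$opening)
  area <- abs(sum((gap[-1] + gap[-steps]) / 2 * diff(grid)))
  list(forward = fw, backward = bw, area = area)
}

#' Waypoint schedules for the experimental scenarios
#'
#' `normal`: the lumen deflates from the swollen bulged state (v ~ 2.8) to
#' the budded state (v ~ 0.7) while the fate-set intrinsic tension ramps
#' up. `early_inflation`: the lumen is held inflated while the tension
#' ramps (PGE treatment of a developing bulged organoid).
#' `late_inflation`: normal development followed by lumen re-inflation of
#' the budded organoid. `blebbistatin_washout`: a budded organoid is
#' inflated while contractility is inhibited (sigma -> 0), then the
#' inhibitor is washed out (sigma restored) with the lumen kept swollen.
#'
#' @param name scenario name
#' @param sigma_final intrinsic tension reached by the fate ramp
#' @param sigma_start tension at the start of the ramp
#' @param v_high,v_low swollen and deflated normalized volumes
#' @param v_reinflate volume reached when a budded organoid is re-inflated
#'   (the experimental inflation ratio applied to the budded volume)
#' @param n_steps steps per phase
#' @return data.frame of waypoints (v, sigma)
#' @export
scenario_waypoints <- function(name = c("normal", "early_inflation",
                                        "late_inflation",
                                        "blebbistatin_washout"),
                               sigma_final = 0.03, sigma_start = 0.005,
                               v_high = 2.8, v_low = 0.7,
                               v_reinflate = 1.8, n_steps = 30) {
  name <- match.arg(name)
  ramp <- seq(sigma_start, sigma_final, length.out = n_steps)
  vdn <- seq(v_high, v_low, length.out = n_steps)
  vup <- seq(v_low, v_reinflate, length.out = n_steps)
  switch(name,
    normal = data.frame(v = vdn, sigma = ramp),
    early_inflation = data.frame(v = rep(v_high, n_steps), sigma = ramp),
    late_inflation = rbind(
      data.frame(v = vdn, sigma = ramp),
      data.frame(v = vup, sigma = rep(sigma_final, n_steps))),
    blebbistatin_washout = rbind(
      data.frame(v = vdn, sigma = ramp),                        # develop
      data.frame(v = vup,                                       # bleb + PGE
                 sigma = seq(sigma_final, 0, length.out = n_steps)),
      data.frame(v = rep(v_reinflate, n_steps),                 # washout
                 sigma = seq(0, sigma_final, length.out = n_steps)))
  )
}

#' Run a named experimental scenario
#'
#' Continues the organoid state along the scenario's waypoint schedule
#' (starting from the open/bulged branch, as organoids develop from a
#' spherical cyst) and reports the categorical outcome: `budded` (final
#' opening < 0.1), `bulged` (> 0.5), or `intermediate`.
#'
#' @param name scenario name, see [scenario_waypoints()]
#' @param model an [organoid_model()]
#' @param law a [mechano_law()]; the schedule drives its intrinsic sigma
#' @param init starting state; the default resolves the open branch at the
#'   first waypoint (pass a precomputed state to share it across scenarios)
#' @param ... passed to [scenario_waypoints()]
#' @return list with `trajectory` (crypt_trajectory), `outcome` and
#'   `final_opening`
#' @export
run_scenario <- function(name, model = organoid_model(),
                         law = mechano_law(0.03), init = "open", ...) {
  wp <- scenario_waypoints(name, sigma_final = law$sigma, ...)
  tr <- continue_path(wp, model, law = law, init = init)
  op <- tr$opening[nrow(tr)]
  outcome <- if (op < 0.1) "budded" else if (op > 0.5) "bulged" else
    "intermediate"
  list(trajectory = tr, outcome = outcome, final_opening = op)
}
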