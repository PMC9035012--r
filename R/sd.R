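#' Stochastic-dynamics run parameters
#'
#' Defaults follow the water-as-solvent parameterisation: a fully exposed
#' atom feels a friction of 91 ps^-1, scaled down linearly with the number
#' of non-hydrogen neighbours within 0.3 nm and vanishing at 6 or more
#' (buried atoms feel no solvent). Friction coefficients are refreshed every
#' 1 ps, the weak-coupling thermostat relaxes with tau_T = 0.1 ps, and the
#' centre-of-mass translation is removed every 2 ps.
#'
#' @param gamma_solv solvent friction at full exposure, ps^-1
#' @param neighbour_radius neighbour-count radius, nm
#' @param N_nbref neighbour count at which friction vanishes
#' @param friction_update_ps interval between friction refreshes, ps
#' @param dt integration time step, ps
#' @param T_ref reference temperature, K
#' @param tau_T weak-coupling relaxation time, ps
#' @param com_removal_ps interval between COM-translation removals, ps
#' @param seed RNG seed for the run (integer or NULL)
#' @param thermostat_group `"all"` scales every atom's velocity by the
#'   weak-coupling factor; `"zero-gamma"` scales only atoms whose friction
#'   is currently zero (the Langevin thermostat controls the rest)
#' @param count_bonded_neighbours include covalently bonded non-hydrogen
#'   atoms in the neighbour count (default TRUE)
#' @return object of class `"sd_params"`
#' @export
sd_params <- function(gamma_solv = 91, neighbour_radius = 0.3, N_nbref = 6,
                      friction_update_ps = 1, dt = 0.002, T_ref = 308,
                      tau_T = 0.1, com_removal_ps = 2, seed = NULL,
                      thermostat_group = c("all", "zero-gamma"),
                      count_bonded_neighbours = TRUE) {
  thermostat_group <- match.arg(thermostat_group)
  stopifnot(gamma_solv >= 0, neighbour_radius > 0, N_nbref > 0,
            dt > 0, tau_T > 0, dt < tau_T, T_ref > 0,
            friction_update_ps > 0, com_removal_ps > 0)
  structure(list(gamma_solv = gamma_solv,
                 neighbour_radius = neighbour_radius, N_nbref = N_nbref,
                 friction_update_ps = friction_update_ps, dt = dt,
                 T_ref = T_ref, tau_T = tau_T,
                 com_removal_ps = com_removal_ps, seed = seed,
                 thermostat_group = thermostat_group,
                 count_bonded_neighbours = count_bonded_neighbours),
            class = "sd_params")
}

#' Non-hydrogen neighbour counts
#'
#' For each atom, the number of non-hydrogen atoms (other than itself)
#' within the given radius. Covalently bonded atoms are counted by default
#' (they sit within the radius by construction; excluding them would make
#' every surface atom look fully exposed), controllably.
#'
#' @param xyz n x 3 coordinates (nm)
#' @param top topology
#' @param radius count radius in nm
#' @param count_bonded include covalently bonded atoms
#' @return integer vector of per-atom counts
#' @export
neighbour_counts <- function(xyz, top, radius = 0.3, count_bonded = TRUE) {
  xyz <- as_xyz(xyz)
  stopifnot(radius > 0)
  n <- nrow(xyz)
  heavy <- top$atoms$element != "H"
  d <- as.matrix(stats::dist(xyz))
  within <- d < radius
  diag(within) <- FALSE
  within[, !heavy] <- FALSE
  if (!count_bonded && nrow(top$bonds) > 0) {
    within[top$bonds] <- FALSE
    within[top$bonds[, c(2, 1), drop = FALSE]] <- FALSE
  }
  as.integer(rowSums(within))
}

#' Exposure-scaled atomic friction coefficients
#'
#' `gamma_i = gamma_solv * max(0, 1 - N_i / N_nbref)`: full solvent friction
#' for an exposed atom, zero for a buried one.
#'
#' @param counts per-atom neighbour counts
#' @param params [sd_params()]
#' @return per-atom friction coefficients, ps^-1
#' @export
friction_coefficients <- function(counts, params = sd_params()) {
  stopifnot(all(counts >= 0))
  params$gamma_solv * pmax(0, 1 - counts / params$N_nbref)
}

#' Maxwell-distributed initial velocities
#'
#' @param masses per-atom masses (u)
#' @param T_init temperature (K)
#' @return n x 3 velocity matrix (nm/ps)
#' @export
maxwell_velocities <- function(masses, T_init) {
  n <- length(masses)
  sd <- sqrt(KB * T_init / masses)
  matrix(stats::rnorm(3 * n), n, 3) * sd
}

#' One leap-frog stochastic-dynamics step
#'
#' Langevin leap-frog with an exact Ornstein-Uhlenbeck treatment of
#' friction and noise: the half-step velocity receives a deterministic half
#' kick, is relaxed by `exp(-gamma dt)` with a Gaussian kick of variance
#' `(kB T_ref / m)(1 - exp(-2 gamma dt))`, receives the second half kick,
#' and the position advances a full step. At `gamma = 0` this reduces
#' exactly to plain (energy-conserving) leap-frog, and buried atoms receive
#' exactly zero stochastic kicks.
#'
#' @param state list with `x` (n x 3 positions, nm) and `v` (n x 3
#'   half-step velocities, nm/ps)
#' @param forces n x 3 forces at the current positions (kJ mol^-1 nm^-1)
#' @param masses per-atom masses (u)
#' @param gamma per-atom friction coefficients (ps^-1)
#' @param params [sd_params()] supplying dt and T_ref
#' @param noise set FALSE to switch the stochastic kicks off (deterministic
#'   damped dynamics; used in tests)
#' @return updated state list
#' @export
sd_step <- function(state, forces, masses, gamma, params, noise = TRUE) {
  if (!all(is.finite(forces)))
    stop("non-finite force encountered; state: ",
         paste(utils::capture.output(utils::str(state$x[1:min(3, nrow(state$x)), ])),
               collapse = " "))
  dt <- params$dt
  a <- forces / masses
  v <- state$v + a * (dt / 2)
  c1 <- exp(-gamma * dt)
  if (noise) {
    sdv <- sqrt(KB * params$T_ref / masses * (1 - c1^2))
    n <- nrow(state$x)
    v <- c1 * v + sdv * matrix(stats::rnorm(3 * n), n, 3)
  } else {
    v <- c1 * v
  }
  v <- v + a * (dt / 2)
  list(x = state$x + v * dt, v = v)
}

#' SHAKE bond-length constraints
#'
#' Iteratively corrects post-step positions so that every constrained
#' distance matches its target to a relative tolerance, applying
#' mass-weighted displacements along the reference (pre-step) bond
#' directions.
#'
#' @param x_ref n x 3 positions before the step (reference geometry)
#' @param x_new n x 3 positions after the unconstrained step
#' @param constraints data.frame(i, j, length_nm)
#' @param masses per-atom masses (u)
#' @param tol relative geometric precision (default 1e-4)
#' @param max_iter iteration cap
#' @return corrected n x 3 position matrix
#' @export
shake <- function(x_ref, x_new, constraints, masses, tol = 1e-4,
                  max_iter = 1000) {
  if (nrow(constraints) == 0) return(x_new)
  ci <- constraints$i; cj <- constraints$j; d0 <- constraints$length_nm
  rref <- x_ref[ci, , drop = FALSE] - x_ref[cj, , drop = FALSE]
  invm <- 1 / masses
  for (iter in seq_len(max_iter)) {
    r <- x_new[ci, , drop = FALSE] - x_new[cj, , drop = FALSE]
    r2 <- rowSums(r^2)
    viol <- abs(sqrt(r2) - d0) / d0
    if (all(viol <= tol)) return(x_new)
    for (c_idx in order(viol, decreasing = TRUE)) {
      if (viol[c_idx] <= tol) next
      i <- ci[c_idx]; j <- cj[c_idx]
      rc <- x_new[i, ] - x_new[j, ]
      diff2 <- sum(rc^2) - d0[c_idx]^2
      denom <- 2 * sum(rc * rref[c_idx, ]) * (invm[i] + invm[j])
      if (abs(denom) < 1e-12)
        stop("SHAKE: degenerate reference geometry for constraint ",
             i, "-", j)
      g <- diff2 / denom
      x_new[i, ] <- x_new[i, ] - g * invm[i] * rref[c_idx, ]
      x_new[j, ] <- x_new[j, ] + g * invm[j] * rref[c_idx, ]
    }
  }
  r <- x_new[ci, , drop = FALSE] - x_new[cj, , drop = FALSE]
  viol <- abs(sqrt(rowSums(r^2)) - d0) / d0
  w <- which.max(viol)
  stop(sprintf(
    "SHAKE did not converge in %d iterations; worst constraint %d-%d, relative violation %.3g",
    max_iter, ci[w], cj[w], viol[w]))
}

#' Weak-coupling velocity scale factor
#'
#' `lambda = sqrt(1 + (dt/tau_T)(T_ref/T - 1))`: first-order relaxation of
#' the instantaneous temperature towards the reference.
#'
#' @param current_T instantaneous temperature (K), > 0
#' @param params [sd_params()] (or a list with dt, tau_T, T_ref)
#' @return scalar velocity scaling factor
#' @export
weak_coupling_scale <- function(current_T, params = sd_params()) {
  stopifnot(current_T > 0)
  sqrt(1 + (params$dt / params$tau_T) * (params$T_ref / current_T - 1))
}

#' Instantaneous kinetic temperature
#'
#' @param v n x 3 velocities (nm/ps)
#' @param masses per-atom masses (u)
#' @param ndof degrees of freedom (default 3n minus the number of
#'   constraints if given)
#' @param n_constraints number of holonomic constraints to subtract
#' @return temperature in K
#' @export
kinetic_temperature <- function(v, masses, ndof = NULL, n_constraints = 0) {
  if (is.null(ndof)) ndof <- 3 * length(masses) - n_constraints
  ekin <- 0.5 * sum(masses * rowSums(v^2))
  2 * ekin / (ndof * KB)
}

#' Run a stochastic-dynamics simulation
#'
#' Orchestrates the leap-frog SD integrator over a system: force evaluation
#' (toy force field and/or position restraints), exposure-dependent friction
#' refreshed at its update interval, SHAKE constraints, weak-coupling
#' temperature control, periodic COM-translation removal, and frame/energy
#' storage. Deterministic given `params$seed`.
#'
#' @param system list with `top` (topology), `xyz` (initial n x 3
#'   coordinates), optional `ff` ([toy_forcefield()]), optional `restraints`
#'   = list(ref = n x 3, k = force constant kJ mol^-1 nm^-2), optional `v`
#'   (initial velocities; Maxwell-drawn at T_ref when absent)
#' @param params [sd_params()]
#' @param n_steps number of integration steps (>= 0)
#' @param store_every_ps frame storage interval in ps
#' @param noise switch stochastic kicks off (tests)
#' @param thermostat apply the weak-coupling thermostat (default TRUE)
#' @return a [trajectory()] whose metadata carries the per-frame energy log
#'   (`energy_log`: time, per-term energies, kinetic, temperature), the
#'   final state and the run parameters
#' @export
run_sd <- function(system, params = sd_params(), n_steps,
                   store_every_ps = 5, noise = TRUE, thermostat = TRUE) {
  stopifnot(n_steps >= 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  top <- system$top
  x <- as_xyz(system$xyz)
  m <- top$atoms$mass
  ncon <- nrow(top$constraints)
  ndof <- max(1, 3 * nrow(x) - ncon)
  v <- if (!is.null(system$v)) system$v else maxwell_velocities(m, params$T_ref)

  eval_forces <- function(x) {
    if (!is.null(system$ff)) {
      fe <- ff_eval(x, system$ff, top)
    } else {
      fe <- list(terms = c(bond = 0), energy = 0,
                 forces = matrix(0, nrow(x), 3))
    }
    if (!is.null(system$restraints)) {
      dr <- x - system$restraints$ref
      fe$terms <- c(fe$terms, restraint = 0.5 * system$restraints$k * sum(dr^2))
      fe$forces <- fe$forces - system$restraints$k * dr
      fe$energy <- sum(fe$terms)
    }
    fe
  }

  upd_every <- max(1, round(params$friction_update_ps / params$dt))
  com_every <- max(1, round(params$com_removal_ps / params$dt))
  store_every <- max(1, round(store_every_ps / params$dt))

  gamma <- friction_coefficients(
    neighbour_counts(x, top, params$neighbour_radius,
                     params$count_bonded_neighbours), params)

  frames <- list(x)
  times <- 0
  log_rows <- list()
  fe <- eval_forces(x)
  log_rows[[1]] <- c(time = 0, fe$terms,
                     kinetic = 0.5 * sum(m * rowSums(v^2)),
                     temperature = kinetic_temperature(v, m, ndof))

  for (step in seq_len(n_steps)) {
    if (step %% upd_every == 0)
      gamma <- friction_coefficients(
        neighbour_counts(x, top, params$neighbour_radius,
                         params$count_bonded_neighbours), params)
    st <- sd_step(list(x = x, v = v), fe$forces, m, gamma, params,
                  noise = noise)
    if (ncon > 0) {
      xs <- shake(x, st$x, top$constraints, m)
      st$v <- st$v + (xs - st$x) / params$dt
      st$x <- xs
    }
    if (thermostat) {
      Tcur <- kinetic_temperature(st$v, m, ndof)
      if (Tcur > 0) {
        lam <- weak_coupling_scale(Tcur, params)
        if (params$thermostat_group == "zero-gamma") {
          sel <- gamma == 0
          st$v[sel, ] <- st$v[sel, ] * lam
        } else {
          st$v <- st$v * lam
        }
      }
    }
    if (step %% com_every == 0) {
      vcm <- colSums(st$v * m) / sum(m)
      st$v <- sweep(st$v, 2, vcm)
    }
    x <- st$x; v <- st$v
    if (step %% store_every == 0) {
      fe_now <- eval_forces(x)
      frames[[length(frames) + 1]] <- x
      times <- c(times, step * params$dt)
      log_rows[[length(log_rows) + 1]] <-
        c(time = step * params$dt, fe_now$terms,
          kinetic = 0.5 * sum(m * rowSums(v^2)),
          temperature = kinetic_temperature(v, m, ndof))
    }
    fe <- eval_forces(x)
  }

  elog <- as.data.frame(do.call(rbind, log_rows))
  trajectory(frames, times,
             metadata = list(energy_log = elog, params = params,
                             seed = params$seed,
                             final_state = list(x = x, v = v, gamma = gamma)))
}

#' Default staged heat-up schedule
#'
#' Five stages at 60, 120, 180, 240 and 308 K; the first four carry
#' harmonic position restraints to the reference structure with force
#' constants 25000, 2500, 250 and 25 kJ mol^-1 nm^-2, the final stage is
#' unrestrained.
#'
#' @param stage_ps duration of each stage in ps (default 20)
#' @return data.frame(T_ref, duration_ps, restraint_k)
#' @export
default_heatup_schedule <- function(stage_ps = 20) {
  data.frame(T_ref = c(60, 120, 180, 240, 308),
             duration_ps = stage_ps,
             restraint_k = c(25000, 2500, 250, 25, NA))
}

#' Staged heat-up equilibration
#'
#' Runs consecutive SD stages with decreasing positional restraints to the
#' initial reference structure; velocities are Maxwell-drawn at the first
#' stage's temperature and carried across stages. A zero-stage schedule is
#' a no-op returning an empty trajectory.
#'
#' @param system as for [run_sd()]
#' @param schedule data.frame(T_ref, duration_ps, restraint_k) — NA
#'   restraint_k means unrestrained
#' @param params [sd_params()]; T_ref is overridden per stage
#' @param store_every_ps frame storage interval
#' @return a [trajectory()] concatenated over stages
#' @export
heatup_protocol <- function(system, schedule = default_heatup_schedule(),
                            params = sd_params(), store_every_ps = 5) {
  if (nrow(schedule) == 0)
    return(trajectory(list(), numeric(0), metadata = list(stages = 0)))
  if (!is.null(params$seed)) set.seed(params$seed)
  ref <- as_xyz(system$xyz)
  m <- system$top$atoms$mass
  v <- maxwell_velocities(m, schedule$T_ref[1])
  frames <- list(); times <- numeric(0); logs <- list()
  t0 <- 0
  pstage <- params
  pstage$seed <- NULL  # one seed for the whole protocol, set above
  for (s in seq_len(nrow(schedule))) {
    pstage$T_ref <- schedule$T_ref[s]
    sys_s <- system
    sys_s$v <- v
    sys_s$restraints <- if (is.na(schedule$restraint_k[s])) NULL else
      list(ref = ref, k = schedule$restraint_k[s])
    n_steps <- round(schedule$duration_ps[s] / params$dt)
    tr <- run_sd(sys_s, pstage, n_steps, store_every_ps = store_every_ps)
    fs <- tr$metadata$final_state
    system$xyz <- fs$x
    v <- fs$v
    keep <- if (s == 1) seq_along(tr$frames) else -1
    frames <- c(frames, tr$frames[keep])
    times <- c(times, t0 + tr$times[keep])
    el <- tr$metadata$energy_log
    el$time <- el$time + t0
    el$stage <- s
    logs[[s]] <- el
    t0 <- t0 + schedule$duration_ps[s]
  }
  cols <- Reduce(union, lapply(logs, names))
  logs <- lapply(logs, function(el) {
    for (cc in setdiff(cols, names(el))) el[[cc]] <- NA
    el[cols]
  })
  trajectory(frames, times,
             metadata = list(energy_log = do.call(rbind, logs),
                             schedule = schedule, params = params,
                             final_state = list(x = system$xyz, v = v)))
}
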