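#' Construct a general load case
#'
#' A load case bundles nodal point forces (N), nodal moments (N mm) and a
#' restraint set. Restraints are given as a named list mapping node labels
#' to logical vectors of length 6 (`ux, uy, uz, rx, ry, rz`; `TRUE` =
#' fixed); `TRUE` alone fully fixes the node.
#'
#' @param name Case label.
#' @param forces Data frame with columns `node`, `fx`, `fy`, `fz`, or NULL.
#' @param moments Data frame with columns `node`, `mx`, `my`, `mz`, or NULL.
#' @param restraints Named list of restraint masks (see above).
#' @return An object of class `load_case`.
#' @export
load_case <- function(name, forces = NULL, moments = NULL,
                      restraints = list()) {
  if (!length(restraints))
    stop("a load case needs at least one restrained node", call. = FALSE)
  restraints <- lapply(restraints, function(r) {
    if (isTRUE(r)) r <- rep(TRUE, 6L)
    if (!is.logical(r) || length(r) != 6L)
      stop("each restraint must be TRUE or a logical vector of length 6",
           call. = FALSE)
    r
  })
  chk <- function(d, cols) {
    if (is.null(d)) return(NULL)
    if (!all(cols %in% names(d)))
      stop("need columns: ", paste(cols, collapse = ", "), call. = FALSE)
    d
  }
  structure(list(name = name,
                 forces = chk(forces, c("node", "fx", "fy", "fz")),
                 moments = chk(moments, c("node", "mx", "my", "mz")),
                 restraints = restraints),
            class = "load_case")
}

# global load vector (6 DOF per node) for a load case
load_vector <- function(loads, node_ids) {
  F <- numeric(6L * length(node_ids))
  add <- function(d, off) {
    for (i in seq_len(nrow(d))) {
      j <- match(d$node[i], node_ids)
      if (is.na(j)) stop("load on unknown node: ", d$node[i], call. = FALSE)
      F[(j - 1L) * 6L + off] <<- F[(j - 1L) * 6L + off] +
        as.numeric(d[i, -match("node", names(d))])
    }
  }
  if (!is.null(loads$forces)) add(loads$forces[, c("node", "fx", "fy", "fz")], 1:3)
  if (!is.null(loads$moments)) add(loads$moments[, c("node", "mx", "my", "mz")], 4:6)
  F
}

# logical mask over global DOFs marking restrained ones
restraint_mask <- function(loads, node_ids) {
  fixed <- logical(6L * length(node_ids))
  for (nm in names(loads$restraints)) {
    j <- match(nm, node_ids)
    if (is.na(j)) stop("restraint on unknown node: ", nm, call. = FALSE)
    fixed[(j - 1L) * 6L + 1:6] <- fixed[(j - 1L) * 6L + 1:6] |
      loads$restraints[[nm]]
  }
  fixed
}

#' Canonical mandible load cases: bite, shake, twist
#'
#' Builds the three feeding load cases for a 'Y' mandible frame. Both
#' posterior nodes are always fully restrained (all translations and
#' rotations). At the anterior tip:
#' \describe{
#'   \item{bite}{a force along -Y (dorso-ventral, out of the frame plane),
#'     the direction of jaw adduction;}
#'   \item{shake}{a force along +X (transverse, in the frame plane), the
#'     direction of lateral head shaking;}
#'   \item{twist}{a moment about +Z (the longitudinal axis), the long-axis
#'     rolling load.}
#' }
#' Default magnitude is 1 (N for bite/shake, N mm for twist): the analyses
#' are linear and comparative, so magnitudes rescale results without
#' changing slopes, likelihoods or rankings.
#'
#' @param kind One of `"bite"`, `"shake"`, `"twist"`.
#' @param model A mandible `frame_model` (needs nodes `anterior_tip`,
#'   `posterior_left`, `posterior_right`).
#' @param magnitude Load magnitude (N or N mm).
#' @return A `load_case`.
#' @examples
#' m <- linear_measurements("x", 4, 1.5, 30, 1.34)
#' make_load_case("shake", build_beam_frame(m))
#' @export
make_load_case <- function(kind, model, magnitude = 1) {
  kind <- match.arg(kind, c("bite", "shake", "twist"))
  need <- c("anterior_tip", "posterior_left", "posterior_right")
  if (!all(need %in% rownames(model$nodes)))
    stop("model lacks the mandible frame nodes: ",
         paste(setdiff(need, rownames(model$nodes)), collapse = ", "),
         call. = FALSE)
  if (!is.finite(magnitude))
    stop("magnitude must be finite", call. = FALSE)
  restr <- list(posterior_left = TRUE, posterior_right = TRUE)
  switch(kind,
    bite = load_case("bite",
      forces = data.frame(node = "anterior_tip", fx = 0, fy = -magnitude,
                          fz = 0),
      restraints = restr),
    shake = load_case("shake",
      forces = data.frame(node = "anterior_tip", fx = magnitude, fy = 0,
                          fz = 0),
      restraints = restr),
    twist = load_case("twist",
      moments = data.frame(node = "anterior_tip", mx = 0, my = 0,
                           mz = magnitude),
      restraints = restr)
  )
}

#' Peak force on the skull from harmonic prey shaking
#'
#' The head (with prey of mass `m` gripped at the jaw tips) oscillates
#' harmonically about a vertical axis: \eqn{\theta(t) = \theta_0
#' \sin(2\pi f t)}, so the peak angular acceleration is
#' \eqn{\alpha_{max} = \theta_0 (2\pi f)^2}, the peak linear acceleration
#' at outlever `r` is \eqn{a = \alpha_{max} r}, and the peak transverse
#' force is \eqn{F = m a}.
#'
#' @param prey_mass Prey mass m (kg); conventionally three times skull mass.
#' @param frequency Shake frequency f (Hz; full cycles per second).
#' @param amplitude Angular amplitude of the sweep (radians, one-sided).
#'   No published default exists, so it must be supplied explicitly
#'   (directly or via the physics config); it is never defaulted silently.
#' @param outlever Distance r from the axis of rotation to the prey's
#'   centre of mass (m).
#' @return List with `alpha_max` (rad/s^2), `acceleration` (m/s^2) and
#'   `force` (N).
#' @examples
#' shake_force(prey_mass = 2.55, frequency = 4, amplitude = 0.5,
#'             outlever = 0.297)
#' @export
shake_force <- function(prey_mass, frequency = 4, amplitude = NULL,
                        outlever) {
  if (is.null(amplitude) || !is.finite(amplitude))
    stop("shake amplitude (radians) is unconfigured: supply `amplitude` ",
         "explicitly; there is no silent default", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (prey_mass <= 0 || frequency <= 0 || outlever <= 0)
    stop("prey_mass, frequency and outlever must be positive", call. = FALSE)
  alpha <- amplitude * (2 * pi * frequency)^2
  a <- alpha * outlever
  list(alpha_max = alpha, acceleration = a, force = prey_mass * a)
}

#' Torque from a long-axis twist ('death roll') from standing start
#'
#' The body (modelled as a point mass `body_mass` at radius `radius` from
#' the roll axis, i.e. moment of inertia \eqn{I = m r^2}) rotates through
#' angle `rotation` in time `duration` under constant angular acceleration
#' from rest, so \eqn{\alpha = 2\theta / t^2} and the torque transmitted
#' through the gripped prey is \eqn{T = m r^2 \alpha}.
#'
#' @param body_mass Rolling mass m (kg); conventionally fifty times skull
#'   mass.
#' @param radius Effective radius r (m); conventionally skull width.
#' @param rotation Angular displacement (radians; default one full
#'   rotation, `2*pi`).
#' @param duration Time t to complete the rotation (s; default 0.5, i.e.
#'   two full rotations per second).
#' @return List with `alpha` (rad/s^2), `inertia` (kg m^2) and `torque`
#'   (N m).
#' @examples
#' twist_torque(body_mass = 40, radius = 0.152)
#' @export
twist_torque <- function(body_mass, radius, rotation = 2 * pi,
                         duration = 0.5) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (body_mass <= 0 || radius <= 0)
    stop("body_mass and radius must be positive", call. = FALSE)
  if (rotation < 0) stop("rotation must be >= 0", call. = FALSE)
  alpha <- 2 * rotation / duration^2
  inertia <- body_mass * radius^2
  list(alpha = alpha, inertia = inertia, torque = inertia * alpha)
}

#' Dry-skull muscle group force and per-truss pretension
#'
#' Estimates a jaw adductor group's force as its cross-sectional area times
#' muscle specific tension, and divides it evenly over the truss elements
#' representing the group in a structural model.
#'
#' @param csa Cross-sectional area of the group (mm^2), from the
#'   osteological boundaries of the adductor chamber.
#' @param n_trusses Number of truss elements representing the group (the
#'   packaged muscle table totals 138 temporal and 160 pterygoid trusses).
#' @param specific_tension Muscle specific tension (MPa; default 0.3, i.e.
#'   300 kPa).
#' @return List with `force` (N) and `pretension` (N per truss).
#' @examples
#' muscle_group_force(csa = 100, n_trusses = 138)
#' @export
muscle_group_force <- function(csa, n_trusses, specific_tension = 0.3) {
  if (!is.finite(csa) || csa <= 0)
    stop("cross-sectional area must be positive", call. = FALSE)
  if (!is.finite(n_trusses) || n_trusses < 1)
    stop("n_trusses must be >= 1", call. = FALSE)
  if (specific_tension <= 0)
    stop("specific_tension must be positive", call. = FALSE)
  f <- csa * specific_tension
  list(force = f, pretension = f / n_trusses)
}

#' Scale a muscle force for a change in model volume
#'
#' Muscle force scales with cross-sectional area, i.e. the 2/3 power of the
#' volume change when a model is rescaled to a reference volume.
#'
#' @param force Force at natural size (N).
#' @param volume_ratio Rescaled volume over natural volume (dimensionless).
#' @return Scaled force (N); vectorized.
#' @examples
#' volume_scale_force(10, 8)  # 40
#' @export
volume_scale_force <- function(force, volume_ratio) {
  if (any(!is.finite(volume_ratio) | volume_ratio <= 0))
    stop("volume_ratio must be positive", call. = FALSE)
  force * volume_ratio^(2 / 3)
}

#' 'Tooth equals tooth' load scale factor
#'
#' Factor by which all muscle pretensions of a linear model must be
#' multiplied so its resultant bite force equals a reference model's bite
#' force at the same bite point. By linearity of the solve, applying the
#' factor scales the model's bite force to the reference exactly.
#'
#' @param bite_force_model Model's bite force (N).
#' @param bite_force_reference Reference bite force (N).
#' @return Dimensionless scale factor.
#' @examples
#' tet_scale_factor(500, 1000)  # 2
#' @export
tet_scale_factor <- function(bite_force_model, bite_force_reference) {
  if (!is.finite(bite_force_model) || bite_force_model <= 0)
    stop("model bite force must be positive", call. = FALSE)
  if (!is.finite(bite_force_reference) || bite_force_reference <= 0)
    stop("reference bite force must be positive", call. = FALSE)
  bite_force_reference / bite_force_model
}

#' Read a physics configuration (YAML or JSON)
#'
#' Expected structure (all entries optional except where noted):
#' ```yaml
#' shake: {frequency_hz: 4, amplitude_rad: 0.5, prey_mass_multiplier: 3}
#' twist: {rotation_rad: 6.2832, duration_s: 0.5, body_mass_multiplier: 50}
#' muscle: {specific_tension_mpa: 0.3}
#' ```
#' The shake amplitude has no published value; [shake_force()] refuses to
#' run without it, so configs intended for shake-magnitude calculations
#' must set `shake.amplitude_rad`.
#'
#' @param path Path to a YAML (or JSON) file; `NULL` returns the defaults.
#' @return Nested list with `shake`, `twist`, `muscle` entries.
#' @export
read_physics_config <- function(path = NULL) {
  defaults <- list(
    shake = list(frequency_hz = 4, amplitude_rad = NULL,
                 prey_mass_multiplier = 3),
    twist = list(rotation_rad = 2 * pi, duration_s = 0.5,
                 body_mass_multiplier = 50),
    muscle = list(specific_tension_mpa = 0.3)
  )
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (sec in names(defaults)) {
    if (!is.null(cfg[[sec]])) {
      for (k in names(cfg[[sec]])) defaults[[sec]][[k]] <- cfg[[sec]][[k]]
    }
  }
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra))
    warning("ignoring unknown physics config sections: ",
            paste(extra, collapse = ", "), call. = FALSE)
  defaults
}
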