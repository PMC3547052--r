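# Linear-elastic 3D space-frame solver: 12-DOF Euler-Bernoulli elements,
# dense direct solve (models here have at most a few dozen DOF).

# Local axes for an element: local x along the element; local y chosen in
# the global XZ plane where possible (so in-plane bending maps to one local
# axis for the planar mandible frames), otherwise derived from global Z.
element_axes <- function(p1, p2) {
  ex <- p2 - p1
  len <- sqrt(sum(ex^2))
  ex <- ex / len
  if (abs(ex[2]) < 1 - 1e-9) {
    ey <- c(ex[3], 0, -ex[1])         # global Y x ex: lies in the XZ plane
  } else {
    ey <- c(-ex[2], ex[1], 0)         # global Z x ex, for vertical elements
  }
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  rbind(ex, ey, ez)
}

# 12x12 local stiffness for a prismatic circular Euler-Bernoulli element.
# DOF order per node: ux uy uz rx ry rz (local), node 1 then node 2.
element_stiffness_local <- function(E, G, A, I, J, L) {
  k <- matrix(0, 12, 12)
  ea <- E * A / L
  gj <- G * J / L
  b1 <- 12 * E * I / L^3
  b2 <- 6 * E * I / L^2
  b3 <- 4 * E * I / L
  b4 <- 2 * E * I / L
  k[1, 1] <- k[7, 7] <- ea; k[1, 7] <- k[7, 1] <- -ea
  k[4, 4] <- k[10, 10] <- gj; k[4, 10] <- k[10, 4] <- -gj
  # bending in local x-y plane (rotations about local z): DOFs 2,6,8,12
  k[2, 2] <- k[8, 8] <- b1; k[2, 8] <- k[8, 2] <- -b1
  k[2, 6] <- k[6, 2] <- k[2, 12] <- k[12, 2] <- b2
  k[6, 8] <- k[8, 6] <- k[8, 12] <- k[12, 8] <- -b2
  k[6, 6] <- k[12, 12] <- b3; k[6, 12] <- k[12, 6] <- b4
  # bending in local x-z plane (rotations about local y): DOFs 3,5,9,11
  k[3, 3] <- k[9, 9] <- b1; k[3, 9] <- k[9, 3] <- -b1
  k[3, 5] <- k[5, 3] <- k[3, 11] <- k[11, 3] <- -b2
  k[5, 9] <- k[9, 5] <- k[9, 11] <- k[11, 9] <- b2
  k[5, 5] <- k[11, 11] <- b3; k[5, 11] <- k[11, 5] <- b4
  k
}

dof_names <- c("ux", "uy", "uz", "rx", "ry", "rz")

# Expand node/DOF bookkeeping: global DOF index for node i, dof j
dof_index <- function(node_ids, node, dof) (match(node, node_ids) - 1L) * 6L + dof

#' Solve a space frame under a load case
#'
#' Assembles the global stiffness matrix from 12-DOF Euler-Bernoulli
#' elements (axial, torsion, and bending without shear deformation -- the
#' mandible beams are slender), applies the restraints, and solves the
#' reduced linear system directly. Element end forces are recovered in
#' element-local axes and reactions at restrained DOFs are reported.
#'
#' @param model A [frame_model()].
#' @param loads A [load_case()] (see also [make_load_case()]).
#' @return An object of class `frame_solution`: list with
#'   \describe{
#'     \item{displacements}{n x 6 matrix (ux, uy, uz, rx, ry, rz per node).}
#'     \item{end_forces}{data frame of per-element local end forces: axial
#'       `N`, shears `Vy`, `Vz`, torque `T`, bending moments `My`, `Mz`,
#'       at ends 1 and 2.}
#'     \item{reactions}{n x 6 matrix of reaction forces/moments (zero at
#'       unrestrained DOFs).}
#'     \item{residual}{global equilibrium residual (max |sum of applied +
#'       reaction forces and moments| relative to the load magnitude).}
#'   }
#' @export
solve_frame <- function(model, loads) {
  stopifnot(inherits(model, "frame_model"), inherits(loads, "load_case"))
  nd <- model$nodes
  node_ids <- rownames(nd)
  ndof <- 6L * nrow(nd)

  K <- matrix(0, ndof, ndof)
  el <- model$elements
  rot <- vector("list", nrow(el))
  kloc <- vector("list", nrow(el))
  idx <- vector("list", nrow(el))
  for (i in seq_len(nrow(el))) {
    p1 <- nd[el$from[i], ]; p2 <- nd[el$to[i], ]
    R <- element_axes(p1, p2)
    sec <- circular_section_properties(el$diameter[i])
    k <- element_stiffness_local(el$E[i], el$G[i], sec$area, sec$I, sec$J,
                                 el$length[i])
    Tm <- matrix(0, 12, 12)
    for (b in 0:3) Tm[b * 3 + 1:3, b * 3 + 1:3] <- R
    ix <- c(dof_index(node_ids, el$from[i], 1:6),
            dof_index(node_ids, el$to[i], 1:6))
    K[ix, ix] <- K[ix, ix] + t(Tm) %*% k %*% Tm
    rot[[i]] <- Tm; kloc[[i]] <- k; idx[[i]] <- ix
  }

  F <- load_vector(loads, node_ids)
  fixed <- restraint_mask(loads, node_ids)
  if (sum(fixed) < 6L)
    stop("under-restrained frame: at least 6 restrained DOFs are needed ",
         "to suppress rigid-body motion", call. = FALSE)
  free <- !fixed

  Kff <- K[free, free, drop = FALSE]
  ev <- eigen(Kff, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    mode <- eigen(Kff, symmetric = TRUE)$vectors[, which.min(ev)]
    worst <- which.max(abs(mode))
    gdof <- which(free)[worst]
    stop(sprintf(
      "rigid-body mode detected: frame is free to move in DOF %s of node %s",
      dof_names[(gdof - 1L) %% 6L + 1L], node_ids[(gdof - 1L) %/% 6L + 1L]),
      call. = FALSE)
  }

  u <- numeric(ndof)
  u[free] <- solve(Kff, F[free])
  reactions <- as.vector(K %*% u) - F
  reactions[free] <- 0

  ef <- data.frame(element = el$label,
                   N1 = 0, Vy1 = 0, Vz1 = 0, T1 = 0, My1 = 0, Mz1 = 0,
                   N2 = 0, Vy2 = 0, Vz2 = 0, T2 = 0, My2 = 0, Mz2 = 0,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(el))) {
    f <- as.vector(kloc[[i]] %*% (rot[[i]] %*% u[idx[[i]]]))
    ef[i, 2:13] <- f[c(1:6, 7:12)]
  }

  load_mag <- max(abs(F), 1e-300)
  total <- equilibrium_residual(nd, F, reactions)
  structure(
    list(displacements = matrix(u, ncol = 6, byrow = TRUE,
                                dimnames = list(node_ids, dof_names)),
         end_forces = ef,
         reactions = matrix(reactions, ncol = 6, byrow = TRUE,
                            dimnames = list(node_ids, dof_names)),
         residual = total / load_mag),
    class = "frame_solution"
  )
}

# max |sum forces|, |sum moments about origin| over applied + reactions
equilibrium_residual <- function(nodes, F, reactions) {
  tot <- F + reactions
  force_sum <- c(0, 0, 0); moment_sum <- c(0, 0, 0)
  for (i in seq_len(nrow(nodes))) {
    f <- tot[(i - 1L) * 6L + 1:3]
    m <- tot[(i - 1L) * 6L + 4:6]
    r <- nodes[i, ]
    force_sum <- force_sum + f
    moment_sum <- moment_sum + m +
      c(r[2] * f[3] - r[3] * f[2],
        r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
  }
  max(abs(c(force_sum, moment_sum)))
}

#' Maximum fibre stress and peak strain of a solved frame
#'
#' Fibre stress is the extreme-fibre normal stress from axial force plus
#' resultant bending, evaluated at both ends of every element (moments vary
#' linearly under end loads, so interior maxima cannot occur):
#' \deqn{\sigma = |N| / A + \sqrt{M_y^2 + M_z^2} \, (d/2) / I.}
#' Torsion produces shear, not fibre stress; an optional von-Mises-style
#' combined measure that folds in torsional and transverse shear is
#' reported alongside, but headline statistics use fibre stress only.
#' Strain is \eqn{\varepsilon = \sigma / E} per element.
#'
#' @param sol A `frame_solution` from [solve_frame()].
#' @param model The `frame_model` that produced it.
#' @return An object of class `stress_result`: list with `elements` (data
#'   frame: element, end-wise fibre stress, element maximum `sigma_mpa`,
#'   `strain`, `von_mises_mpa`), `peak_stress_mpa`, `peak_strain`,
#'   `element_of_peak`.
#' @export
max_fibre_stress <- function(sol, model) {
  stopifnot(inherits(sol, "frame_solution"), inherits(model, "frame_model"))
  el <- model$elements
  ef <- sol$end_forces
  out <- data.frame(element = el$label, sigma1_mpa = NA_real_,
                    sigma2_mpa = NA_real_, sigma_mpa = NA_real_,
                    strain = NA_real_, von_mises_mpa = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(el))) {
    sec <- circular_section_properties(el$diameter[i])
    c_over_I <- (el$diameter[i] / 2) / sec$I
    s1 <- abs(ef$N1[i]) / sec$area +
      sqrt(ef$My1[i]^2 + ef$Mz1[i]^2) * c_over_I
    s2 <- abs(ef$N2[i]) / sec$area +
      sqrt(ef$My2[i]^2 + ef$Mz2[i]^2) * c_over_I
    # shear from torsion (tau = T r / J) and transverse forces (4V/3A max)
    tau <- max(abs(ef$T1[i]), abs(ef$T2[i])) * (el$diameter[i] / 2) / sec$J +
      max(sqrt(ef$Vy1[i]^2 + ef$Vz1[i]^2),
          sqrt(ef$Vy2[i]^2 + ef$Vz2[i]^2)) * 4 / (3 * sec$area)
    sig <- max(s1, s2)
    out$sigma1_mpa[i] <- s1
    out$sigma2_mpa[i] <- s2
    out$sigma_mpa[i] <- sig
    out$strain[i] <- sig / el$E[i]
    out$von_mises_mpa[i] <- sqrt(sig^2 + 3 * tau^2)
  }
  peak <- which.max(out$sigma_mpa)
  structure(
    list(elements = out,
         peak_stress_mpa = out$sigma_mpa[peak],
         peak_strain = out$strain[peak],
         element_of_peak = out$element[peak]),
    class = "stress_result"
  )
}

#' @export
print.stress_result <- function(x, ...) {
  cat(sprintf("peak fibre stress %.6g MPa (strain %.6g) in element '%s'\n",
              x$peak_stress_mpa, x$peak_strain, x$element_of_peak))
  invisible(x)
}

#' Peak strain for a set of models under a set of load cases
#'
#' Solves every model under every load case and tabulates peak fibre
#' strain. Load cases may be given as case names (`"bite"`, `"shake"`,
#' `"twist"`, built per model via [make_load_case()] with unit magnitude)
#' or as a named list of functions `model -> load_case`.
#'
#' @param models List of `frame_model`s (taxon labels are taken from the
#'   models, else from `names(models)`).
#' @param cases Character vector of case kinds, or named list of functions.
#' @param magnitudes Named numeric vector of load magnitudes per case
#'   (default 1 for each; N for forces, N mm for the twist moment).
#' @return Data frame of class `strain_table`: columns `taxon`,
#'   `load_case`, `peak_fibre_stress_mpa`, `peak_strain`, `element_of_peak`.
#' @export
peak_strain_study <- function(models, cases = c("bite", "shake", "twist"),
                              magnitudes = NULL) {
  if (inherits(models, "frame_model")) models <- list(models)
  labels <- vapply(seq_along(models), function(i) {
    tx <- models[[i]]$taxon
    if (!is.null(tx) && !is.na(tx)) tx
    else if (!is.null(names(models)) && nzchar(names(models)[i]))
      names(models)[i]
    else sprintf("model_%d", i)
  }, character(1))
  case_names <- if (is.list(cases)) names(cases) else cases
  rows <- list()
  for (i in seq_along(models)) {
    for (cs in case_names) {
      mag <- if (!is.null(magnitudes) && cs %in% names(magnitudes))
        magnitudes[[cs]] else 1
      lc <- if (is.list(cases)) cases[[cs]](models[[i]])
      else make_load_case(cs, models[[i]], magnitude = mag)
      res <- tryCatch(
        max_fibre_stress(solve_frame(models[[i]], lc), models[[i]]),
        error = function(e) stop("solve failed for taxon '", labels[i],
                                 "', case '", cs, "': ", conditionMessage(e),
                                 call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = labels[i], load_case = cs,
        peak_fibre_stress_mpa = res$peak_stress_mpa,
        peak_strain = res$peak_strain,
        element_of_peak = res$element_of_peak,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("strain_table", "data.frame")
  out
}
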