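#' General 3D space-frame model
#'
#' A minimal container for a linear-elastic space frame: labelled 3D nodes
#' and prismatic elements with solid circular sections. [build_beam_frame()]
#' constructs the specific 4-node 'Y' mandible idealization; this
#' constructor also serves the test oracles (cantilevers, subdivided beams).
#'
#' @param nodes Numeric matrix (n x 3) with row names (node labels) and
#'   columns x, y, z (mm). X is transverse, Y dorso-ventral, Z longitudinal.
#' @param elements Data frame with columns `label`, `from`, `to` (node
#'   labels) and `diameter` (mm); optional columns `E`, `nu`, `rho`
#'   override `mat` per element.
#' @param mat Default [material()] for elements without their own.
#' @return An object of class `frame_model`: list with `nodes`, `elements`
#'   (with per-element `E`, `nu`, `rho`, `G` filled in) and `material`.
#' @export
frame_model <- function(nodes, elements, mat = material()) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3L || is.null(rownames(nodes)))
    stop("nodes must be an n x 3 matrix with row names", call. = FALSE)
  colnames(nodes) <- c("x", "y", "z")
  need <- c("label", "from", "to", "diameter")
  if (!all(need %in% names(elements)))
    stop("elements needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(c(elements$from, elements$to), rownames(nodes))
  if (length(bad))
    stop("elements reference unknown nodes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(elements$diameter <= 0))
    stop("element diameters must be positive", call. = FALSE)
  if (is.null(elements$E)) elements$E <- mat$E
  if (is.null(elements$nu)) elements$nu <- mat$nu
  if (is.null(elements$rho)) elements$rho <- mat$rho
  elements$G <- elements$E / (2 * (1 + elements$nu))
  len <- sqrt(rowSums((nodes[elements$to, , drop = FALSE] -
                         nodes[elements$from, , drop = FALSE])^2))
  if (any(len <= 0))
    stop("zero-length element: ",
         paste(elements$label[len <= 0], collapse = ", "), call. = FALSE)
  elements$length <- len
  structure(list(nodes = nodes, elements = elements, material = mat),
            class = "frame_model")
}

#' Build the 'Y'-frame beam idealization of a mandible
#'
#' Places the anterior tip at the origin, the symphysis along +Z to the
#' symphysis-rami junction at `(0, 0, SL)`, and the two rami running from
#' the junction to posterior nodes at `(+/- W/2, 0, L)`. All nodes lie in
#' the XZ (coronal) plane; vertical geometry is deliberately constant so
#' that only in-plane shape varies. Coordinates are determined by L, SL and
#' W; the measured angle is treated as derived and is only checked for
#' consistency by [linear_measurements()]. A zero-length symphysis
#' (`SL = 0`) degenerates cleanly to a two-element 'V' frame.
#'
#' @param m A one-row `linear_measurements` object (or a list with fields
#'   `taxon`, `length_mm`, `symphysis_mm`, `width_mm`).
#' @param symphysis_d Symphysis beam diameter (mm). The default maintains
#'   mass, width and overall length between the zero-length-symphysis
#'   configuration and one whose symphysis is 37.5% of overall length.
#' @param ramus_d Ramus beam diameter (mm).
#' @param mat Element [material()]; defaults to structural steel.
#' @return A `frame_model` whose nodes are `anterior_tip`, `junction`,
#'   `posterior_left`, `posterior_right` and whose elements are
#'   `symphysis`, `ramus_left`, `ramus_right` (no `symphysis` if SL = 0).
#' @examples
#' m <- linear_measurements("M. cataphractus", 3.18, 0.80, 16.19, 1.38,
#'                          angle_convention = "half")
#' build_beam_frame(m)
#' @export
build_beam_frame <- function(m, symphysis_d = 0.069054, ramus_d = 0.05,
                             mat = material()) {
  if (is.data.frame(m)) {
    if (nrow(m) != 1L)
      stop("build_beam_frame() takes a single measurement row; ",
           "use lapply() or peak_strain_study() for sets", call. = FALSE)
    m <- as.list(m)
  }
  if (symphysis_d <= 0 || ramus_d <= 0)
    stop("beam diameters must be positive", call. = FALSE)
  L <- m$length_mm; SL <- m$symphysis_mm; W <- m$width_mm
  if (!is.finite(L) || !is.finite(SL) || !is.finite(W) ||
      L <= 0 || SL < 0 || SL >= L || W <= 0)
    stop("invalid measurements: need 0 <= SL < L and W > 0", call. = FALSE)

  if (SL > 0) {
    nodes <- rbind(anterior_tip = c(0, 0, 0),
                   junction = c(0, 0, SL),
                   posterior_left = c(-W / 2, 0, L),
                   posterior_right = c(W / 2, 0, L))
    elements <- data.frame(
      label = c("symphysis", "ramus_left", "ramus_right"),
      from = c("anterior_tip", "junction", "junction"),
      to = c("junction", "posterior_left", "posterior_right"),
      diameter = c(symphysis_d, ramus_d, ramus_d),
      stringsAsFactors = FALSE
    )
  } else {
    # degenerate limit: junction coincides with the tip, symphysis dropped
    nodes <- rbind(anterior_tip = c(0, 0, 0),
                   posterior_left = c(-W / 2, 0, L),
                   posterior_right = c(W / 2, 0, L))
    elements <- data.frame(
      label = c("ramus_left", "ramus_right"),
      from = c("anterior_tip", "anterior_tip"),
      to = c("posterior_left", "posterior_right"),
      diameter = c(ramus_d, ramus_d),
      stringsAsFactors = FALSE
    )
  }
  model <- frame_model(nodes, elements, mat)
  model$taxon <- if (!is.null(m$taxon)) as.character(m$taxon) else NA_character_
  model
}

#' Recover linear measurements from a built 'Y' frame
#'
#' Inverse of [build_beam_frame()]: reads L, SL and W off the node
#' coordinates and derives the full inter-rami angle from them. Used by the
#' round-trip consistency checks.
#'
#' @param model A `frame_model` built by [build_beam_frame()].
#' @return A `linear_measurements` row (full-angle convention).
#' @export
frame_measurements <- function(model) {
  nd <- model$nodes
  if (!all(c("posterior_left", "posterior_right", "anterior_tip") %in%
           rownames(nd)))
    stop("not a mandible 'Y' frame", call. = FALSE)
  tip <- nd["anterior_tip", ]
  SL <- if ("junction" %in% rownames(nd)) nd["junction", "z"] - tip["z"] else 0
  L <- nd["posterior_left", "z"] - tip["z"]
  W <- abs(nd["posterior_right", "x"] - nd["posterior_left", "x"])
  A <- angle_from_geometry(L, SL, W)
  linear_measurements(if (is.null(model$taxon)) NA_character_ else model$taxon,
                      L, SL, A, W)
}

#' Total mass of a frame (sum of rho * A * length over elements)
#'
#' Densities are g/cm^3 and lengths mm, so the result is in grams after the
#' 1e-3 mm^3-to-cm^3 conversion.
#'
#' @param model A `frame_model`.
#' @return Mass in grams.
#' @export
frame_mass <- function(model) {
  el <- model$elements
  area <- pi * el$diameter^2 / 4
  sum(el$rho * area * el$length) * 1e-3
}

#' Subdivide every element of a frame into equal segments
#'
#' Splits each element into `n` collinear segments with the same section and
#' material, inserting intermediate nodes. Under end loads an
#' Euler-Bernoulli frame is exactly insensitive to this refinement, which
#' the test suite uses as a solver invariant.
#'
#' @param model A `frame_model`.
#' @param n Number of segments per element (integer >= 1).
#' @return A refined `frame_model`.
#' @export
subdivide_frame <- function(model, n = 2L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n == 1L) return(model)
  nodes <- model$nodes
  rows <- list()
  for (i in seq_len(nrow(model$elements))) {
    el <- model$elements[i, ]
    p1 <- nodes[el$from, ]; p2 <- nodes[el$to, ]
    labs <- el$from
    for (k in seq_len(n - 1L)) {
      nm <- sprintf("%s_mid%d", el$label, k)
      nodes <- rbind(nodes, matrix(p1 + (p2 - p1) * k / n, 1, 3,
                                   dimnames = list(nm, colnames(nodes))))
      labs <- c(labs, nm)
    }
    labs <- c(labs, el$to)
    for (k in seq_len(n)) {
      seg <- el
      seg$label <- sprintf("%s_seg%d", el$label, k)
      seg$from <- labs[k]; seg$to <- labs[k + 1L]
      rows[[length(rows) + 1L]] <- seg
    }
  }
  out <- frame_model(nodes, do.call(rbind, rows)[
    , c("label", "from", "to", "diameter", "E", "nu", "rho")],
    model$material)
  out$taxon <- model$taxon
  out
}

#' Serialize a frame model to JSON
#'
#' Writes nodes as `label -> [x, y, z]` and elements with their node pair,
#' diameter and material constants; [frame_from_json()] restores the model.
#'
#' @param model A `frame_model`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
frame_to_json <- function(model, path = NULL) {
  nd <- model$nodes
  obj <- list(
    taxon = if (is.null(model$taxon)) NA_character_ else model$taxon,
    nodes = stats::setNames(lapply(seq_len(nrow(nd)),
                                   function(i) unname(nd[i, ])),
                            rownames(nd)),
    elements = model$elements[, c("label", "from", "to", "diameter",
                                  "E", "nu", "rho")]
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname frame_to_json
#' @param json A JSON string or path produced by [frame_to_json()].
#' @export
frame_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  nodes <- do.call(rbind, obj$nodes)
  colnames(nodes) <- c("x", "y", "z")
  model <- frame_model(nodes, obj$elements)
  model$taxon <- obj$taxon
  model
}

#' @export
print.frame_model <- function(x, ...) {
  cat(sprintf("frame model%s: %d nodes, %d elements, mass %.4g g\n",
              if (!is.null(x$taxon) && !is.na(x$taxon))
                paste0(" [", x$taxon, "]") else "",
              nrow(x$nodes), nrow(x$elements), frame_mass(x)))
  invisible(x)
}
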