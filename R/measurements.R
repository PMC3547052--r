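#' Linear mandible measurements
#'
#' Bundles the four linear variables describing mandible geometry in the
#' coronal plane: overall length L, symphyseal length SL, inter-rami angle A
#' (the full angle between the two rami) and posterior width W. Under the
#' 'Y'-frame idealization these covary as \eqn{W = 2 (L - SL) \tan(A/2)};
#' published measurement tables round inconsistently, so consistency between
#' the printed angle and the printed lengths is checked against a loose
#' relative tolerance (warning) and a hard tolerance (rejection).
#'
#' @param taxon Character vector of taxon labels.
#' @param length_mm Overall mandible length L (mm).
#' @param symphysis_mm Symphyseal length SL (mm), `0 <= SL < L`.
#' @param angle_deg Full inter-rami angle A (degrees), in (0, 180).
#' @param width_mm Posterior width W (mm).
#' @param tol Relative tolerance on `|W - 2 (L - SL) tan(A/2)| / W` beyond
#'   which a warning is raised (default 0.15).
#' @param hard_tol Relative tolerance beyond which the measurements are
#'   rejected as inconsistent (default 0.5).
#' @param angle_convention `"full"` (the default: `angle_deg` is the full
#'   inter-rami angle, the canonical convention throughout the package),
#'   `"half"` (`angle_deg` is the angle of each ramus to the midline, so
#'   the implied width is `2 (L - SL) tan(A)`), or `"auto"` (pick the
#'   convention whose implied widths deviate least from the supplied
#'   widths). Published tables use both conventions; the parametric-sweep
#'   dimensions are consistent with the full angle and the seven-taxon
#'   beam dimensions with the half angle.
#' @return A data frame of class `linear_measurements` with columns
#'   `taxon`, `length_mm`, `symphysis_mm`, `angle_deg`, `width_mm`. The
#'   angle column is kept exactly as supplied (it is the regression
#'   predictor); node coordinates are always built from L, SL and W.
#' @examples
#' linear_measurements("M. cataphractus", 3.18, 0.80, 16.19, 1.38,
#'                     angle_convention = "half")
#' @export
linear_measurements <- function(taxon, length_mm, symphysis_mm, angle_deg,
                                width_mm, tol = 0.15, hard_tol = 0.5,
                                angle_convention = c("full", "half",
                                                     "auto")) {
  angle_convention <- match.arg(angle_convention)
  n <- length(taxon)
  stopifnot(length(length_mm) == n, length(symphysis_mm) == n,
            length(angle_deg) == n, length(width_mm) == n)
  if (n == 0L) stop("no measurements supplied", call. = FALSE)
  bad <- !is.finite(length_mm) | !is.finite(symphysis_mm) |
    !is.finite(angle_deg) | !is.finite(width_mm)
  if (any(bad))
    stop("non-finite measurement for: ", paste(taxon[bad], collapse = ", "),
         call. = FALSE)
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("length_mm and width_mm must be positive", call. = FALSE)
  if (any(symphysis_mm < 0) || any(symphysis_mm >= length_mm))
    stop("symphyseal length must satisfy 0 <= SL < L", call. = FALSE)
  if (any(angle_deg <= 0) || any(angle_deg >= 180))
    stop("inter-rami angle must lie in (0, 180) degrees", call. = FALSE)

  if (angle_convention == "auto") {
    dev_for <- function(conv) {
      a <- if (conv == "half") 2 * angle_deg else angle_deg
      if (any(a >= 180)) return(Inf)
      max(abs(width_mm - width_from_geometry(length_mm, symphysis_mm, a)) /
            width_mm)
    }
    angle_convention <- if (dev_for("half") < dev_for("full")) "half"
    else "full"
  }
  full_angle <- if (angle_convention == "half") 2 * angle_deg else angle_deg
  if (any(full_angle >= 180))
    stop("full inter-rami angle must be below 180 degrees", call. = FALSE)
  implied <- width_from_geometry(length_mm, symphysis_mm, full_angle)
  rel <- abs(width_mm - implied) / width_mm
  if (any(rel > hard_tol))
    stop("width inconsistent with length/symphysis/angle beyond hard ",
         "tolerance for: ",
         paste(sprintf("%s (relative deviation %.2f)",
                       taxon[rel > hard_tol], rel[rel > hard_tol]),
               collapse = ", "), call. = FALSE)
  if (any(rel > tol))
    warning("width deviates from 2 (L - SL) tan(A/2) by more than ",
            sprintf("%d%%", round(100 * tol)), " for: ",
            paste(taxon[rel > tol], collapse = ", "),
            "; coordinates will trust L, SL, W", call. = FALSE)

  structure(
    data.frame(taxon = as.character(taxon), length_mm = length_mm,
               symphysis_mm = symphysis_mm, angle_deg = angle_deg,
               width_mm = width_mm, stringsAsFactors = FALSE),
    angle_convention = angle_convention,
    class = c("linear_measurements", "data.frame")
  )
}

#' Posterior width implied by length, symphyseal length and angle
#'
#' Under the 'Y'-frame geometry the rami diverge from the posterior end of
#' the symphysis at half the inter-rami angle each side of the midline, so
#' the posterior width is \eqn{W = 2 (L - SL) \tan(A/2)}.
#'
#' @param L Overall length (mm).
#' @param SL Symphyseal length (mm), `0 <= SL < L` (SL = L gives width 0).
#' @param A Full inter-rami angle (degrees).
#' @return Width (mm); vectorized over the inputs.
#' @examples
#' width_from_geometry(4.0, 1.5, 10)  # 0.437
#' @export
width_from_geometry <- function(L, SL, A) {
  if (any(!is.finite(L) | !is.finite(SL) | !is.finite(A)))
    stop("non-finite input", call. = FALSE)
  if (any(SL > L)) stop("symphyseal length must not exceed overall length",
                        call. = FALSE)
  if (any(A <= 0 | A >= 180)) stop("angle must lie in (0, 180) degrees",
                                   call. = FALSE)
  2 * (L - SL) * tan(A * pi / 360)
}

#' Inter-rami angle implied by length, symphyseal length and width
#'
#' Inverse of [width_from_geometry()]: \eqn{A = 2 \arctan(W / (2 (L - SL)))}.
#'
#' @param L Overall length (mm).
#' @param SL Symphyseal length (mm), `SL < L`.
#' @param W Posterior width (mm).
#' @return Full inter-rami angle (degrees).
#' @export
angle_from_geometry <- function(L, SL, W) {
  if (any(SL >= L)) stop("requires SL < L", call. = FALSE)
  if (any(W <= 0)) stop("width must be positive", call. = FALSE)
  2 * atan(W / (2 * (L - SL))) * 180 / pi
}

#' Read linear measurements from CSV
#'
#' Expects columns `taxon,length_mm,symphysis_mm,angle_deg,width_mm`; extra
#' columns (e.g. an `abbrev` taxon code) are carried through as attributes.
#'
#' @param path Path to a CSV file.
#' @param ... Passed to [linear_measurements()] (e.g. tolerances).
#' @return A `linear_measurements` data frame.
#' @export
read_measurements <- function(path, ...) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "length_mm", "symphysis_mm", "angle_deg", "width_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("measurement file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L) stop("measurement file is empty: ", path, call. = FALSE)
  m <- linear_measurements(d$taxon, d$length_mm, d$symphysis_mm,
                           d$angle_deg, d$width_mm, ...)
  extra <- setdiff(names(d), need)
  for (nm in extra) m[[nm]] <- d[[nm]]
  m
}

#' Write linear measurements to CSV
#' @param m A `linear_measurements` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged measurement fixtures
#'
#' Returns one of the measurement tables shipped with the package: the four
#' parametric sweep blocks for the first beam-model set (`"sweeps"`), the
#' seven-taxon beam-model dimensions (`"taxa"`, 1/100 of the volume-scaled
#' specimens), or the volume-scaled specimen measurements at full size
#' (`"specimens"`, which also carries a jaw-hinge length column).
#'
#' @param which One of `"sweeps"`, `"taxa"`, `"specimens"`.
#' @return A data frame (a `linear_measurements` object for `"taxa"`).
#' @examples
#' head(packaged_measurements("taxa"))
#' @export
packaged_measurements <- function(which = c("taxa", "sweeps", "specimens")) {
  which <- match.arg(which)
  file <- switch(which,
    taxa = "beam_models_taxa.csv",
    sweeps = "beam_models_sweeps.csv",
    specimens = "specimen_measurements_scaled.csv"
  )
  path <- system.file("extdata", file, package = "mandibeam", mustWork = TRUE)
  if (which == "taxa") read_measurements(path, angle_convention = "half")
  else utils::read.csv(path, stringsAsFactors = FALSE)
}
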