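#' Canonical mandible landmark scheme
#'
#' The 22-landmark scheme used for mandible shape capture: `S1` anterior
#' midline origin through `S21`/`S22` the left/right anterior points of the
#' adductor fossa. Published descriptions enumerate S1-S21 and state 22
#' landmarks; `S22` is taken to be the right-side partner of `S21` (and
#' `S12` the right-side partner of `S11`). Readers accept either 21- or
#' 22-landmark files as long as all configurations share the same set.
#'
#' @return Data frame with columns `landmark` (S1..S22) and `side`
#'   (`midline`, `left`, `right`).
#' @export
landmark_scheme <- function() {
  data.frame(
    landmark = paste0("S", 1:22),
    side = c("midline", "left", "right", "midline", "left", "right",
             "left", "right", "left", "right", "left", "right",
             "left", "right", "midline", "midline", "left", "right",
             "left", "right", "left", "right"),
    stringsAsFactors = FALSE
  )
}

#' Assemble a set of landmark configurations
#'
#' @param configs A `k x 3 x n` array, or a list of `k x 3` matrices with
#'   landmark row names. All configurations must share the same landmark
#'   set; left/right pairs of the scheme must be complete.
#' @param taxa Specimen labels (defaults to list/array names).
#' @return A `landmark_set`: `k x 3 x n` array with dimnames
#'   `(landmark, c("x","y","z"), taxon)`.
#' @export
landmark_set <- function(configs, taxa = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
  } else if (is.list(configs)) {
    k <- nrow(configs[[1]])
    lms <- rownames(configs[[1]])
    for (cf in configs) {
      if (!identical(rownames(cf), lms))
        stop("configurations disagree in landmarks: missing ",
             paste(setdiff(lms, rownames(cf)), collapse = ", "),
             call. = FALSE)
    }
    arr <- array(unlist(configs), dim = c(k, 3, length(configs)),
                 dimnames = list(lms, c("x", "y", "z"), names(configs)))
  } else stop("configs must be a 3D array or list of matrices",
              call. = FALSE)
  if (is.null(dimnames(arr)[[1]]))
    stop("landmarks must be named", call. = FALSE)
  dimnames(arr)[[2]] <- c("x", "y", "z")
  if (!is.null(taxa)) dimnames(arr)[[3]] <- taxa
  if (is.null(dimnames(arr)[[3]]))
    dimnames(arr)[[3]] <- sprintf("specimen_%d", seq_len(dim(arr)[3]))
  lms <- dimnames(arr)[[1]]
  sch <- landmark_scheme()
  known <- sch[sch$landmark %in% lms, ]
  pairs <- list(c("S2", "S3"), c("S5", "S6"), c("S7", "S8"), c("S9", "S10"),
                c("S11", "S12"), c("S13", "S14"), c("S17", "S18"),
                c("S19", "S20"), c("S21", "S22"))
  for (p in pairs) {
    if (xor(p[1] %in% lms, p[2] %in% lms))
      stop("incomplete left/right landmark pair: ", paste(p, collapse = "/"),
           call. = FALSE)
  }
  cs <- apply(arr, 3, function(m) sqrt(sum(scale(m, scale = FALSE)^2)))
  if (any(cs <= 0))
    stop("degenerate (all-coincident) configuration: ",
         paste(dimnames(arr)[[3]][cs <= 0], collapse = ", "), call. = FALSE)
  structure(arr, class = c("landmark_set", "array"))
}

#' Read landmark configurations from CSV
#'
#' Expects columns `taxon,landmark,side,x,y,z` (side is checked against the
#' scheme where the landmark is known). 21- and 22-landmark files are both
#' accepted.
#'
#' @param path CSV path.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "landmark", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  taxa <- unique(d$taxon)
  lms <- unique(d$landmark)
  configs <- lapply(taxa, function(tx) {
    sub <- d[d$taxon == tx, ]
    miss <- setdiff(lms, sub$landmark)
    if (length(miss))
      stop("taxon '", tx, "' is missing landmarks: ",
           paste(miss, collapse = ", "), call. = FALSE)
    m <- as.matrix(sub[match(lms, sub$landmark), c("x", "y", "z")])
    rownames(m) <- lms
    m
  })
  names(configs) <- taxa
  landmark_set(configs)
}

#' Write a landmark set to CSV
#' @param lset A `landmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lset, path) {
  sch <- landmark_scheme()
  dn <- dimnames(lset)
  rows <- do.call(rbind, lapply(seq_len(dim(lset)[3]), function(i) {
    data.frame(taxon = dn[[3]][i], landmark = dn[[1]],
               side = sch$side[match(dn[[1]], sch$landmark)],
               x = lset[, 1, i], y = lset[, 2, i], z = lset[, 3, i],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# centroid size of a k x 3 configuration
centroid_size <- function(m) sqrt(sum(scale(m, scale = FALSE)^2))

# optimal rotation (no reflection) aligning centred X onto centred Y
procrustes_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes superimposition
#'
#' Removes translation (centring), size (scaling to unit centroid size) and
#' orientation (iterative rotation to the evolving consensus, by SVD-based
#' orthogonal Procrustes without reflection) from a set of landmark
#' configurations. Iteration stops when the consensus changes by less than
#' `tol` (default 1e-10). The result is invariant, to numerical precision,
#' under arbitrary rotation, translation and rescaling of any input.
#'
#' @param configs A `landmark_set` (or anything [landmark_set()] accepts).
#' @param tol Convergence tolerance on the consensus update.
#' @param max_iter Iteration cap.
#' @return An object of class `gpa`: list with `aligned` (`k x 3 x n`
#'   array of unit-centroid-size aligned shapes), `consensus` (`k x 3`
#'   mean shape, unit centroid size), `centroid_sizes` (original sizes),
#'   `iterations`.
#' @export
procrustes_align <- function(configs, tol = 1e-10, max_iter = 200L) {
  arr <- if (inherits(configs, "landmark_set")) configs
  else landmark_set(configs)
  n <- dim(arr)[3]
  if (n < 2L) stop("need at least two configurations", call. = FALSE)
  sizes <- numeric(n)
  aligned <- unclass(arr)
  for (i in seq_len(n)) {
    m <- scale(arr[, , i], scale = FALSE)
    sizes[i] <- sqrt(sum(m^2))
    aligned[, , i] <- m / sizes[i]
  }
  consensus <- aligned[, , 1]
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*%
        procrustes_rotation(aligned[, , i], consensus)
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- max(abs(new_cons - consensus))
    consensus <- new_cons
    if (delta < tol || it >= max_iter) break
  }
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = stats::setNames(sizes, dimnames(arr)[[3]]),
                 iterations = it),
            class = "gpa")
}

#' Procrustes distance between two aligned configurations
#'
#' Square root of the summed squared landmark differences after both
#' configurations are centred, unit-scaled and optimally rotated together.
#'
#' @param a,b `k x 3` landmark matrices (same landmarks).
#' @return Non-negative distance.
#' @export
procrustes_distance <- function(a, b) {
  ca <- scale(a, scale = FALSE); ca <- ca / sqrt(sum(ca^2))
  cb <- scale(b, scale = FALSE); cb <- cb / sqrt(sum(cb^2))
  sqrt(sum((ca %*% procrustes_rotation(ca, cb) - cb)^2))
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the vectorized Procrustes
#' aligned coordinates (size already removed by centroid-size scaling; the
#' standard orthogonal tangent-space projection is implicit in working with
#' the aligned coordinates directly). PC axes are sign-fixed: PC1 is
#' oriented so that a longer symphysis scores higher (using the S1-S4
#' chord when those landmarks exist), and any remaining axis so that its
#' largest-magnitude loading is positive.
#'
#' @param x A `gpa` object (or a `landmark_set`, which is aligned first).
#' @return An object of class `shape_pca`: list with `consensus`,
#'   `eigenvalues`, `variance_fraction`, `scores` (n x PCs, rows named by
#'   taxon), `loadings`, `gpa`.
#' @export
shape_pca <- function(x) {
  g <- if (inherits(x, "gpa")) x else procrustes_align(x)
  arr <- g$aligned
  n <- dim(arr)[3]
  if (n < 2L) stop("need at least two specimens", call. = FALSE)
  X <- t(apply(arr, 3, as.vector))  # n x 3k
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n - 1L, ncol(pc$rotation)))
  scores <- pc$x[, keep, drop = FALSE]
  load <- pc$rotation[, keep, drop = FALSE]
  ev <- pc$sdev[keep]^2
  # sign conventions
  lms <- dimnames(arr)[[1]]
  for (j in seq_along(keep)) {
    flip <- FALSE
    if (j == 1L && all(c("S1", "S4") %in% lms)) {
      proxy <- apply(arr, 3, function(m) sqrt(sum((m["S4", ] - m["S1", ])^2)))
      if (stats::sd(proxy) > 0 && stats::cor(scores[, 1], proxy) < 0)
        flip <- TRUE
    } else {
      flip <- load[which.max(abs(load[, j])), j] < 0
    }
    if (flip) {
      scores[, j] <- -scores[, j]
      load[, j] <- -load[, j]
    }
  }
  colnames(scores) <- colnames(load) <- paste0("PC", seq_along(keep))
  structure(
    list(consensus = g$consensus,
         eigenvalues = ev,
         variance_fraction = ev / sum(pc$sdev^2),
         scores = scores,
         loadings = load,
         gpa = g),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("shape PCA: %d specimens, PC1 %.1f%%, PC2 %s of variance\n",
              nrow(x$scores), 100 * vf[1],
              if (length(vf) > 1) sprintf("%.1f%%", 100 * vf[2]) else "-"))
  invisible(x)
}

#' Write PCA scores and eigenvalues to CSV
#'
#' @param pca A `shape_pca`.
#' @param scores_path,eigen_path Output paths (either may be NULL to skip).
#' @return Invisibly, a list of the two data frames written.
#' @export
write_shape_pca <- function(pca, scores_path = NULL, eigen_path = NULL) {
  sc <- data.frame(taxon = rownames(pca$scores), pca$scores,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(sc) <- c("taxon", tolower(colnames(pca$scores)))
  ei <- data.frame(component = colnames(pca$scores),
                   eigenvalue = pca$eigenvalues,
                   variance_fraction = pca$variance_fraction[
                     seq_along(pca$eigenvalues)])
  if (!is.null(scores_path))
    utils::write.csv(sc, scores_path, row.names = FALSE, quote = FALSE)
  if (!is.null(eigen_path))
    utils::write.csv(ei, eigen_path, row.names = FALSE, quote = FALSE)
  invisible(list(scores = sc, eigenvalues = ei))
}

#' Linear measurements from a landmark configuration
#'
#' Measurement recipes (fixed package conventions, since the published
#' measurements were taken interactively in a 3D viewer):
#' \itemize{
#'   \item L: distance from S1 (anterior origin) to the midpoint of
#'     S2/S3 (the retro-articular apices);
#'   \item SL: projection of the S1-to-S4 chord (S4 = posterior apex of
#'     the symphysis) onto the S1-to-midpoint(S2,S3) longitudinal axis;
#'   \item W: distance between S2 and S3;
#'   \item A: full angle at S4 between the directions to S2 and S3, after
#'     projecting both onto the plane normal to the dorso-ventral axis
#'     (the axis orthogonal to the longitudinal and transverse directions
#'     of the configuration itself).
#' }
#'
#' @param config A `k x 3` landmark matrix with named rows (needs S1-S4),
#'   or a `landmark_set` (each specimen is measured).
#' @param taxon Label for a single-configuration call.
#' @return A `linear_measurements` data frame (full-angle convention).
#' @export
landmarks_to_linear <- function(config, taxon = "config") {
  if (inherits(config, "landmark_set")) {
    dn <- dimnames(config)
    out <- lapply(seq_len(dim(config)[3]), function(i)
      landmarks_to_linear(config[, , i], taxon = dn[[3]][i]))
    return(do.call(rbind, out))
  }
  need <- c("S1", "S2", "S3", "S4")
  miss <- setdiff(need, rownames(config))
  if (length(miss))
    stop("missing landmarks: ", paste(miss, collapse = ", "), call. = FALSE)
  s1 <- config["S1", ]; s2 <- config["S2", ]
  s3 <- config["S3", ]; s4 <- config["S4", ]
  mid <- (s2 + s3) / 2
  axis_l <- mid - s1
  L <- sqrt(sum(axis_l^2))
  W <- sqrt(sum((s2 - s3)^2))
  if (L <= 1e-12 || W <= 1e-12)
    stop("degenerate landmarks: zero length or width", call. = FALSE)
  zhat <- axis_l / L
  xraw <- (s3 - s2) - sum((s3 - s2) * zhat) * zhat
  if (sqrt(sum(xraw^2)) <= 1e-12 * W)
    stop("degenerate landmarks: transverse axis collinear with length axis",
         call. = FALSE)
  xhat <- xraw / sqrt(sum(xraw^2))
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  SL <- sum((s4 - s1) * zhat)
  proj <- function(v) v - sum(v * yhat) * yhat
  v2 <- proj(s2 - s4); v3 <- proj(s3 - s4)
  n2 <- sqrt(sum(v2^2)); n3 <- sqrt(sum(v3^2))
  if (n2 <= 1e-12 || n3 <= 1e-12)
    stop("degenerate landmarks: rami directions undefined at S4",
         call. = FALSE)
  A <- acos(max(-1, min(1, sum(v2 * v3) / (n2 * n3)))) * 180 / pi
  linear_measurements(taxon, L, SL, A, W)
}
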