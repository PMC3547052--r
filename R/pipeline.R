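# End-to-end orchestration: measurements -> frames -> load cases -> strain
# -> (optional) morphometrics -> regressions -> AICc comparison -> rankings.

default_predictors <- function(cases, have_pcs) {
  base <- list(
    bite = list("length_mm"),
    shake = list("length_mm", "symphysis_mm", "angle_deg"),
    twist = list("length_mm", "symphysis_mm", "angle_deg")
  )
  if (have_pcs) {
    base <- lapply(base, function(p) c(p, list("PC1", c("PC1", "PC2"))))
  }
  base[cases]
}

predictor_label <- function(vars) {
  pretty <- c(length_mm = "ln(Length)", symphysis_mm = "ln(Symphyseal L.)",
              angle_deg = "ln(Angle)", width_mm = "ln(Width)")
  paste(ifelse(vars %in% names(pretty), pretty[vars], vars), collapse = " + ")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the comparative beam study
#'
#' The full pipeline: build a 'Y'-frame beam model per taxon, solve the
#' requested load cases, extract peak fibre strains, optionally align
#' landmarks and compute PC scores, regress log strain on each candidate
#' predictor, compare the candidate explanatory models by AICc, and rank
#' taxa by strain per load case.
#'
#' Because the solve is linear and the response enters the regressions on
#' the log scale, the load magnitudes shift only the intercepts: slopes,
#' log-likelihoods, AICc differences, weights and rankings are invariant
#' to them.
#'
#' @param measurements A `linear_measurements` data frame or CSV path.
#' @param landmarks Optional `landmark_set` or landmark CSV path; when
#'   given, PC1/PC2 scores join the candidate predictors.
#' @param cases Load cases to run (subset of bite/shake/twist).
#' @param magnitudes Named load magnitudes (default 1 each).
#' @param predictors Named list (per case) of predictor sets, each set a
#'   character vector of measurement columns and/or `"PC1"`/`"PC2"`;
#'   default: length for bite; length, symphyseal length and angle for
#'   shake and twist; plus PC1 and PC1+PC2 when landmarks are given.
#' @param symphysis_d,ramus_d Beam diameters (mm).
#' @param mat Element [material()].
#' @param angle_convention Angle convention used when `measurements` is a
#'   CSV path (see [linear_measurements()]); default `"auto"`.
#' @param out_dir Optional output directory: writes `strain_table.csv`,
#'   `comparison_<case>.csv`, `rankings.csv`, `manifest.json`. Written
#'   atomically (assembled in a temporary directory first), so a failed
#'   run leaves no partial outputs.
#' @param seed Optional integer recorded in the manifest (the beam study
#'   itself is deterministic).
#' @return An object of class `beam_study`: list with `measurements`,
#'   `strains` (strain table), `fits`, `comparisons` (one
#'   `model_comparison` per case), `rankings`, `pca` (or NULL),
#'   `manifest`.
#' @examples
#' \donttest{
#' study <- run_beam_study(packaged_measurements("taxa"))
#' study$comparisons$shake
#' }
#' @export
run_beam_study <- function(measurements, landmarks = NULL,
                           cases = c("bite", "shake", "twist"),
                           magnitudes = NULL, predictors = NULL,
                           symphysis_d = 0.069054, ramus_d = 0.05,
                           mat = material(), angle_convention = "auto",
                           out_dir = NULL, seed = NULL) {
  cases <- match.arg(cases, several.ok = TRUE)
  m <- stage("read", {
    if (is.character(measurements))
      read_measurements(measurements, angle_convention = angle_convention)
    else measurements
  })
  if (!nrow(m)) stop("[stage read] no measurement rows", call. = FALSE)
  if (anyDuplicated(m$taxon))
    stop("[stage read] duplicated taxon labels", call. = FALSE)

  models <- stage("build", lapply(seq_len(nrow(m)), function(i)
    build_beam_frame(m[i, ], symphysis_d = symphysis_d, ramus_d = ramus_d,
                     mat = mat)))
  strains <- stage("solve", peak_strain_study(models, cases = cases,
                                              magnitudes = magnitudes))

  pca <- NULL
  scores <- NULL
  if (!is.null(landmarks)) {
    pca <- stage("morphometrics", {
      ls <- if (is.character(landmarks)) read_landmarks(landmarks)
      else landmarks
      shape_pca(procrustes_align(ls))
    })
    sc <- pca$scores
    miss <- setdiff(m$taxon, rownames(sc))
    if (length(miss))
      stop("[stage morphometrics] no landmarks for taxa: ",
           paste(miss, collapse = ", "), call. = FALSE)
    scores <- sc[m$taxon, , drop = FALSE]
  }

  if (is.null(predictors))
    predictors <- default_predictors(cases, have_pcs = !is.null(scores))

  fits <- list(); comparisons <- list()
  for (cs in cases) {
    d <- strains[strains$load_case == cs, ]
    d <- d[match(m$taxon, d$taxon), ]
    case_fits <- stage(paste0("regress_", cs), lapply(
      predictors[[cs]], function(vars) {
        vars <- unlist(vars)
        X <- list(); logx <- logical(0)
        for (v in vars) {
          if (v %in% names(m)) {
            X[[v]] <- m[[v]]; logx <- c(logx, TRUE)
          } else if (!is.null(scores) && v %in% colnames(scores)) {
            X[[v]] <- scores[, v]; logx <- c(logx, FALSE)
          } else stop("unknown predictor '", v, "'", call. = FALSE)
        }
        fit_log_model(d$peak_strain, as.data.frame(X), log_x = logx,
                      label = predictor_label(vars))
      }))
    fits[[cs]] <- case_fits
    comparisons[[cs]] <- stage(paste0("compare_", cs),
                               compare_models(case_fits))
  }
  rankings <- stage("rank", rank_performance(strains))

  manifest <- list(
    package = "mandibeam",
    version = as.character(utils::packageVersion("mandibeam")),
    taxa = m$taxon,
    cases = cases,
    magnitudes = if (is.null(magnitudes)) "unit" else as.list(magnitudes),
    symphysis_diameter_mm = symphysis_d,
    ramus_diameter_mm = ramus_d,
    material = list(E_mpa = mat$E, poisson = mat$nu, density = mat$rho),
    predictors = lapply(predictors, function(p)
      vapply(p, function(v) paste(unlist(v), collapse = "+"), character(1))),
    landmarks_used = !is.null(pca),
    seed = seed
  )

  res <- structure(
    list(measurements = m, strains = strains, fits = fits,
         comparisons = comparisons, rankings = rankings, pca = pca,
         manifest = manifest),
    class = "beam_study"
  )
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' @export
print.beam_study <- function(x, ...) {
  cat(sprintf("beam study: %d taxa, cases %s\n", nrow(x$measurements),
              paste(unique(x$strains$load_case), collapse = "/")))
  for (cs in names(x$comparisons)) {
    best <- x$comparisons[[cs]][1, ]
    cat(sprintf("  %s: AICc-best %s (AICc %.2f, weight %.2f)\n",
                cs, best$model, best$AICc, best$akaike_weight))
  }
  invisible(x)
}

# write result tables + manifest; assemble in tempdir, then move
write_study <- function(res, out_dir) {
  tmp <- tempfile("beam_study_out_")
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  utils::write.csv(as.data.frame(res$strains),
                   file.path(tmp, "strain_table.csv"),
                   row.names = FALSE, quote = FALSE)
  for (cs in names(res$comparisons)) {
    utils::write.csv(as.data.frame(res$comparisons[[cs]]),
                     file.path(tmp, sprintf("comparison_%s.csv", cs)),
                     row.names = FALSE, quote = TRUE)
  }
  utils::write.csv(res$rankings, file.path(tmp, "rankings.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(res$pca))
    write_shape_pca(res$pca, file.path(tmp, "pc_scores.csv"),
                    file.path(tmp, "pc_eigenvalues.csv"))
  jsonlite::write_json(res$manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(tmp)) {
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  }
  ok <- TRUE
  unlink(tmp, recursive = TRUE)
  invisible(out_dir)
}

#' Run the parametric sweep study
#'
#' Solves every model of each sweep block under each load case and
#' summarizes how peak strain varies across the block: the relative spread
#' `(max - min) / min` quantifies whether the varied variable has any
#' mechanical effect. On the canonical blocks this reproduces the
#' beam-theory picture: under biting, strain tracks overall length and
#' ignores width; under shaking it is flat whenever symphyseal length is
#' constant; under twisting it is flat whenever angle is constant.
#'
#' @param blocks Character vector of preset names, or list of
#'   `sweep_spec`s (default: all four presets).
#' @param cases Load cases to run.
#' @param symphysis_d,ramus_d,mat As in [run_beam_study()].
#' @return An object of class `sweep_study`: list with `strains` (per
#'   block x model x case) and `spread` (per block x case relative
#'   strain spread).
#' @export
run_sweep_study <- function(blocks = names(sweep_preset("all")),
                            cases = c("bite", "shake", "twist"),
                            symphysis_d = 0.069054, ramus_d = 0.05,
                            mat = material()) {
  cases <- match.arg(cases, several.ok = TRUE)
  specs <- if (is.character(blocks)) lapply(blocks, sweep_preset)
  else blocks
  rows <- list(); spreads <- list()
  for (spec in specs) {
    mm <- generate_sweep(spec)
    models <- lapply(seq_len(nrow(mm)), function(i)
      build_beam_frame(mm[i, ], symphysis_d = symphysis_d,
                       ramus_d = ramus_d, mat = mat))
    st <- peak_strain_study(models, cases = cases)
    st <- merge(st, as.data.frame(mm), by = "taxon", sort = FALSE)
    st$block <- spec$block
    rows[[spec$block]] <- st
    for (cs in cases) {
      s <- st$peak_strain[st$load_case == cs]
      spreads[[length(spreads) + 1L]] <- data.frame(
        block = spec$block, load_case = cs,
        min_strain = min(s), max_strain = max(s),
        relative_spread = (max(s) - min(s)) / min(s),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(strains = do.call(rbind, rows),
                 spread = do.call(rbind, spreads)),
            class = "sweep_study")
}

#' @export
print.sweep_study <- function(x, ...) {
  cat("sweep study strain spreads ((max-min)/min):\n")
  print(x$spread, row.names = FALSE)
  invisible(x)
}
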