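#' Ordinary least squares on (optionally) log-transformed variables
#'
#' Fits `y ~ X` by OLS after applying natural logs where requested
#' (strains and linear measurements are log-transformed; PC scores are
#' used raw because they can be negative). The log-likelihood is the
#' Gaussian maximum-likelihood value with the MLE variance `RSS/n`:
#' \deqn{\log L = -\frac{n}{2}\left(\ln(2\pi\,RSS/n) + 1\right),}
#' and the parameter count `k` includes the residual variance, so a
#' one-predictor fit has `k = 3`.
#'
#' @param y Response values (e.g. peak strains), length n.
#' @param X Data frame (or named list) of predictor columns.
#' @param log_y Log-transform the response? (default TRUE).
#' @param log_x Logical vector (recycled / named by predictor) saying which
#'   predictors are log-transformed; default TRUE for every predictor.
#' @param label Optional model label (defaults to the predictor names).
#' @return An object of class `strain_fit`: list with `label`,
#'   `predictors`, `coefficients` (intercept first), `n`, `k`, `rss`,
#'   `logLik`, `aicc`, `degenerate` (TRUE when RSS is numerically zero, in
#'   which case `logLik`/`aicc` are NA rather than infinite numbers), the
#'   transformed `response` vector (used to guard model comparisons), and
#'   the underlying `lm` fit.
#' @examples
#' fit_log_model(c(1, 2, 3, 5, 8), data.frame(L = 1:5))
#' @export
fit_log_model <- function(y, X = NULL, log_y = TRUE, log_x = TRUE,
                          label = NULL) {
  X <- if (is.null(X)) data.frame(row.names = seq_along(y))
  else as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n && ncol(X) > 0)
    stop("y and X disagree in length", call. = FALSE)
  p <- ncol(X)
  if (is.null(names(log_x))) {
    log_x <- rep_len(log_x, p)
  } else {
    lx <- rep(TRUE, p)
    lx[match(names(log_x), names(X))] <- log_x
    log_x <- lx
  }
  if (log_y) {
    if (any(y <= 0)) stop("log response requires positive values",
                          call. = FALSE)
    y <- log(y)
  }
  for (j in seq_len(p)) {
    if (log_x[j]) {
      if (any(X[[j]] <= 0))
        stop("log predictor '", names(X)[j], "' requires positive values",
             call. = FALSE)
      X[[j]] <- log(X[[j]])
    }
  }
  k <- p + 2L  # slopes + intercept + residual variance
  if (n <= p + 1L) stop("need n > number of coefficients", call. = FALSE)

  fit <- if (p == 0L) stats::lm(y ~ 1, data = data.frame(y = y))
  else stats::lm(.y ~ ., data = cbind(.y = y, X))
  rss <- sum(stats::residuals(fit)^2)
  degenerate <- rss <= 1e-12 * max(1, sum(y^2))
  ll <- if (degenerate) NA_real_ else -(n / 2) * (log(2 * pi * rss / n) + 1)
  structure(
    list(label = if (!is.null(label)) label
         else if (p == 0L) "intercept-only"
         else paste(names(X), collapse = "+"),
         predictors = names(X),
         coefficients = stats::coef(fit),
         n = n, k = k, rss = rss, logLik = ll,
         aicc = if (degenerate || n <= k + 1L) NA_real_ else aicc(ll, k, n),
         degenerate = degenerate,
         response = unname(y),
         lm = fit),
    class = "strain_fit"
  )
}

#' @export
print.strain_fit <- function(x, ...) {
  cat(sprintf("strain_fit [%s]: n = %d, k = %d", x$label, x$n, x$k))
  if (x$degenerate) {
    cat(" -- degenerate (RSS = 0; likelihood unbounded)\n")
  } else {
    cat(sprintf(", logLik = %.2f, AICc = %.2f\n", x$logLik, x$aicc))
  }
  co <- x$coefficients
  cat("  coefficients:",
      paste(sprintf("%s = %.3f", names(co), co), collapse = ", "), "\n")
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' \deqn{AICc = -2\log L + 2k + \frac{2k(k+1)}{n-k-1}}
#' where `k` counts every estimated parameter including the residual
#' variance. Undefined when `n <= k + 1`.
#'
#' @param logLik Model log-likelihood.
#' @param k Number of estimated parameters (including the variance).
#' @param n Sample size.
#' @return AICc value.
#' @examples
#' aicc(32.12, 3, 7)  # -50.24
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1))
    stop("AICc small-sample correction is undefined for n <= k + 1",
         call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted explanatory models by AICc
#'
#' Ranks fits by AICc, computes differences from the AICc-best model and
#' Akaike weights \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}, and
#' attaches the conventional qualitative support labels (a difference
#' within 2 of the best is nearly identical in information, 4-8 fair, and
#' above 10 poor). All fits must share the same response data; comparing
#' likelihoods across different data is meaningless and is refused.
#'
#' @param fits List of `strain_fit` objects (or a single fit).
#' @return Data frame of class `model_comparison`, sorted by AICc:
#'   columns `model`, intercept and per-predictor slope columns, `df`,
#'   `logLik`, `AICc`, `dAICc`, `akaike_weight`, `support`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "strain_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits to compare", call. = FALSE)
  y0 <- fits[[1]]$response
  for (f in fits) {
    if (!inherits(f, "strain_fit"))
      stop("compare_models() expects strain_fit objects", call. = FALSE)
    if (f$degenerate)
      stop("cannot compare a degenerate (RSS = 0) fit", call. = FALSE)
    if (length(f$response) != length(y0) ||
        max(abs(f$response - y0)) > 1e-8 * max(1, max(abs(y0))))
      stop("fits were made to different response data; AICc comparison ",
           "requires identical data", call. = FALSE)
  }
  labels <- vapply(fits, `[[`, character(1), "label")
  aic <- vapply(fits, `[[`, numeric(1), "aicc")
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  df <- vapply(fits, `[[`, integer(1), "k")
  preds <- unique(unlist(lapply(fits, `[[`, "predictors")))
  coefm <- matrix(NA_real_, length(fits), length(preds) + 1L,
                  dimnames = list(NULL, c("intercept", preds)))
  for (i in seq_along(fits)) {
    co <- fits[[i]]$coefficients
    coefm[i, "intercept"] <- co[["(Intercept)"]]
    for (pn in fits[[i]]$predictors) coefm[i, pn] <- co[[pn]]
  }
  res <- akaike_weights(aic)
  out <- data.frame(model = labels, coefm, df = df, logLik = ll, AICc = aic,
                    dAICc = res$delta, akaike_weight = res$weight,
                    support = res$support,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$AICc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Akaike weights from AICc (or delta-AICc) values
#'
#' @param aicc Numeric vector of AICc values, or already-formed deltas
#'   (weights depend only on differences).
#' @return List with `delta`, `weight` (summing to 1) and qualitative
#'   `support` labels.
#' @examples
#' akaike_weights(c(0, 0.17, 6.47, 8.66, 13.74))$weight
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc) || any(!is.finite(aicc)))
    stop("AICc values must be finite", call. = FALSE)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  lab <- cut(delta, breaks = c(-Inf, 2, 4, 8, 10, Inf),
             labels = c("nearly identical", "substantial", "fair", "weak",
                        "poor"))
  list(delta = delta, weight = w / sum(w), support = as.character(lab))
}

#' Quantile of an element strain distribution
#'
#' Robust peak-strain summary for element strain fields: the `q` quantile
#' with linear interpolation between order statistics at positions
#' `1 + (n - 1) q` (the R type-7 convention; the convention is fixed and
#' documented so published-style 95% values are reproducible). High-res FE
#' strain maxima are often restraint artifacts; the 0.95 quantile discards
#' that tail while tracking the bulk of the field.
#'
#' @param values Numeric vector of element strains (non-empty).
#' @param q Quantile(s) in `[0, 1]` (default 0.95).
#' @return Quantile value(s).
#' @examples
#' strain_percentile(1:100, 0.95)  # 95.05
#' @export
strain_percentile <- function(values, q = 0.95) {
  if (!length(values)) stop("empty strain field", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite strain values", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(values, q, type = 7))
}

#' Summary quantiles of a strain field
#'
#' @param values Element strains.
#' @return Named vector with mean and the 50/75/90/95/99/100% quantiles
#'   (non-decreasing in the quantile order).
#' @export
strain_summary <- function(values) {
  qs <- strain_percentile(values, c(0.5, 0.75, 0.9, 0.95, 0.99, 1))
  c(mean = mean(values),
    `50%` = qs[1], `75%` = qs[2], `90%` = qs[3], `95%` = qs[4],
    `99%` = qs[5], `100%` = qs[6])
}

#' Rank taxa by strain within each load case
#'
#' Rank 1 is the lowest peak strain (the structurally best performer).
#' Exact ties are broken alphabetically by taxon label and flagged.
#'
#' @param strain_table Data frame with columns `taxon`, `load_case` and a
#'   strain column (`peak_strain` by default).
#' @param value Name of the strain column.
#' @return Data frame with columns `load_case`, `rank`, `taxon`, `strain`,
#'   `tied`.
#' @export
rank_performance <- function(strain_table, value = "peak_strain") {
  need <- c("taxon", "load_case", value)
  if (!all(need %in% names(strain_table)))
    stop("strain table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(strain_table[[value]])))
    stop("missing strain cells for: ",
         paste(strain_table$taxon[is.na(strain_table[[value]])],
               collapse = ", "), call. = FALSE)
  cases <- unique(strain_table$load_case)
  taxa <- unique(strain_table$taxon)
  out <- list()
  for (cs in cases) {
    d <- strain_table[strain_table$load_case == cs, ]
    miss <- setdiff(taxa, d$taxon)
    if (length(miss))
      stop("load case '", cs, "' is missing taxa: ",
           paste(miss, collapse = ", "), call. = FALSE)
    o <- order(d[[value]], d$taxon)
    d <- d[o, ]
    tied <- duplicated(d[[value]]) | duplicated(d[[value]], fromLast = TRUE)
    if (any(tied))
      warning("tied strains in load case '", cs, "': ",
              paste(d$taxon[tied], collapse = ", "),
              " (ties broken by taxon label)", call. = FALSE)
    out[[cs]] <- data.frame(load_case = cs, rank = seq_len(nrow(d)),
                            taxon = d$taxon, strain = d[[value]],
                            tied = tied, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an external per-element strain field from CSV
#'
#' Accepts strain exports from any external FE solver with columns
#' `element_id,strain`, enabling the quantile summaries and regressions on
#' user-supplied high-resolution results.
#'
#' @param path CSV path.
#' @return Numeric vector of strains (named by element id).
#' @export
read_strain_field <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("element_id", "strain") %in% names(d)))
    stop("strain field CSV needs columns element_id,strain", call. = FALSE)
  stats::setNames(d$strain, d$element_id)
}
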