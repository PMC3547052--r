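#' Published model-comparison tables
#'
#' The printed explanatory-model comparison tables (beam shake/twist and
#' high-resolution FE bite/shake/twist), transcribed as shipped data. The
#' FE rows cannot be regenerated at desk scale (they require the
#' multi-million-element CT-based models), but their logLik/AICc/weight
#' arithmetic is fully checkable with [aicc()] and [akaike_weights()].
#'
#' @param analysis Optional filter: one of `"shake_beam"`, `"twist_beam"`,
#'   `"bite_fem"`, `"shake_fem"`, `"twist_fem"`.
#' @return Data frame with columns `analysis`, `response_model`, `rank`,
#'   `predictors`, `intercept`, `slope1`, `slope2`, `df`, `logLik`,
#'   `AICc`, `dAICc`, `akaike_weight`.
#' @export
published_comparisons <- function(analysis = NULL) {
  d <- utils::read.csv(system.file("extdata", "published_comparisons.csv",
                                   package = "mandibeam", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  if (!is.null(analysis)) {
    analysis <- match.arg(analysis, unique(d$analysis))
    d <- d[d$analysis == analysis, , drop = FALSE]
  }
  d
}

#' Packaged jaw-muscle tables
#'
#' `"groups"`: the adductor muscles with their functional group (temporal
#' or pterygoid) and the number of truss elements representing each
#' (totals: 138 temporal, 160 pterygoid). `"pretensions"`: per-truss
#' pretensions (N) per taxon at natural size and after volume scaling.
#'
#' @param which `"groups"` or `"pretensions"`.
#' @return Data frame.
#' @export
packaged_muscles <- function(which = c("groups", "pretensions")) {
  which <- match.arg(which)
  f <- if (which == "groups") "muscle_groups.csv" else "muscle_pretensions.csv"
  utils::read.csv(system.file("extdata", f, package = "mandibeam",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}
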