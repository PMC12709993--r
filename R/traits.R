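#' Canopy-scale trait derivation
#'
#' Spreads leaf-scale traits to the canopy: canopy chlorophyll content
#' `CCC = Cab * LAI` (ug cm-2) and canopy equivalent water
#' `CEW = Cw * LAI` (cm).
#'
#' @param Cab Leaf chlorophyll a+b content (ug cm-2), >= 0.
#' @param Cw Leaf equivalent water thickness (cm), >= 0.
#' @param LAI Leaf area index, >= 0.
#' @return Tibble with columns `CCC`, `CEW`.
#' @export
derive_canopy_traits <- function(Cab, Cw, LAI) {
  if (any(Cab < 0) || any(Cw < 0) || any(LAI < 0)) {
    stop("Cab, Cw and LAI must be non-negative", call. = FALSE)
  }
  tibble::tibble(CCC = Cab * LAI, CEW = Cw * LAI)
}

#' Append canopy traits to a parameter table
#' @param params Data frame with `Cab`, `Cw`, `LAI` columns.
#' @return `params` with `CCC` and `CEW` columns added.
#' @export
add_canopy_traits <- function(params) {
  dplyr::mutate(tibble::as_tibble(params),
                CCC = .data$Cab * .data$LAI,
                CEW = .data$Cw * .data$LAI)
}

#' Retrieval accuracy metrics
#'
#' Pearson correlation R, root mean square error RMSE, relative RMSE
#' (RMSE divided by the mean of the measured values), and the composite
#' general accuracy index GAI. Two GAI conventions are supported:
#' `"literal"` gives `1 - R + RRMSE` (lower is better) and
#' `"complement"` gives `R - RRMSE` (higher is better).
#'
#' @param mea Measured (reference) values, length >= 2 with positive sd.
#' @param sim Predicted/simulated values, same length.
#' @param gai_form `"literal"` (default) or `"complement"`.
#' @return One-row tibble with `R`, `RMSE`, `RRMSE`, `GAI`, `n`.
#' @export
evaluate_retrieval <- function(mea, sim, gai_form = c("literal", "complement")) {
  gai_form <- match.arg(gai_form)
  if (length(mea) != length(sim)) stop("mea and sim must have equal length", call. = FALSE)
  if (length(mea) < 2) stop("at least two value pairs are required", call. = FALSE)
  if (stats::sd(mea) == 0 || stats::sd(sim) == 0) {
    stop("R is undefined for zero-variance input", call. = FALSE)
  }
  if (abs(mean(mea)) < .Machine$double.eps) {
    stop("RRMSE is undefined when mean(mea) is zero", call. = FALSE)
  }
  r <- stats::cov(mea, sim) / (stats::sd(mea) * stats::sd(sim))
  rmse <- sqrt(mean((mea - sim)^2))
  rrmse <- rmse / mean(mea)
  gai <- if (gai_form == "literal") 1 - r + rrmse else r - rrmse
  tibble::tibble(R = r, RMSE = rmse, RRMSE = rrmse, GAI = gai, n = length(mea))
}

#' One-way F test for group differences in a trait
#'
#' Classic one-way analysis-of-variance F statistic for differences in
#' group means, used to flag treatment effects on retrieved traits.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), >= 2 groups with >= 2
#'   values each.
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
f_test_group_difference <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least two values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- stats::anova(fit)
  tibble::tibble(
    statistic = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
    p_value = tab$`Pr(>F)`[1]
  )
}
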