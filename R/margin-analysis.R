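#' Fit a second-order polynomial model of thermal limit on thermal affinity
#'
#' Ordinary least squares of experimentally derived upper thermal limit on
#' occupancy-derived mean thermal affinity, `tmax = a + b*x + c*x^2`, in one
#' of three forms: `"pooled"` (one curve), `"additive"` (per-group
#' intercepts, shared curve shape), or `"interaction"` (group interacts
#' with both polynomial terms, i.e. per-group curves sharing one residual
#' variance). Coefficients are reported on the raw basis — the
#' parameterisation in which the quadratic vertex `-b/(2c)` is meaningful —
#' with 95% t-based Wald confidence intervals.
#'
#' @param data data frame with one row per species, containing the response
#'   and predictor columns.
#' @param form model form, one of `"pooled"`, `"additive"`, `"interaction"`.
#' @param tmax_col,affinity_col,group_col column names of the response,
#'   predictor, and grouping factor (`group_col` ignored for `"pooled"`).
#' @param conf_level confidence level of the coefficient intervals.
#' @return An object of class `polynomial_fit`: list with the `lm` model,
#'   `form`, `coefficients` (with CIs), `r_squared`, `residual_df`, the
#'   observed affinity range, and for grouped forms the group levels.
#' @export
fit_polynomial_model <- function(data, form = c("pooled", "additive", "interaction"),
                                 tmax_col = "tmax", affinity_col = "affinity",
                                 group_col = "group", conf_level = 0.95) {
  form <- match.arg(form)
  stopifnot(all(c(tmax_col, affinity_col) %in% names(data)))
  df <- data.frame(
    .tmax = as.numeric(data[[tmax_col]]),
    .x = as.numeric(data[[affinity_col]])
  )
  if (form != "pooled") {
    if (!group_col %in% names(data)) stop("grouped form needs column: ", group_col)
    df$.group <- factor(data[[group_col]])
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (!all(is.finite(df$.x))) stop("affinities must be finite")
  n_par <- switch(form, pooled = 3L,
                  additive = 2L + nlevels(df$.group),
                  interaction = 3L * nlevels(df$.group))
  if (nrow(df) < n_par + 2L) {
    stop("too few complete species (", nrow(df), ") for the ", form, " form")
  }
  if (form == "interaction") {
    cnt <- table(df$.group)
    if (any(cnt < 3)) {
      stop("group(s) with fewer than 3 species under the interaction form: ",
           paste(names(cnt)[cnt < 3], collapse = ", "))
    }
  }
  fm <- switch(form,
    pooled = .tmax ~ .x + I(.x^2),
    additive = .tmax ~ .group + .x + I(.x^2),
    interaction = .tmax ~ .group * (.x + I(.x^2))
  )
  fit <- stats::lm(fm, data = df)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design for the ", form, " form")
  }
  # R^2 computed from sums of squares directly: summary.lm's ratio is
  # numerically meaningless when the response is (near-)constant
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((df$.tmax - mean(df$.tmax))^2)
  r2 <- if (tss <= 1e-10 * max(1, mean(df$.tmax)^2)) 0 else 1 - rss / tss
  r2 <- min(max(r2, 0), 1)
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  coefs <- data.frame(
    term = names(stats::coef(fit)),
    estimate = unname(stats::coef(fit)),
    lower = ci[, 1], upper = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(model = fit, form = form,
         coefficients = coefs,
         r_squared = r2,
         residual_df = fit$df.residual,
         affinity_range = range(df$.x),
         groups = if (form != "pooled") levels(df$.group),
         n = nrow(df)),
    class = "polynomial_fit"
  )
}

#' @export
print.polynomial_fit <- function(x, ...) {
  cat("Second-order polynomial fit (", x$form, " form), n = ", x$n,
      ", R^2 = ", round(x$r_squared, 3), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Raw-basis quadratic coefficients of a polynomial fit
#'
#' Collapses a fitted model to one `(a, b, c)` triple per curve —
#' intercept, linear, and quadratic coefficient of
#' `tmax = a + b*x + c*x^2` — resolving treatment contrasts so each group's
#' own curve is reported (for the pooled form there is a single row with
#' `group = NA`).
#'
#' @param fit a [fit_polynomial_model()] object.
#' @return data frame with columns `group`, `a`, `b`, `c`.
#' @export
raw_coefficients <- function(fit) {
  cf <- stats::coef(fit$model)
  if (fit$form == "pooled") {
    return(data.frame(group = NA_character_,
                      a = unname(cf["(Intercept)"]),
                      b = unname(cf[".x"]),
                      c = unname(cf["I(.x^2)"]),
                      stringsAsFactors = FALSE))
  }
  groups <- fit$groups
  rows <- lapply(groups, function(g) {
    gi <- paste0(".group", g)
    a <- unname(cf["(Intercept)"]) +
      if (gi %in% names(cf)) unname(cf[gi]) else 0
    b <- unname(cf[".x"]) +
      if (paste0(gi, ":.x") %in% names(cf)) unname(cf[paste0(gi, ":.x")]) else 0
    c <- unname(cf["I(.x^2)"]) +
      if (paste0(gi, ":I(.x^2)") %in% names(cf)) {
        unname(cf[paste0(gi, ":I(.x^2)")])
      } else 0
    data.frame(group = g, a = a, b = b, c = c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two nested polynomial fits by extra-sum-of-squares F-test
#'
#' The usual nested-model comparison: does the richer design (e.g. the
#' group-by-affinity interaction) explain significantly more variance than
#' the simpler one (e.g. additive group intercepts)? Both fits must be on
#' the same response vector and the simpler design must be contained in the
#' richer one.
#'
#' @param fit_nested,fit_full [fit_polynomial_model()] objects, the first
#'   nested in the second.
#' @return An object of class `model_comparison`: `df1` (parameters added),
#'   `df2` (residual df of the full model), `F`, `p`, and `delta_r2`.
#' @export
compare_models <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "polynomial_fit"),
            inherits(fit_full, "polynomial_fit"))
  y1 <- stats::model.response(stats::model.frame(fit_nested$model))
  y2 <- stats::model.response(stats::model.frame(fit_full$model))
  if (length(y1) != length(y2) || !isTRUE(all.equal(unname(y1), unname(y2)))) {
    stop("models were not fitted to the same response vector")
  }
  rank_order <- c(pooled = 1, additive = 2, interaction = 3)
  if (rank_order[fit_nested$form] >= rank_order[fit_full$form]) {
    stop("first model must be nested in the second (",
         fit_nested$form, " vs ", fit_full$form, ")")
  }
  rss_n <- sum(stats::resid(fit_nested$model)^2)
  rss_f <- sum(stats::resid(fit_full$model)^2)
  df1 <- fit_nested$residual_df - fit_full$residual_df
  df2 <- fit_full$residual_df
  Fstat <- if (rss_f == 0 && rss_n == rss_f) 0 else ((rss_n - rss_f) / df1) / (rss_f / df2)
  Fstat <- max(Fstat, 0)
  structure(
    list(df1 = df1, df2 = df2, F = Fstat,
         p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
         delta_r2 = fit_full$r_squared - fit_nested$r_squared),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4f, delta R^2 = %.4f\n",
              x$df1, x$df2, x$F, x$p, x$delta_r2))
  invisible(x)
}

#' Affinity at which the fitted quadratic peaks
#'
#' The vertex `-b/(2c)` of each fitted curve, defined only when the
#' quadratic coefficient is negative (an interior maximum exists). Vertices
#' outside the observed affinity range are flagged as extrapolated: the
#' curve peaks beyond the data.
#'
#' @param fit a [fit_polynomial_model()] object.
#' @return data frame with one row per curve: `group` (`NA` for the pooled
#'   form), `vertex` (degC, `NA` when the quadratic term is >= 0), and
#'   logical `extrapolated`.
#' @export
vertex <- function(fit) {
  stopifnot(inherits(fit, "polynomial_fit"))
  rc <- raw_coefficients(fit)
  v <- ifelse(rc$c < 0, -rc$b / (2 * rc$c), NA_real_)
  data.frame(
    group = rc$group,
    vertex = v,
    extrapolated = !is.na(v) &
      (v < fit$affinity_range[1] | v > fit$affinity_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Thermal safety margins
#'
#' The margin of a species is its experimentally derived upper thermal
#' limit minus its mean occupancy-derived thermal affinity: how far, in
#' degrees, the species lives from its physiological limit. Species are
#' binned by affinity as cold (<= 10 degC), moderate (> 10 and <= 20 degC),
#' or warm (> 20 degC). Species missing an affinity on the chosen measure
#' are omitted and logged.
#'
#' @param limits a [aggregate_tmax()] table (`species_id`, `tmax`, and
#'   optionally `group`).
#' @param affinities a [summarize_affinity()] table.
#' @param measure affinity measure to use (default the temperature at
#'   sampling depth from the monthly gridded product).
#' @param exclude_groups groups dropped from the margin analysis (data-poor
#'   groups by default).
#' @return data frame of class `safety_margins`: `species_id`, `group`,
#'   `affinity`, `margin`, `affinity_bin`; omitted species are recorded in
#'   attribute `"omitted"`.
#' @export
safety_margins <- function(limits, affinities, measure = "grid_t_at_depth",
                           exclude_groups = c("birds", "mammals", "nekton")) {
  aff <- affinities[affinities$measure == measure & !is.na(affinities$mean),
                    c("species_id", "mean")]
  lim <- limits
  if ("group" %in% names(lim) && length(exclude_groups) > 0) {
    lim <- lim[!(lim$group %in% exclude_groups), , drop = FALSE]
  }
  m <- match(lim$species_id, aff$species_id)
  omitted <- lim$species_id[is.na(m)]
  keep <- !is.na(m)
  affin <- aff$mean[m[keep]]
  out <- data.frame(
    species_id = lim$species_id[keep],
    group = if ("group" %in% names(lim)) lim$group[keep] else NA_character_,
    affinity = affin,
    margin = lim$tmax[keep] - affin,
    affinity_bin = cut(affin, breaks = c(-Inf, 10, 20, Inf),
                       labels = c("cold", "moderate", "warm"), right = TRUE),
    stringsAsFactors = FALSE
  )
  attr(out, "omitted") <- omitted
  class(out) <- c("safety_margins", "data.frame")
  out
}

#' Margin summary by functional group and affinity bin
#'
#' Mean and standard deviation of the thermal safety margin per functional
#' group per affinity bin, with counts. Empty group-bin combinations are
#' absent from the table, not reported as zero.
#'
#' @param margins a [safety_margins()] table.
#' @return data frame with `group`, `affinity_bin`, `n`, `mean_margin`,
#'   `sd_margin` (SD `NA` for singleton cells).
#' @export
bin_margin_table <- function(margins) {
  stopifnot(all(c("group", "affinity_bin", "margin") %in% names(margins)))
  key <- interaction(margins$group, margins$affinity_bin, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    v <- margins$margin[sel]
    data.frame(
      group = margins$group[sel][1],
      affinity_bin = as.character(margins$affinity_bin[sel][1]),
      n = length(v),
      mean_margin = mean(v),
      sd_margin = if (length(v) > 1) stats::sd(v) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$group, match(out$affinity_bin, c("cold", "moderate", "warm"))), ,
      drop = FALSE]
}
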