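#' Two-way ANOVA with Tukey HSD for longitudinal device features
#'
#' Compares device-mean feature values across culture groups and days in
#' vitro (DIV): `value ~ group * div` with both factors crossed, followed by
#' Tukey honest-significant-difference contrasts on the group factor.
#' Significance threshold alpha = 0.05. The ANOVA arithmetic is delegated to
#' [stats::aov()] / [stats::TukeyHSD()]; this layer does the table assembly,
#' design checks and tidying.
#'
#' @param data A long table with one row per device x DIV x feature:
#'   columns `device_id`, `group`, `div`, `feature`, `value` (the shape
#'   produced by stacking device rows of [device_features()] over time).
#' @param feature Which feature to test.
#' @param alpha Significance level (default 0.05).
#' @return An `mea_anova` object; see [tidy.mea_anova()].
#' @export
two_way_anova_tukey <- function(data, feature, alpha = 0.05) {
  df <- data[data$feature == feature & !is.na(data$value), , drop = FALSE]
  df$group <- factor(df$group)
  df$div <- factor(df$div)
  if (nlevels(df$group) < 2 || nlevels(df$div) < 2) {
    stop("need at least 2 groups and 2 DIV levels", call. = FALSE)
  }
  cell_n <- table(df$group, df$div)
  if (any(cell_n == 0)) {
    bad <- which(cell_n == 0, arr.ind = TRUE)[1, ]
    stop("unbalanced design: no devices for group ",
         rownames(cell_n)[bad[1]], " at DIV ", colnames(cell_n)[bad[2]],
         "; drop the empty cell or pool DIVs before testing", call. = FALSE)
  }
  if (all(cell_n < 2)) {
    stop("need at least 2 replicate devices in some cells to estimate ",
         "residual error", call. = FALSE)
  }
  fit <- stats::aov(value ~ group * div, data = df)
  tk <- stats::TukeyHSD(fit, which = "group")
  new_mea_anova(fit, tk, design = "two_way", feature = feature,
                alpha = alpha, data = df)
}

#' One-way ANOVA with Tukey HSD for fold changes
#'
#' Compares per-device fold changes (or any per-device scalar) across groups:
#' `value ~ group`, Tukey contrasts on all group pairs, per-group mean and
#' standard error of the mean (SEM = SD / sqrt(n)). Groups with a single
#' device cannot contribute a variance estimate and are excluded with a
#' warning; if all groups have zero within-group variance the F statistic is
#' degenerate and flagged.
#'
#' @param data A table with columns `group` and `value` (one row per device);
#'   an optional `feature` column is filtered by `feature`.
#' @param feature Feature to test when `data` holds several.
#' @param alpha Significance level.
#' @return An `mea_anova` object; `glance()` has the F and p, `tidy()` the
#'   Tukey contrasts, and `$group_summary` the per-group mean/SEM.
#' @export
one_way_anova_tukey <- function(data, feature = NULL, alpha = 0.05) {
  df <- data
  if (!is.null(feature) && "feature" %in% names(df)) {
    df <- df[df$feature == feature, , drop = FALSE]
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  df$group <- factor(df$group)
  sizes <- table(df$group)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding group(s) with a single device: ",
            paste(drop, collapse = ", "), call. = FALSE)
    df <- df[!df$group %in% drop, , drop = FALSE]
    df$group <- droplevels(df$group)
  }
  if (nlevels(df$group) < 2) {
    stop("need at least 2 groups with at least 2 devices each", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  degenerate <- stats::sigma(fit) < 1e-10 * max(1, abs(mean(df$value)))
  tk <- if (degenerate) NULL else stats::TukeyHSD(fit, which = "group")
  out <- new_mea_anova(fit, tk, design = "one_way", feature = feature,
                       alpha = alpha, data = df)
  out$degenerate <- degenerate
  out
}

new_mea_anova <- function(fit, tukey, design, feature, alpha, data) {
  gs <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$group),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  structure(list(fit = fit, tukey = tukey, design = design,
                 feature = feature, alpha = alpha, group_summary = gs,
                 degenerate = FALSE),
            class = "mea_anova")
}

#' @export
print.mea_anova <- function(x, ...) {
  cat(sprintf("<mea_anova> %s ANOVA%s, alpha = %g\n",
              sub("_", "-", x$design),
              if (is.null(x$feature)) "" else paste0(" of ", x$feature),
              x$alpha))
  print(glance(x))
  invisible(x)
}

#' Tidy an `mea_anova` object
#'
#' `tidy()` returns the Tukey HSD group contrasts (estimate, confidence
#' bounds, adjusted p, significance at the object's alpha); `glance()` the
#' ANOVA F statistics and p-values, one row per model term.
#'
#' @param x An `mea_anova` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mea_anova
#' @export
tidy.mea_anova <- function(x, ...) {
  if (is.null(x$tukey)) {
    return(tibble::tibble(contrast = character(), estimate = double(),
                          conf_low = double(), conf_high = double(),
                          adj_p_value = double(), significant = logical()))
  }
  m <- x$tukey$group
  tibble::tibble(contrast = rownames(m), estimate = m[, "diff"],
                 conf_low = m[, "lwr"], conf_high = m[, "upr"],
                 adj_p_value = m[, "p adj"],
                 significant = m[, "p adj"] < x$alpha)
}

#' @rdname tidy.mea_anova
#' @method glance mea_anova
#' @export
glance.mea_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  tibble::tibble(term = terms[keep],
                 df = s[keep, "Df"],
                 statistic = s[keep, "F value"],
                 p_value = s[keep, "Pr(>F)"],
                 significant = s[keep, "Pr(>F)"] < x$alpha,
                 degenerate = x$degenerate)
}

#' Assemble a longitudinal feature table
#'
#' Stacks device-level rows of several [device_features()] tables into the
#' long (device, group, DIV, feature, value) shape that
#' [two_way_anova_tukey()] consumes.
#'
#' @param runs A data frame with columns `group`, `div` and a list column
#'   `features` holding `device_features` tibbles (one per device x DIV).
#' @return A long tibble: `device_id`, `group`, `div`, `feature`, `value`.
#' @export
longitudinal_table <- function(runs) {
  stopifnot(all(c("group", "div", "features") %in% names(runs)))
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    feats <- runs$features[[i]]
    dev <- feats[feats$level == "device", , drop = FALSE]
    vals <- c(percent_active_electrodes = dev$percent_active_electrodes,
              vapply(feature_cols, function(f) as.double(dev[[f]]), 1.0))
    tibble::tibble(device_id = dev$device_id, group = runs$group[i],
                   div = runs$div[i], feature = names(vals),
                   value = unname(vals))
  })
  dplyr::bind_rows(rows)
}
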