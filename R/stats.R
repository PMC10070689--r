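# the two statistical stages: two-way ANOVA + Tukey, Kruskal-Wallis + Dunn

new_stat_result <- function(test, statistic, df, p_value, posthoc, fit = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc, fit = fit),
            class = "vm_stat")
}

#' @export
print.vm_stat <- function(x, ...) {
  cat("<vm_stat>", format_stat(x), "\n")
  if (nrow(x$posthoc) > 0) {
    cat("post-hoc (", nrow(x$posthoc), " contrasts):\n", sep = "")
    print(utils::head(as.data.frame(x$posthoc), 10))
  }
  invisible(x)
}

#' Format a test result the way the study reports it
#'
#' `[F(24, 96) = 7.965, p < 0.0001]` for the ANOVA interaction,
#' `[H(3) = 139.7, p < 0.0001]` for Kruskal-Wallis.
#'
#' @param x a `vm_stat` object.
#' @return character scalar.
#' @export
format_stat <- function(x) {
  stopifnot(inherits(x, "vm_stat"))
  p <- if (x$p_value < 1e-4) "p < 0.0001" else sprintf("p = %.4g", x$p_value)
  if (x$test == "anova2") {
    sprintf("[F(%d, %d) = %.4g, %s]", x$df[1], x$df[2], x$statistic, p)
  } else {
    sprintf("[H(%d) = %.4g, %s]", x$df[1], x$statistic, p)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the post-hoc contrast table of a test result
#' @param x a `vm_stat` object.
#' @param ... unused.
#' @return tibble of contrasts with adjusted p-values.
#' @method tidy vm_stat
#' @export
tidy.vm_stat <- function(x, ...) x$posthoc

#' One-row summary of a test result
#' @param x a `vm_stat` object.
#' @param ... unused.
#' @return one-row tibble: test, statistic, df, p.
#' @method glance vm_stat
#' @export
glance.vm_stat <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 df1 = x$df[1], df2 = ifelse(length(x$df) > 1, x$df[2], NA_integer_),
                 p_value = x$p_value)
}

#' Two-way ANOVA (group x segment) with Tukey post-hoc contrasts
#'
#' Fits `response ~ group * segment` on the per-animal table of one region
#' with sum-to-zero contrasts and type-III sums of squares (so unbalanced
#' cells — the n = 3 day-45 group, cavity-dropped cells — are handled by
#' dropping, not imputing). The headline statistic is the interaction F
#' with (df_interaction, df_within). Post-hoc: Tukey-adjusted pairwise
#' group comparisons within each segment via `emmeans`; by default only
#' the group-vs-sham contrasts are returned (the comparisons the study
#' displays), `full_pairwise = TRUE` keeps all of them.
#'
#' @param data per-animal tibble for one region (columns `group`,
#'   `segment`, and the response).
#' @param response response column name (string).
#' @param full_pairwise keep every pairwise group contrast.
#' @param posthoc compute the Tukey contrasts (disable in large
#'   calibration loops that only need the omnibus F).
#' @return a `vm_stat` object (`test = "anova2"`).
#' @export
anova_tukey <- function(data, response = "vessel_density_per_mm2",
                        full_pairwise = FALSE, posthoc = TRUE) {
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[response]]), ]
  data$group <- factor(data$group, levels = intersect(GROUPS, unique(data$group)))
  data$segment <- factor(data$segment, levels = intersect(SEGMENTS, unique(data$segment)))
  if (nlevels(data$group) < 2 || nlevels(data$segment) < 2)
    abort("anova_tukey needs at least 2 groups and 2 segments")
  empty <- with(data, table(group, segment)) == 0
  if (any(empty)) {
    cells <- which(empty, arr.ind = TRUE)
    abort(paste("empty design cell(s):",
                paste(sprintf("%s:%s", rownames(empty)[cells[, 1]],
                              colnames(empty)[cells[, 2]]), collapse = ", ")))
  }
  fml <- stats::as.formula(paste(response, "~ group * segment"))
  fit <- lm(fml, data = data,
            contrasts = list(group = "contr.sum", segment = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  irow <- grep("group:segment", rownames(a3))
  df_i <- a3$Df[irow]
  df_w <- a3$Df[rownames(a3) == "Residuals"]
  Fv <- a3$`F value`[irow]
  p <- a3$`Pr(>F)`[irow]

  if (posthoc) {
    emm <- emmeans::emmeans(fit, ~ group | segment)
    prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
    ph <- tibble::as_tibble(prs) |>
      dplyr::transmute(contrast = as.character(.data$contrast),
                       segment = as.character(.data$segment),
                       estimate = .data$estimate,
                       adj_p = .data$p.value)
    if (!full_pairwise) ph <- dplyr::filter(ph, grepl("\\bsham\\b", .data$contrast))
  } else {
    ph <- tibble::tibble(contrast = character(), segment = character(),
                         estimate = numeric(), adj_p = numeric())
  }
  new_stat_result("anova2", Fv, c(df_i, df_w), p, ph, fit)
}

#' Dunn's post-hoc test of stochastic dominance between groups
#'
#' Rank-based z statistics on the joint ranking with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12(N - 1))` over tie blocks. Two-sided p-values
#' are multiplicity-adjusted (Bonferroni by default, the convention of
#' Dunn's original procedure and of common statistics software).
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @param p_adjust_method passed to [stats::p.adjust()].
#' @return tibble `contrast, z, p_value, adj_p`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "bonferroni") {
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(factor(g[keep]))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(r)
  ties <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  cmb <- utils::combn(lv, 2)
  z <- apply(cmb, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - ties) * (1 / ns[p[1]] + 1 / ns[p[2]]))
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  pv <- 2 * pnorm(-abs(z))
  tibble::tibble(contrast = paste(cmb[1, ], "-", cmb[2, ]),
                 z = unname(z), p_value = unname(pv),
                 adj_p = p.adjust(pv, p_adjust_method))
}

#' Kruskal-Wallis test with Dunn's post-hoc over design cells
#'
#' Values are compared across the cells of `by` (default the group x
#' segment crossing, so sham/day-2 at T10/T11 gives H with 3 degrees of
#' freedom). The omnibus H uses [stats::kruskal.test()]; pairwise
#' contrasts use [dunn_test()].
#'
#' @param data tidy measurement tibble.
#' @param response value column (string), e.g. `thickness_nm`.
#' @param by columns whose crossing defines the compared cells.
#' @param p_adjust_method multiplicity adjustment for Dunn p-values.
#' @return a `vm_stat` object (`test = "kruskal"`).
#' @export
kruskal_dunn <- function(data, response = "thickness_nm",
                         by = c("group", "segment"),
                         p_adjust_method = "bonferroni") {
  data <- tibble::as_tibble(data)
  cell <- interaction(data[by], drop = TRUE, sep = ":")
  x <- data[[response]]
  tab <- table(cell[!is.na(x)])
  if (length(tab) < 2 || any(tab < 2))
    abort("kruskal_dunn needs >= 2 cells with >= 2 values each")
  if (length(unique(x[!is.na(x)])) == 1)
    abort("all values tied; Kruskal-Wallis is degenerate")
  kw <- kruskal.test(x, cell)
  ph <- dunn_test(x, cell, p_adjust_method)
  new_stat_result("kruskal", unname(kw$statistic),
                  unname(kw$parameter), kw$p.value, ph)
}
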