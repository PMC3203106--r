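# Statistical conventions for the morphometric report tables: mean +/- SD
# summaries, two-sided Student's t-tests (paired when BrdU-exposure
# conditions are the same, e.g. littermates or tissues within a specimen;
# unpaired otherwise), the p < 0.05 asterisk convention, and one-way ANOVA
# across rudiments.  No multiple-testing correction is applied; this is
# stated in the report metadata.

#' Group summaries: mean, SD, n
#'
#' @param table long-format data.frame of measurements.
#' @param groupVars character vector of grouping column names.
#' @param valueVar measurement column name (default `"value"`).
#' @return data.frame with one row per group: grouping columns, `mean`,
#'   `sd` (sample SD, `NA` for n = 1), `n`.
#' @export
summarizeGroups <- function(table, groupVars, valueVar = "value") {
  if (!all(c(groupVars, valueVar) %in% names(table)))
    stop("missing columns")
  g <- interaction(table[groupVars], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(table, g), function(d) {
    out <- d[1, groupVars, drop = FALSE]
    out$mean <- mean(d[[valueVar]])
    out$sd <- stats::sd(d[[valueVar]])
    out$n <- nrow(d)
    out
  }))
  rownames(agg) <- NULL
  agg
}

#' Two-group comparison with the p < 0.05 asterisk convention
#'
#' Two-sided Student's t-test, paired or unpaired.  Unpaired tests assume
#' equal variances (classic Student) by default, matching the reporting
#' convention the package reproduces; Welch's correction is available via
#' `welch = TRUE`.
#'
#' @param x,y numeric samples (equal length required when paired).
#' @param paired paired test (same BrdU-exposure conditions)?
#' @param welch use Welch's unequal-variance correction (unpaired only).
#' @return list with `statistic` (t), `df`, `p.value`, `significant`
#'   (p < 0.05) and `mark` (`"*"` or `""`).
#' @export
compareGroups <- function(x, y, paired = FALSE, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  if (paired && length(x) != length(y))
    stop("paired comparison requires matched samples of equal length")
  if (paired && stats::sd(x - y) == 0) {
    # degenerate pairs: constant difference has no sampling variance
    same <- mean(x - y) == 0
    return(list(statistic = if (same) 0 else sign(mean(x - y)) * Inf,
                df = length(x) - 1, p.value = if (same) 1 else 0,
                significant = !same, mark = if (same) "" else "*"))
  }
  ht <- stats::t.test(x, y, paired = paired,
                      var.equal = !welch && !paired)
  sig <- is.finite(ht$p.value) && ht$p.value < 0.05
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, significant = sig,
       mark = if (sig) "*" else "")
}

#' One-way ANOVA across rudiments
#'
#' Tests whether a quantity differs among the rudiment groups (classically
#' the five rudiment pairs) with a one-way fixed-effects ANOVA.
#'
#' @param table long-format data.frame.
#' @param valueVar,groupVar column names of measurement and group.
#' @return list with `F`, `df` (numerator, denominator) and `p.value`.
#' @export
anovaAcrossRudiments <- function(table, valueVar = "value",
                                 groupVar = "rudiment") {
  v <- table[[valueVar]]; g <- factor(table[[groupVar]])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tabulate(g) < 2)) stop("need >= 2 values per group")
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p.value = s[["Pr(>F)"]][1])
}
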