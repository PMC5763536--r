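# qRT-PCR relative expression (2^-deltaCt against an internal control such as
# a cel-miR-39 spike-in or U6 snRNA) and two-group comparison.

#' Relative expression from Ct values
#'
#' deltaCt = Ct(target) - Ct(internal control); relative expression is
#' 2^-deltaCt. Vectorized over samples.
#'
#' @param target_ct Target-gene Ct value(s), finite and positive.
#' @param control_ct Internal-control Ct value(s), finite and positive.
#' @return Nonnegative relative expression value(s).
#' @examples
#' relative_expression(25, 25)   # 1
#' relative_expression(24, 25)   # 2
#' relative_expression(28, 25)   # 0.125
#' @export
relative_expression <- function(target_ct, control_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(control_ct))) {
    stop("Ct values must be finite")
  }
  if (any(target_ct <= 0) || any(control_ct <= 0)) {
    stop("Ct values must be positive")
  }
  2^-(target_ct - control_ct)
}

#' Compare relative expression between two groups
#'
#' Unpaired two-sided t test: Student's (pooled variance) for equal
#' variances, Welch's otherwise. When `equal_variance = NULL` the choice is
#' made by an F ratio test at the 0.05 level.
#'
#' @param expressions_a,expressions_b Numeric vectors (n >= 2 each) of
#'   relative expression values.
#' @param equal_variance `TRUE` (Student), `FALSE` (Welch) or `NULL`
#'   (auto-select via F test).
#' @return List: `mean_a`, `mean_b`, `t`, `df`, `p`, `equal_variance`.
#' @export
group_compare <- function(expressions_a, expressions_b,
                          equal_variance = NULL) {
  if (length(expressions_a) < 2L || length(expressions_b) < 2L) {
    stop("each group needs at least two observations")
  }
  if (is.null(equal_variance)) {
    equal_variance <- var.test(expressions_a, expressions_b)$p.value >= 0.05
  }
  ht <- t.test(expressions_a, expressions_b, var.equal = equal_variance)
  list(mean_a = mean(expressions_a), mean_b = mean(expressions_b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, equal_variance = equal_variance)
}

#' Analyze a qRT-PCR table
#'
#' @param measurements Data frame with columns `sample`, `group`,
#'   `target_ct`, `control_ct` (two groups expected for the comparison).
#' @param equal_variance Passed to [group_compare()].
#' @return List with `expressions` (the input plus `rel_expr`) and
#'   `comparison` (the [group_compare()] result, `NULL` unless exactly two
#'   groups are present).
#' @export
qpcr_analysis <- function(measurements, equal_variance = NULL) {
  stopifnot(all(c("sample", "group", "target_ct", "control_ct") %in%
                  names(measurements)))
  measurements$rel_expr <- relative_expression(measurements$target_ct,
                                               measurements$control_ct)
  groups <- unique(measurements$group)
  comparison <- NULL
  if (length(groups) == 2L) {
    comparison <- group_compare(
      measurements$rel_expr[measurements$group == groups[1L]],
      measurements$rel_expr[measurements$group == groups[2L]],
      equal_variance = equal_variance
    )
    names(comparison)[1:2] <- c(paste0("mean_", groups[1L]),
                                paste0("mean_", groups[2L]))
  }
  list(expressions = measurements, comparison = comparison)
}
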