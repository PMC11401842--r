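#' Assign PRS tertiles
#'
#' Splits values into three groups at the empirical 1/3 and 2/3 quantiles
#' (order statistics at `round(n/3)` and `round(2n/3)`). Without ties the
#' group sizes differ by at most 1; tied values are always assigned to the
#' lower group, making the assignment deterministic and order-independent.
#' The labelling is location-invariant: adding a constant to all values leaves
#' the groups unchanged.
#'
#' @param prs numeric vector of at least 3 finite values.
#' @return Factor with levels `low`, `intermediate`, `high`, plus the cut
#'   points in attribute `"cut_points"`.
#' @examples
#' table(assign_prs_tertiles(1:9))
#' @export
assign_prs_tertiles <- function(prs) {
  if (!is.numeric(prs) || length(prs) < 3L || any(!is.finite(prs))) {
    stop_config("'prs' must contain at least 3 finite values")
  }
  n <- length(prs)
  if (length(unique(prs)) == 1L) {
    stop_config("tertiles are undefined: all PRS values are identical")
  }
  xs <- sort(prs)
  k1 <- max(1L, round(n / 3))
  k2 <- max(k1, round(2 * n / 3))
  c1 <- xs[k1]
  c2 <- xs[k2]
  lab <- ifelse(prs <= c1, "low", ifelse(prs <= c2, "intermediate", "high"))
  out <- factor(lab, levels = c("low", "intermediate", "high"))
  attr(out, "cut_points") <- c(c1, c2)
  out
}
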