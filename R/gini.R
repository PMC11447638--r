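#' Gini coefficient from a Lorenz curve or raw incomes
#'
#' The Gini coefficient is the percentage of the area between the Lorenz
#' curve (cumulative income share against cumulative population share,
#' poorest first) and the 45-degree line of perfect equality. It is
#' evaluated by the trapezoid rule,
#' \deqn{G = 100 (1 - \sum_i (x_i - x_{i-1})(y_i + y_{i-1})),}
#' where \eqn{(x_i, y_i)} are Lorenz coordinates with
#' \eqn{x_0 = y_0 = 0} and \eqn{x_N = y_N = 1}. 0 is perfect equality; 100
#' maximal inequality.
#'
#' Raw incomes are converted to a Lorenz curve over `N` equal population
#' segments (one per income, sorted ascending), so a finite sample attains
#' \eqn{G < 100} strictly.
#'
#' @param incomes Numeric vector of non-negative incomes; ignored when
#'   `lorenz` is given.
#' @param lorenz Optional two-column matrix/data frame of ordered Lorenz
#'   coordinates (x, y), including the (0, 0) and (1, 1) endpoints.
#' @param percent If `TRUE` (default) return on the 0-100 scale; otherwise
#'   the 0-1 scale.
#' @return The Gini coefficient.
#' @examples
#' gini_coefficient(c(5, 5, 5, 5))   # 0: perfect equality
#' gini_coefficient(c(0, 0, 0, 1))   # 75
#' @export
gini_coefficient <- function(incomes = NULL, lorenz = NULL, percent = TRUE) {
  if (is.null(lorenz)) {
    if (is.null(incomes)) stop("supply incomes or a lorenz curve")
    if (any(!is.finite(incomes))) stop("domain error: non-finite incomes")
    if (any(incomes < 0)) stop("domain error: negative incomes")
    tot <- sum(incomes)
    if (tot == 0) stop("degenerate input: all incomes are zero")
    inc <- sort(incomes)
    n <- length(inc)
    lorenz <- cbind(x = c(0, seq_len(n) / n),
                    y = c(0, cumsum(inc) / tot))
  }
  lorenz <- as.matrix(lorenz)
  x <- lorenz[, 1]
  y <- lorenz[, 2]
  if (x[1] != 0 || y[1] != 0 ||
      abs(x[length(x)] - 1) > 1e-12 || abs(y[length(y)] - 1) > 1e-12) {
    stop("lorenz curve must run from (0,0) to (1,1)")
  }
  if (any(diff(x) <= 0)) stop("lorenz x must be strictly increasing")
  if (any(diff(y) < 0)) stop("lorenz y must be non-decreasing")
  g <- 1 - sum(diff(x) * (y[-1] + y[-length(y)]))
  if (percent) 100 * g else g
}
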