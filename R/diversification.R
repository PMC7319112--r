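#' Net diversification rate from clade size and stem age
#'
#' Method-of-moments stem-age estimator of the net diversification rate
#' (speciation minus extinction, per lineage per Ma):
#' \deqn{r = \frac{1}{t}\,\log\{n(1-\epsilon)+\epsilon\}}
#' where `n` is the number of extant species, `t` the clade's stem age (Ma)
#' and `eps` the assumed relative extinction fraction (extinction/speciation).
#' With `eps = 0` this is `log(n)/t`; a monotypic clade (`n = 1`) always gets
#' rate 0.  The estimator is increasing in `n`, decreasing in `t`, and
#' decreasing in `eps` for `n > 1`.
#'
#' @param n integer species count(s), `>= 1`.
#' @param t stem age(s) in Ma, `> 0`.
#' @param eps relative extinction fraction in `[0, 1)`.
#' @return Net diversification rate(s) per Ma; vectorized over `n` and `t`.
#' @examples
#' net_diversification(10, 34, eps = 0.9)  # log(1.9)/34
#' net_diversification(1, 50, eps = 0.9)   # 0
#' @export
net_diversification <- function(n, t, eps = 0.9) {
  if (any(t <= 0)) stop("stem age 't' must be positive", call. = FALSE)
  if (any(n < 1) || any(n != round(n))) {
    stop("'n' must be a positive integer species count", call. = FALSE)
  }
  if (length(eps) != 1L || eps < 0 || eps >= 1) {
    stop("'eps' must be a single value in [0, 1)", call. = FALSE)
  }
  log(n * (1 - eps) + eps) / t
}
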