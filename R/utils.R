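# Internal sampling helpers shared by the simulators.
#
# A pure-birth (Yule) process started from n cells, observed after an
# interval with integrated per-capita rate L = int lambda(v) dv, has the
# exact transition law  X = n + NegBinomial(n, p) with p = exp(-L)
# (time-change property: a pure-birth process with time-varying rate is a
# deterministically time-changed Yule process).  All lineage growth in the
# package is sampled from this law directly rather than event by event.

.INT_MAX <- 2147483647

# Exact pure-birth transition: n cells, per-cell survival-of-clock p =
# exp(-integrated rate). Vectorised over n and p. Normal approximation is
# used only where the count is so large that the law is indistinguishable
# from it (relative sd < 1e-3).
rpurebirth <- function(n, p) {
  n <- as.numeric(n)
  stopifnot(all(p > 0), all(p <= 1), all(n >= 0))
  out <- n
  todo <- n > 0 & p < 1
  if (!any(todo)) return(out)
  nn <- n[todo]
  pp <- rep_len(p, length(n))[todo]
  big <- nn > 1e6
  res <- numeric(length(nn))
  if (any(!big)) {
    res[!big] <- stats::rnbinom(sum(!big), size = nn[!big], prob = pp[!big])
  }
  if (any(big)) {
    m <- nn[big] * (1 - pp[big]) / pp[big]
    v <- nn[big] * (1 - pp[big]) / pp[big]^2
    res[big] <- pmax(0, round(stats::rnorm(sum(big), m, sqrt(v))))
  }
  out[todo] <- nn + res
  out
}

# Binomial thinning that tolerates counts beyond .Machine's integer range.
rbinom_large <- function(n_draws, size, prob) {
  size <- as.numeric(size)
  out <- numeric(length(size))
  ok <- size < 2e9
  if (any(ok)) out[ok] <- stats::rbinom(sum(ok), size[ok], prob)
  if (any(!ok)) {
    m <- size[!ok] * prob
    out[!ok] <- pmax(0, round(stats::rnorm(sum(!ok), m, sqrt(m * (1 - prob)))))
  }
  out
}

# Exact transition law of a linear birth-death process (per-capita birth b,
# death d) over an interval u, started from n cells. Classical result: each
# ancestor independently leaves 0 descendants with probability alpha, or
# j >= 1 with probability (1 - alpha)(1 - beta) beta^(j-1).
rbirthdeath <- function(n, b, d, u) {
  if (n == 0 || u <= 0) return(n)
  if (abs(b - d) < 1e-12) {
    bt <- b * u
    alpha <- bt / (1 + bt)
    beta <- alpha
  } else {
    e <- exp((b - d) * u)
    alpha <- d * (e - 1) / (b * e - d)
    beta <- b * (e - 1) / (b * e - d)
  }
  k <- stats::rbinom(1, n, 1 - alpha)
  if (k == 0) return(0)
  k + stats::rnbinom(1, size = k, prob = 1 - beta)
}

# Independent per-replicate seeds derived from one root seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .INT_MAX))
  sample.int(.INT_MAX - 1L, n)
}

# Inverse-CDF sample of mutation origin times in an exponentially growing
# phase: density proportional to e^(r t) on [0, tau).
sample_origin_times <- function(n, r, tau) {
  u <- stats::runif(n)
  log(1 + u * expm1(r * tau)) / r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
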