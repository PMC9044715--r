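# Independent oracles, deliberately naive: direct loops and from-scratch
# model refits, sharing no code with the implementation under test.

# Hermans-Rasson statistic by the literal double loop over ordered pairs
hr_oracle <- function(theta) {
  n <- length(theta)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- theta[i] - theta[j]
      total <- total + abs(abs(d) - pi) - pi / 2 -
        2.895 * (abs(sin(d)) - 2 / pi)
    }
  }
  total / n
}

# Sequential Pillai traces by brute force: refit every nested model from
# scratch with lm.fit and difference the explained SSCPs
brute_pillai_traces <- function(theta, formula, data) {
  Y <- cbind(cos(theta), sin(theta))
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  stopifnot(attr(tt, "intercept") == 1)
  explained <- function(rhs_labels) {
    f <- if (length(rhs_labels) == 0) ~ 1 else stats::reformulate(rhs_labels)
    X <- stats::model.matrix(f, data)
    fit <- stats::lm.fit(X, Y)
    crossprod(as.matrix(fit$fitted.values))
  }
  X_full <- stats::model.matrix(tt, data)
  fit_full <- stats::lm.fit(X_full, Y)
  E <- crossprod(as.matrix(fit_full$residuals))
  C_prev <- matrix(0, 2, 2)
  traces <- numeric(length(labels) + 1)
  for (k in 0:length(labels)) {
    C_k <- explained(labels[seq_len(k)])
    H_k <- C_k - C_prev
    traces[k + 1] <- sum(diag(H_k %*% solve(H_k + E)))
    C_prev <- C_k
  }
  stats::setNames(traces, c("(Intercept)", labels))
}

# One-sample Hotelling T-squared test of mean (0, 0) on the embedded
# response, via the classical T2 -> F transform
hotelling_oracle <- function(theta) {
  Y <- cbind(cos(theta), sin(theta))
  n <- nrow(Y)
  m <- colMeans(Y)
  S <- stats::cov(Y)
  T2 <- n * drop(t(m) %*% solve(S) %*% m)
  Fv <- (n - 2) / (2 * (n - 1)) * T2
  list(F = Fv, p = stats::pf(Fv, 2, n - 2, lower.tail = FALSE))
}

# random small dataset with one factor and one covariate
rand_dataset <- function(n = 30, levels = 3) {
  list(
    theta = stats::runif(n, 0, 2 * pi),
    data = data.frame(
      g = factor(sample(letters[seq_len(levels)], n, replace = TRUE)),
      x = stats::rnorm(n)
    )
  )
}

rad <- function(x) angle_sample(x, unit = "radians")
deg <- function(x) angle_sample(x, unit = "degrees")
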