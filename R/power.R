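#' Define a uniformity-testing simulation scenario
#'
#' Bundles a generating distribution, a sample-size grid and the replication
#' settings for [run_uniformity_suite()]. `spec = NULL` means the circular
#' uniform distribution (the type-I error scenario); otherwise any
#' [mixture_spec()] (a single-component mixture gives the unimodal suites).
#'
#' @param name scenario label carried into results.
#' @param spec a [mixture_spec()] or `NULL` for the uniform null.
#' @param sample_sizes increasing vector of positive sample sizes.
#' @param binned aggregate each sample into bins before testing?
#' @param bin_width bin width in degrees (default 10).
#' @param replicates Monte-Carlo replicates per sample size (default 9999).
#' @param alpha significance level (default 0.05); a rejection is `p < alpha`.
#' @return An object of class `"circ_scenario"`.
#' @export
scenario <- function(name, spec = NULL, sample_sizes, binned = FALSE,
                     bin_width = 10, replicates = 9999, alpha = 0.05) {
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 1) || is.unsorted(sample_sizes, strictly = TRUE)) {
    stop("sample_sizes must be positive and strictly increasing")
  }
  if (!is.null(spec) && !inherits(spec, "mixture_spec")) {
    stop("spec must be NULL (uniform) or a mixture_spec")
  }
  structure(
    list(name = name, spec = spec, sample_sizes = sample_sizes,
         binned = binned, bin_width = bin_width,
         replicates = as.integer(replicates), alpha = alpha),
    class = "circ_scenario"
  )
}

# draw an n x reps matrix of angles from the scenario's distribution
.draw_matrix <- function(spec, n, reps) {
  theta <- if (is.null(spec)) stats::runif(n * reps, 0, 2 * pi)
           else rcirc_mixture(spec, n * reps)$angles
  matrix(theta, n, reps)
}

# bin a matrix of radians to centers of width-degree bins (vectorized twin
# of bin_angles)
.bin_matrix <- function(theta, width) {
  deg <- theta * 180 / pi
  ((floor(deg / width + 0.5) * width) %% 360) * pi / 180
}

# Monte-Carlo p-values for observed statistics against a null sample,
# upper tail, ignoring exact ties (the statistics are continuous)
.mc_p_upper <- function(observed, null_sorted) {
  B <- length(null_sorted)
  count_ge <- B - findInterval(observed, null_sorted)
  (1 + count_ge) / (B + 1)
}

# rejection rate of the MC-calibrated test for each column of (Cmat, Smat):
# every replicate gets its own fresh uniform-null p-value sample of size B,
# processed in chunks to bound memory
.mc_calibrated_rejections <- function(Q, ranks, Cmat, Smat, df_error, B, alpha) {
  n <- nrow(Cmat)
  reps <- ncol(Cmat)
  obs <- .theory_p_matrix(Q, ranks, Cmat, Smat, df_error)
  nterms <- nrow(obs)
  chunk <- max(1L, min(reps, as.integer(4e6 / (n * B))))
  reject <- matrix(NA, nterms, reps)
  done <- 0L
  while (done < reps) {
    take <- seq(done + 1L, min(done + chunk, reps))
    theta <- matrix(stats::runif(n * B * length(take), 0, 2 * pi),
                    n, B * length(take))
    null_p <- .theory_p_matrix(Q, ranks, cos(theta), sin(theta), df_error)
    for (t in seq_len(nterms)) {
      np <- matrix(null_p[t, ], B, length(take))
      cnt <- colSums(np <= matrix(obs[t, take], B, length(take), byrow = TRUE))
      reject[t, take] <- (1 + cnt) / (B + 1) < alpha
    }
    done <- done + length(take)
  }
  reject
}

#' Estimate type-I error or power of the uniformity tests
#'
#' For every sample size in the scenario: draw `replicates` samples from the
#' scenario's distribution (optionally binned), apply each requested test,
#' and report the proportion of replicates with `p < alpha` — the type-I
#' error rate when the generator is uniform, the power otherwise.
#'
#' Tests: `"rayleigh"`, `"hr"` (Hermans-Rasson, Monte-Carlo null
#' distribution of the statistic shared within a sample size — the same
#' decision rule as the per-sample Monte-Carlo test at fixed `alpha`),
#' `"manova"` (theory p-value of the intercept-only Pillai test) and
#' `"manova_mc"` (its Monte-Carlo calibrated variant, `B_mc` fresh uniform
#' nulls per replicate). The Hermans-Rasson null is always the continuous
#' uniform, also for binned scenarios — binning sensitivity is precisely
#' what that comparison measures.
#'
#' @param scn a [scenario()].
#' @param tests character subset of
#'   `c("rayleigh", "hr", "manova", "manova_mc")`.
#' @param B_mc calibration replicates per sample for `"manova_mc"`.
#' @param hr_null size of the Hermans-Rasson null reference sample.
#' @return A data frame with columns `scenario`, `test`, `term`, `n`,
#'   `replicates`, `rate`.
#' @export
run_uniformity_suite <- function(scn,
                                 tests = c("rayleigh", "hr", "manova", "manova_mc"),
                                 B_mc = 999, hr_null = 2000) {
  stopifnot(inherits(scn, "circ_scenario"))
  tests <- match.arg(tests, several.ok = TRUE)
  reps <- scn$replicates
  alpha <- scn$alpha
  out <- list()
  for (n in scn$sample_sizes) {
    theta <- .draw_matrix(scn$spec, n, reps)
    if (scn$binned) theta <- .bin_matrix(theta, scn$bin_width)
    Cmat <- cos(theta)
    Smat <- sin(theta)
    Q1 <- matrix(1 / sqrt(n), n, 1)
    for (test in tests) {
      rate <- switch(test,
        rayleigh = {
          z <- n * (colMeans(Cmat)^2 + colMeans(Smat)^2)
          mean(.rayleigh_p(z, n) < alpha)
        },
        manova = {
          p <- .theory_p_matrix(Q1, 1L, Cmat, Smat, n - 1L)
          mean(p[1, ] < alpha)
        },
        manova_mc = {
          rej <- .mc_calibrated_rejections(Q1, 1L, Cmat, Smat, n - 1L,
                                           B_mc, alpha)
          mean(rej[1, ])
        },
        hr = {
          obs <- vapply(seq_len(reps), function(j) .hr_stat(theta[, j]),
                        numeric(1))
          null_sorted <- sort(vapply(
            seq_len(hr_null),
            function(b) .hr_stat(stats::runif(n, 0, 2 * pi)),
            numeric(1)
          ))
          mean(.mc_p_upper(obs, null_sorted) < alpha)
        }
      )
      out[[length(out) + 1L]] <- data.frame(
        scenario = scn$name, test = test, term = "intercept", n = n,
        replicates = reps, rate = rate, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Define the two-group by five-age simulation design
#'
#' A hypothetical displacement study: two groups of animals observed at
#' ages 1 to 5, where homeward orientation becomes more clustered with age.
#' Each group has a mean direction and a concentration schedule linear in
#' age: `kappa(age) = start + (end - start) * (age - 1) / 4`.
#'
#' @param kappa1,kappa2 length-2 vectors `c(start, end)` of von Mises
#'   concentrations at ages 1 and 5 for groups 1 and 2 (all `>= 0`).
#' @param mu1_deg,mu2_deg mean directions of the two groups, degrees.
#' @return An object of class `"hypothetical_design"`.
#' @examples
#' # clustering grows 0 -> 2 with age, groups oriented 180 degrees apart
#' hypothetical_design(kappa1 = c(0, 2), kappa2 = c(0, 2),
#'                     mu1_deg = 0, mu2_deg = 180)
#' @export
hypothetical_design <- function(kappa1 = c(0, 2), kappa2 = c(0, 2),
                                mu1_deg = 0, mu2_deg = 0) {
  stopifnot(length(kappa1) == 2, length(kappa2) == 2)
  if (any(c(kappa1, kappa2) < 0)) stop("kappa must be nonnegative everywhere")
  structure(
    list(kappa1 = kappa1, kappa2 = kappa2,
         mu1 = mu1_deg * pi / 180, mu2 = mu2_deg * pi / 180,
         ages = 1:5),
    class = "hypothetical_design"
  )
}

.kappa_at <- function(schedule, age) {
  schedule[1] + (schedule[2] - schedule[1]) * (age - 1) / 4
}

#' Per-term power in the group-by-age scenario
#'
#' For each total sample size: allocate equally over the 10 group-by-age
#' cells, simulate every cell from its von Mises distribution, fit the
#' MANOVA `~ age + group` (age as a linear covariate, group as a factor)
#' and record rejections per term. The Rayleigh and Hermans-Rasson tests
#' run on the pooled angles for the intercept (overall non-uniformity)
#' comparison.
#'
#' @param design a [hypothetical_design()].
#' @param n_total total sample sizes, each divisible by 10.
#' @param replicates Monte-Carlo replicates (default 9999).
#' @param alpha significance level; rejection is `p < alpha`.
#' @param tests subset of `c("manova", "manova_mc", "rayleigh", "hr")`.
#' @param B_mc calibration replicates for `"manova_mc"`.
#' @param hr_null size of the Hermans-Rasson null reference sample.
#' @return A data frame with columns `scenario`, `test`, `term`
#'   (`intercept`, `age` or `group`), `n`, `replicates`, `rate`.
#' @export
run_hypothetical_suite <- function(design, n_total = c(10, 20, 30, 50, 100),
                                   replicates = 9999, alpha = 0.05,
                                   tests = c("manova", "rayleigh", "hr"),
                                   B_mc = 999, hr_null = 2000) {
  stopifnot(inherits(design, "hypothetical_design"))
  tests <- match.arg(tests, c("manova", "manova_mc", "rayleigh", "hr"),
                     several.ok = TRUE)
  if (any(n_total %% 10 != 0)) {
    stop("every n_total must be divisible by 10 (2 groups x 5 ages)")
  }
  out <- list()
  for (n in as.integer(n_total)) {
    m <- n %/% 10L
    cells <- expand.grid(age = design$ages, group = c("g1", "g2"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data <- cells[rep(seq_len(nrow(cells)), each = m), , drop = FALSE]
    rownames(data) <- NULL
    des <- build_design(data, ~ age + group)
    basis <- .seq_basis(des$X, des$assign, des$term_labels)
    df_error <- n - basis$ranks[length(basis$ranks)]
    theta <- matrix(NA_real_, n, replicates)
    row0 <- 0L
    for (i in seq_len(nrow(cells))) {
      g <- cells$group[i]
      kappa <- .kappa_at(if (g == "g1") design$kappa1 else design$kappa2,
                         cells$age[i])
      mu <- if (g == "g1") design$mu1 else design$mu2
      theta[row0 + seq_len(m), ] <-
        rcirc_vonmises(m * replicates, mu, kappa)$angles
      row0 <- row0 + m
    }
    Cmat <- cos(theta)
    Smat <- sin(theta)
    terms <- des$term_labels
    terms[terms == "(Intercept)"] <- "intercept"
    for (test in tests) {
      if (test %in% c("manova", "manova_mc")) {
        if (test == "manova") {
          P <- .theory_p_matrix(basis$Q, basis$ranks, Cmat, Smat, df_error)
          rates <- rowMeans(P < alpha)
        } else {
          rej <- .mc_calibrated_rejections(basis$Q, basis$ranks, Cmat, Smat,
                                           df_error, B_mc, alpha)
          rates <- rowMeans(rej)
        }
        for (t in seq_along(terms)) {
          out[[length(out) + 1L]] <- data.frame(
            scenario = "hypothetical", test = test, term = terms[t], n = n,
            replicates = replicates, rate = rates[t], stringsAsFactors = FALSE
          )
        }
      } else {
        rate <- if (test == "rayleigh") {
          z <- n * (colMeans(Cmat)^2 + colMeans(Smat)^2)
          mean(.rayleigh_p(z, n) < alpha)
        } else {
          obs <- vapply(seq_len(replicates), function(j) .hr_stat(theta[, j]),
                        numeric(1))
          null_sorted <- sort(vapply(
            seq_len(hr_null),
            function(b) .hr_stat(stats::runif(n, 0, 2 * pi)),
            numeric(1)
          ))
          mean(.mc_p_upper(obs, null_sorted) < alpha)
        }
        out[[length(out) + 1L]] <- data.frame(
          scenario = "hypothetical", test = test, term = "intercept", n = n,
          replicates = replicates, rate = rate, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate simulation results with binomial confidence intervals
#'
#' @param results data frame(s) from [run_uniformity_suite()] or
#'   [run_hypothetical_suite()] (rows are concatenated).
#' @param conf confidence level for the normal-approximation binomial
#'   interval (default 0.95).
#' @return The combined table sorted by scenario, test, term and `n`, with
#'   `se`, `ci_lo`, `ci_hi` columns appended; rates are clamped to `[0, 1]`.
#' @export
summarize_suite <- function(results, conf = 0.95) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  cols <- c("scenario", "test", "term", "n", "replicates", "rate")
  if (is.null(results) || nrow(results) == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols) + 3)),
      c(cols, "se", "ci_lo", "ci_hi")
    )
    return(out)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  results$se <- sqrt(results$rate * (1 - results$rate) / results$replicates)
  results$ci_lo <- pmax(0, results$rate - z * results$se)
  results$ci_hi <- pmin(1, results$rate + z * results$se)
  results[order(results$scenario, results$test, results$term, results$n), ,
          drop = FALSE]
}
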