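#' Partial eta-squared per term and response channel
#'
#' For each model term and each response channel (cos, sin), the partial
#' eta-squared `SS_term / (SS_term + SS_residual)` of the underlying
#' univariate ANOVA, where `SS_term` is the channel's diagonal entry of the
#' term's sequential hypothesis SSCP. Used to pre-rank candidate variables
#' before the exhaustive AIC comparison.
#'
#' @param fit a `"circ_mlm"` from [fit_mlm()] or the `fit` element of a
#'   [circular_manova()] result.
#' @return A data frame with columns `term`, `channel`, `eta_sq` and
#'   `degenerate` (`TRUE` when the channel's residual SS is zero).
#' @export
eta_squared_per_response <- function(fit) {
  if (inherits(fit, "circ_manova")) fit <- fit$fit
  if (!inherits(fit, "circ_mlm")) stop("fit must be a circ_mlm or circ_manova")
  channels <- c("cos", "sin")
  rows <- lapply(seq_along(fit$term_labels), function(t) {
    ss_term <- diag(fit$H[[t]])
    ss_res <- diag(fit$E)
    degen <- ss_res <= 1e-12 * max(1, sum(diag(crossprod(fit$Y))))
    data.frame(
      term = fit$term_labels[t], channel = channels,
      eta_sq = ifelse(degen & ss_term > 0, 1, ss_term / (ss_term + ss_res)),
      degenerate = degen, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Mean Gaussian AIC of the two response channels
#'
#' Each channel (cos, sin) is an ordinary Gaussian linear model sharing the
#' design; its AIC is `n*log(2*pi*RSS/n) + n + 2*(k + 1)` with `k` design
#' columns (the `+1` counts the residual variance). The model score is the
#' mean of the two channel AICs.
#'
#' @param fit a `"circ_mlm"` or `"circ_manova"`.
#' @return The mean AIC (a single number; `-Inf` with a warning if a
#'   channel has zero residual sum of squares).
#' @export
mean_aic <- function(fit) {
  if (inherits(fit, "circ_manova")) fit <- fit$fit
  if (!inherits(fit, "circ_mlm")) stop("fit must be a circ_mlm or circ_manova")
  n <- fit$n
  k <- ncol(fit$X)
  rss <- diag(fit$E)
  if (any(rss <= 0)) {
    warning("zero residual sum of squares: AIC is -Inf")
    return(-Inf)
  }
  mean(n * log(2 * pi * rss / n) + n + 2 * (k + 1))
}

#' Two-stage eta-squared / AIC model selection
#'
#' Reduces a set of candidate explanatory variables in two stages, the
#' procedure used for the real-data analyses: (1) fit the full model with
#' every candidate and order candidates by their eta-squared (aggregated
#' over the cos and sin channels), keeping the first `top_n`; (2) fit
#' every subset of the retained candidates (always including the
#' intercept) and rank the models by mean AIC, ties broken by fewer terms
#' then lexicographically.
#'
#' Interaction terms are not generated automatically; list them explicitly
#' (e.g. `"age:treatment"`) among the candidates.
#'
#' @param sample an [angle_sample()].
#' @param data data frame of explanatory variables.
#' @param candidates character vector of candidate terms (column names or
#'   interaction terms). May be empty, in which case the intercept-only
#'   model is returned trivially.
#' @param top_n how many candidates survive the eta-squared screen
#'   (default all; capped at 15 so the `2^top_n` enumeration stays
#'   tractable).
#' @param aggregate how to pool a term's two channel eta-squares for
#'   ordering: `"mean"` (default) or `"max"`.
#' @return An object of class `"circ_selection"`: `eta_table`,
#'   `candidate_order`, `aic_table` (all subsets, ascending mean AIC) and
#'   `best` (the winning formula).
#' @export
select_model <- function(sample, data, candidates = character(),
                         top_n = length(candidates),
                         aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  sample <- angle_sample(sample)
  candidates <- unique(as.character(candidates))
  if (top_n > length(candidates)) top_n <- length(candidates)
  if (top_n > 15) stop("top_n > 15: 2^top_n model fits would be intractable")
  eta_table <- NULL
  kept <- character()
  if (length(candidates) > 0) {
    # the sequential partition is order dependent; fit the screening model
    # with candidates in sorted order so the screen ignores input order
    full <- circular_manova(
      sample, stats::reformulate(sort(candidates)), data
    )
    eta_table <- eta_squared_per_response(full$fit)
    cand_eta <- vapply(candidates, function(tm) {
      v <- eta_table$eta_sq[eta_table$term == tm]
      if (aggregate == "mean") mean(v) else max(v)
    }, numeric(1))
    kept <- names(sort(cand_eta, decreasing = TRUE))[seq_len(top_n)]
  }
  subsets <- .all_subsets(kept)
  rows <- lapply(subsets, function(terms) {
    f <- if (length(terms) == 0) ~ 1 else stats::reformulate(terms)
    m <- circular_manova(sample, f, data)
    data.frame(
      model = if (length(terms) == 0) "(intercept only)"
              else paste(terms, collapse = " + "),
      n_terms = length(terms), mean_aic = mean_aic(m$fit),
      stringsAsFactors = FALSE
    )
  })
  aic_table <- do.call(rbind, rows)
  ord <- order(aic_table$mean_aic, aic_table$n_terms, aic_table$model)
  aic_table <- aic_table[ord, , drop = FALSE]
  rownames(aic_table) <- NULL
  best_terms <- subsets[[ord[1]]]
  best <- if (length(best_terms) == 0) ~ 1 else stats::reformulate(best_terms)
  structure(
    list(eta_table = eta_table, candidate_order = kept,
         aic_table = aic_table, best = best),
    class = "circ_selection"
  )
}

# all subsets of a term set, in a stable order (empty set first); the
# subset keeps the screened candidate order within each model
.all_subsets <- function(terms) {
  k <- length(terms)
  if (k == 0) return(list(character()))
  lapply(seq_len(2^k) - 1L, function(mask) {
    terms[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
  })
}

#' @export
print.circ_selection <- function(x, digits = 4, ...) {
  cat("Two-stage eta-squared / AIC model selection\n")
  if (length(x$candidate_order) > 0) {
    cat("Candidates retained after eta-squared screen (in order):\n  ",
        paste(x$candidate_order, collapse = ", "), "\n")
  }
  cat(sprintf("Models compared: %d\n", nrow(x$aic_table)))
  cat("Best model:", deparse(x$best), "\n\nTop of the AIC ranking:\n")
  tab <- utils::head(x$aic_table, 8)
  tab$mean_aic <- signif(tab$mean_aic, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
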