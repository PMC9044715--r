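#' Read a CSV of angles and covariates
#'
#' Reads a flat table with one angular response column plus any number of
#' explanatory columns. Rows with a missing or unparseable angle are
#' dropped with a warning giving their line numbers. Non-numeric columns
#' become factors downstream; numeric columns are treated as covariates
#' unless named in `factors`.
#'
#' @param path path to a CSV file with a header row.
#' @param angle_col name of the angle column (default `"angle"`).
#' @param unit `"degrees"` (default) or `"radians"`.
#' @param axial apply [axial_transform()] after reading?
#' @param factors character vector of numeric columns to coerce to factor.
#' @return A list with `sample` (an [angle_sample()]), `data` (the
#'   remaining columns, rows aligned with the sample) and `n_dropped`.
#' @export
read_angle_table <- function(path, angle_col = "angle",
                             unit = c("degrees", "radians"),
                             axial = FALSE, factors = character()) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop(sprintf("empty file: %s", path))
  if (!angle_col %in% names(raw)) {
    stop(sprintf("angle column '%s' not found; available columns: %s",
                 angle_col, paste(names(raw), collapse = ", ")))
  }
  ang <- suppressWarnings(as.numeric(raw[[angle_col]]))
  bad <- which(!is.finite(ang))
  if (length(bad) > 0) {
    warning(sprintf(
      "dropped %d row(s) with missing/unparseable angle (data line %s)",
      length(bad), paste(bad, collapse = ", ")
    ))
    raw <- raw[-bad, , drop = FALSE]
    ang <- ang[-bad]
  }
  if (length(ang) == 0) stop("no parseable angles in file")
  sample <- angle_sample(ang, unit = unit)
  if (axial) sample <- axial_transform(sample)
  data <- raw[, setdiff(names(raw), angle_col), drop = FALSE]
  for (v in intersect(factors, names(data))) data[[v]] <- factor(data[[v]])
  rownames(data) <- NULL
  list(sample = sample, data = data, n_dropped = length(bad))
}

#' Write a simulated dataset to CSV
#'
#' Deterministic given `seed`. Kinds mirror the simulation study:
#' `uniform`; `vm` (von Mises, params `mu_deg`, `kappa`); `wsn` (wrapped
#' skew normal, params `xi`, `omega`, `alpha`); `bimodal` / `trimodal`
#' (equal-weight von Mises mixtures, params `mu_deg` vector and `kappa`);
#' `hypothetical` (the two-group by five-age design of
#' [hypothetical_design()], `n` divisible by 10, extra columns `group`
#' and `age`).
#'
#' @param kind one of `"uniform"`, `"vm"`, `"wsn"`, `"bimodal"`,
#'   `"trimodal"`, `"hypothetical"`.
#' @param path output CSV path.
#' @param n number of rows.
#' @param seed RNG seed recorded into the draw.
#' @param params named list of distribution parameters (see above).
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind, path, n, seed = 1, params = list()) {
  kinds <- c("uniform", "vm", "wsn", "bimodal", "trimodal", "hypothetical")
  if (!kind %in% kinds) {
    stop(sprintf("invalid kind '%s'; must be one of %s", kind,
                 paste(kinds, collapse = ", ")))
  }
  set.seed(seed)
  get_par <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  if (kind == "hypothetical") {
    if (n %% 10 != 0) stop("hypothetical fixture needs n divisible by 10")
    design <- hypothetical_design(
      kappa1 = get_par("kappa1", c(0, 2)), kappa2 = get_par("kappa2", c(0, 2)),
      mu1_deg = get_par("mu1_deg", 0), mu2_deg = get_par("mu2_deg", 0)
    )
    m <- n %/% 10L
    cells <- expand.grid(age = design$ages, group = c("g1", "g2"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- cells[rep(seq_len(nrow(cells)), each = m), , drop = FALSE]
    theta <- unlist(lapply(seq_len(nrow(cells)), function(i) {
      kappa <- .kappa_at(
        if (cells$group[i] == "g1") design$kappa1 else design$kappa2,
        cells$age[i]
      )
      mu <- if (cells$group[i] == "g1") design$mu1 else design$mu2
      rcirc_vonmises(m, mu, kappa)$angles
    }))
    out <- data.frame(angle_deg = theta * 180 / pi,
                      group = df$group, age = df$age)
  } else {
    sample <- switch(kind,
      uniform = rcirc_uniform(n),
      vm = rcirc_vonmises(n, get_par("mu_deg", 0) * pi / 180,
                          get_par("kappa", 1)),
      wsn = rcirc_wsn(n, get_par("xi", 0), get_par("omega", 2),
                      get_par("alpha", 30)),
      bimodal = rcirc_mixture(
        vm_mixture(get_par("mu_deg", c(0, 180)), get_par("kappa", 1)), n
      ),
      trimodal = rcirc_mixture(
        vm_mixture(get_par("mu_deg", c(0, 120, 240)), get_par("kappa", 1)), n
      )
    )
    out <- data.frame(angle_deg = sample$angles * 180 / pi)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# tidy term table -> TSV or JSON text
.format_table <- function(table, format = c("tsv", "json"), meta = list()) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::toJSON(c(meta, list(results = table)), auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")
  } else {
    con <- textConnection("out", "w", local = TRUE)
    if (length(meta) > 0) {
      writeLines(sprintf("# %s: %s", names(meta),
                         vapply(meta, function(x) paste(format(x), collapse = " "),
                                character(1))), con)
    }
    utils::write.table(table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paste(out, collapse = "\n")
  }
}
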