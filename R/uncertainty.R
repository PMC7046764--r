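#' Pedigree-matrix data-quality scores
#'
#' The six ordinal indicators of the pedigree matrix used to express
#' life-cycle inventory data quality: reliability, completeness, temporal
#' correlation, geographical correlation, technological correlation and
#' sample size, each scored 1 (best) to 5 (worst).
#'
#' @param reliability,completeness,temporal,geographical,technological,sample_size
#'   integer scores in 1..5.
#' @return a `pedigree_scores` list.
#' @export
pedigree_scores <- function(reliability = 1L, completeness = 1L,
                            temporal = 1L, geographical = 1L,
                            technological = 1L, sample_size = 1L) {
  s <- c(reliability = reliability, completeness = completeness,
         temporal = temporal, geographical = geographical,
         technological = technological, sample_size = sample_size)
  if (any(s < 1 | s > 5 | s != round(s))) {
    stop("pedigree scores must be integers in 1..5", call. = FALSE)
  }
  s <- stats::setNames(as.integer(s), names(s))
  structure(as.list(s), class = "pedigree_scores")
}

#' Load the pedigree indicator-to-factor lookup table
#'
#' Reads the shipped table mapping each pedigree indicator score to a
#' lognormal uncertainty factor (geometric standard deviation contribution).
#'
#' @param path optional path to an alternative table (CSV with columns
#'   `indicator`, `score`, `factor`).
#' @return data.frame with columns `indicator`, `score`, `factor`.
#' @export
pedigree_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pedigree_factors.csv",
                        package = "palmghg", mustWork = TRUE)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Combined pedigree uncertainty factor
#'
#' Translates six pedigree scores into a single lognormal geometric standard
#' deviation by combining the per-indicator factors f_i from the lookup
#' table: `gsd = exp(sqrt(sum(ln(f_i)^2)))`. All scores at 1 give gsd = 1 (no
#' added uncertainty).
#'
#' @param scores a [pedigree_scores()].
#' @param table lookup table from [pedigree_table()].
#' @return geometric standard deviation (>= 1).
#' @export
pedigree_factor <- function(scores, table = pedigree_table()) {
  stopifnot(inherits(scores, "pedigree_scores"))
  f <- vapply(names(scores), function(ind) {
    row <- table$indicator == ind & table$score == scores[[ind]]
    if (!any(row)) stop("no factor for ", ind, " score ", scores[[ind]],
                        call. = FALSE)
    table$factor[row][1]
  }, numeric(1))
  exp(sqrt(sum(log(f)^2)))
}

#' Parameter distributions for Monte Carlo propagation
#'
#' Tag a parameter with its sampling distribution. `dist_normal` uses an
#' absolute standard deviation, `dist_normal_rel` a standard deviation
#' expressed as a fraction of the central value (the convention used for
#' NEE: 5% of the measured value), `dist_lognormal` a geometric standard
#' deviation around the central value as geometric mean (the pedigree
#' convention).
#'
#' @param mean central (deterministic) value.
#' @param sd absolute standard deviation.
#' @param sd_fraction standard deviation as a fraction of `|mean|`.
#' @param gsd geometric standard deviation (>= 1), e.g. from
#'   [pedigree_factor()].
#' @return a `mc_dist` list.
#' @name mc_dist
NULL

#' @rdname mc_dist
#' @export
dist_normal <- function(mean, sd) {
  structure(list(dist = "normal", mean = mean, sd = sd), class = "mc_dist")
}

#' @rdname mc_dist
#' @export
dist_normal_rel <- function(mean, sd_fraction) {
  structure(list(dist = "normal_rel", mean = mean,
                 sd_fraction = sd_fraction), class = "mc_dist")
}

#' @rdname mc_dist
#' @export
dist_lognormal <- function(mean, gsd) {
  if (gsd < 1) stop("`gsd` must be >= 1", call. = FALSE)
  if (mean <= 0) stop("lognormal parameters must be positive", call. = FALSE)
  structure(list(dist = "lognormal", mean = mean, gsd = gsd),
            class = "mc_dist")
}

.draw_mc <- function(d, n) {
  switch(d$dist,
    normal = stats::rnorm(n, d$mean, d$sd),
    normal_rel = stats::rnorm(n, d$mean, abs(d$mean) * d$sd_fraction),
    lognormal = stats::rlnorm(n, meanlog = log(d$mean),
                              sdlog = log(d$gsd)),
    stop("unknown distribution tag: ", d$dist, call. = FALSE)
  )
}

#' Monte Carlo uncertainty specification
#'
#' @param params named list of [mc_dist] parameter distributions.
#' @param n_iterations number of Monte Carlo iterations (>= 1); the analysis
#'   default is 1000.
#' @param seed integer RNG seed.
#' @param report_percentiles two ordered percentiles in (0, 100) to report;
#'   default the 25th and 75th.
#' @return an `uncertainty_spec` list.
#' @export
uncertainty_spec <- function(params, n_iterations = 1000L, seed = 1L,
                             report_percentiles = c(25, 75)) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (length(report_percentiles) != 2L ||
      any(report_percentiles <= 0 | report_percentiles >= 100) ||
      diff(report_percentiles) <= 0) {
    stop("`report_percentiles` must be two ordered values in (0, 100)",
         call. = FALSE)
  }
  if (!all(vapply(params, inherits, logical(1), "mc_dist"))) {
    stop("all `params` entries must be mc_dist objects", call. = FALSE)
  }
  structure(
    list(params = params, n_iterations = as.integer(n_iterations),
         seed = as.integer(seed), report_percentiles = report_percentiles),
    class = "uncertainty_spec"
  )
}

#' Run a Monte Carlo uncertainty propagation
#'
#' Draws `n_iterations` independent parameter sets from the distributions in
#' `uspec`, evaluates `model` on each (a function taking a named list of
#' parameter values and returning a named numeric vector of outputs), and
#' summarizes each output by mean, median and the requested percentiles.
#' Deterministic under a fixed seed. Draws on which the model errors are
#' excluded and counted; more than 1% failures aborts the run.
#'
#' @param model function(named list) -> named numeric vector.
#' @param uspec an [uncertainty_spec()].
#' @return an `mc_summary`: data.frame with one row per model output
#'   (`output`, `mean`, `median`, `p_lo`, `p_hi`, `sd`) plus attributes
#'   `n_ok`, `n_failed` and `draws` (matrix of parameter draws).
#' @export
run_mc <- function(model, uspec) {
  stopifnot(inherits(uspec, "uncertainty_spec"))
  set.seed(uspec$seed)
  n <- uspec$n_iterations
  draws <- vapply(uspec$params, .draw_mc, numeric(n), n = n)
  if (n == 1L) draws <- matrix(draws, nrow = 1,
                               dimnames = list(NULL, names(uspec$params)))
  results <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    par_i <- as.list(draws[i, ])
    res <- tryCatch(model(par_i), error = function(e) NULL)
    if (is.null(res)) next
    results[[i]] <- res
    ok[i] <- TRUE
  }
  failed <- sum(!ok)
  if (failed > 0.01 * n) {
    stop(sprintf("%d of %d model evaluations failed (> 1%%)", failed, n),
         call. = FALSE)
  }
  mat <- do.call(rbind, results[ok])
  pr <- uspec$report_percentiles / 100
  out <- data.frame(
    output = colnames(mat),
    mean = colMeans(mat),
    median = apply(mat, 2, stats::median),
    p_lo = apply(mat, 2, stats::quantile, probs = pr[1]),
    p_hi = apply(mat, 2, stats::quantile, probs = pr[2]),
    sd = apply(mat, 2, stats::sd),
    row.names = NULL
  )
  attr(out, "n_ok") <- sum(ok)
  attr(out, "n_failed") <- failed
  attr(out, "percentiles") <- uspec$report_percentiles
  attr(out, "draws") <- draws
  class(out) <- c("mc_summary", "data.frame")
  out
}

#' @export
print.mc_summary <- function(x, ...) {
  p <- attr(x, "percentiles")
  cat(sprintf(
    "<mc_summary> %d iterations (%d failed), percentiles %g/%g\n",
    attr(x, "n_ok") + attr(x, "n_failed"), attr(x, "n_failed"), p[1], p[2]
  ))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
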