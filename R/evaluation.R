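#' Score variance estimators against the Monte Carlo truth
#'
#' For every method, pools the per-replicate per-center errors
#' `err = estimate - truth` and reports `bias = mean(err)`,
#' `variance = mean((err - bias)^2)` (population denominator),
#' `mse = mean(err^2)`; under these conventions `mse = bias^2 + variance`
#' exactly. The sample-denominator variance is reported alongside as
#' `variance_sample`.
#'
#' Two variance summaries are reported: `variance` (population variance of
#' the pooled errors, the decomposition partner of `mse`) and
#' `variance_across_reps` (mean over centers of the replicate-to-replicate
#' sampling variance of the estimates, requiring a `rep` column) — the
#' latter isolates estimator stability from between-center systematic
#' differences.
#'
#' @param estimates data.frame with columns `method`, `center_id`, `est`
#'   (the estimated `Var(Log-SIR_c)`) and optionally `rep`.
#' @param truth data.frame with `center_id` and `true_var` (see
#'   [monte_carlo_true_variance()]).
#' @return data.frame of class `eval_report`: one row per method with
#'   `bias`, `variance`, `mse`, `variance_sample`, `variance_across_reps`,
#'   `n_obs`; the per-center breakdown is attached as attribute
#'   `"by_center"`.
#' @export
evaluate_methods <- function(estimates, truth) {
  stopifnot(all(c("method", "center_id", "est") %in% names(estimates)),
            all(c("center_id", "true_var") %in% names(truth)))
  m <- match(estimates$center_id, truth$center_id)
  if (anyNA(m)) {
    missing <- unique(estimates$center_id[is.na(m)])
    stop(sprintf("no truth entry for center(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tv <- truth$true_var[m]
  if (anyNA(tv)) {
    missing <- unique(estimates$center_id[is.na(tv)])
    stop(sprintf("truth is flagged missing for center(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  err <- estimates$est - tv
  ok <- !is.na(err)

  methods <- unique(as.character(estimates$method))
  rows <- lapply(methods, function(me) {
    sel <- ok & estimates$method == me
    e <- err[sel]
    if (length(e) < 2L)
      stop(sprintf("method '%s' needs >= 2 estimates", me), call. = FALSE)
    bias <- mean(e)
    vpop <- mean((e - bias)^2)
    v_reps <- if ("rep" %in% names(estimates)) {
      per_center <- tapply(estimates$est[sel], estimates$center_id[sel],
                           function(x) if (length(x) >= 2L) stats::var(x)
                                       else NA_real_)
      mean(per_center, na.rm = TRUE)
    } else NA_real_
    data.frame(method = me, bias = bias, variance = vpop,
               mse = mean(e^2), variance_sample = stats::var(e),
               variance_across_reps = v_reps,
               n_obs = length(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  by_center <- stats::aggregate(
    err[ok],
    by = list(method = estimates$method[ok], center_id = estimates$center_id[ok]),
    FUN = function(e) c(bias = mean(e), mse = mean(e^2)))
  by_center <- data.frame(by_center[1:2], unclass(by_center[[3]]))
  attr(out, "by_center") <- by_center
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Estimator performance vs Monte Carlo truth",
      "(variance uses the population denominator; mse = bias^2 + variance)\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Consistency summary across center-size tiers
#'
#' Summarizes per-method absolute error `|est - truth|` at each center-size
#' tier and reports the Kendall rank correlation of the tier median error
#' with size (a consistent estimator should trend negative).
#'
#' @param estimates data.frame with columns `method`, `n_c` (tier),
#'   `center_id`, `est`, `true_var`.
#' @return list with `tiers` (method x tier median absolute errors) and
#'   `trend` (per-method Kendall tau, `NA` when undefined, e.g. constant
#'   errors).
#' @export
consistency_table <- function(estimates) {
  stopifnot(all(c("method", "n_c", "est", "true_var") %in% names(estimates)))
  tiers_n <- sort(unique(estimates$n_c))
  if (length(tiers_n) < 3L)
    stop("at least 3 size tiers are required", call. = FALSE)
  abs_err <- abs(estimates$est - estimates$true_var)
  tiers <- stats::aggregate(abs_err,
                            by = list(method = estimates$method, n_c = estimates$n_c),
                            FUN = stats::median)
  names(tiers)[3] <- "median_abs_error"
  trend <- vapply(unique(as.character(estimates$method)), function(me) {
    t <- tiers[tiers$method == me, ]
    if (length(unique(t$median_abs_error)) < 2L) return(NA_real_)
    suppressWarnings(stats::cor(t$n_c, t$median_abs_error, method = "kendall"))
  }, numeric(1))
  list(tiers = tiers, trend = trend)
}

#' Write the estimator-performance table
#'
#' Columns `method,bias,variance,mse`.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report[, c("method", "bias", "variance", "mse")],
                   path, row.names = FALSE)
  invisible(path)
}
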