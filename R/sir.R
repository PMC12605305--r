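#' Per-center observed and expected counts and Log-SIR
#'
#' Aggregates observed outcomes and model-based predicted probabilities into
#' each center's observed count `O_c = sum(y_i)`, expected count
#' `E_c = sum(p_hat_i)` and `log_sir = log(O_c / E_c)`. The ratio is the
#' standardized incidence ratio of indirect standardization; results are
#' reported on the natural log scale throughout.
#'
#' @param cohort cohort data.frame with `center_id` and `y`.
#' @param p_hat per-patient predicted probabilities aligned 1:1 with cohort
#'   rows (use [predict_probabilities()] with `mode = "marginal"`).
#' @param correction `"none"` leaves `log_sir` `NA` (flagged undefined) for
#'   centers with `O = 0`; `"halves"` adds 0.5 to both O and E before the
#'   log (simulation-harness use).
#' @return data.frame of class `center_summary` with columns `center_id`,
#'   `n`, `O`, `E`, `log_sir`, `defined`.
#' @export
summarize_centers <- function(cohort, p_hat,
                              correction = c("none", "halves")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(cohort), all(c("center_id", "y") %in% names(cohort)))
  if (length(p_hat) != nrow(cohort))
    stop("`p_hat` must align 1:1 with cohort rows", call. = FALSE)
  if (any(p_hat <= 0 | p_hat >= 1))
    stop("`p_hat` must lie strictly in (0, 1)", call. = FALSE)

  labels <- unique(as.character(cohort$center_id))
  idx <- match(as.character(cohort$center_id), labels)
  n <- tabulate(idx, length(labels))
  if (any(n == 0L)) stop("empty center in cohort", call. = FALSE)
  O <- as.numeric(rowsum(as.numeric(cohort$y), idx))
  E <- as.numeric(rowsum(as.numeric(p_hat), idx))
  if (any(E <= 0)) stop("expected count is zero for a center", call. = FALSE)

  if (correction == "halves") {
    log_sir <- log((O + 0.5) / (E + 0.5))
    defined <- rep(TRUE, length(O))
  } else {
    defined <- O > 0
    log_sir <- ifelse(defined, log(O / E), NA_real_)
  }
  structure(data.frame(
    center_id = labels, n = as.integer(n), O = O, E = E,
    log_sir = log_sir, defined = defined, stringsAsFactors = FALSE
  ), class = c("center_summary", "data.frame"))
}

#' Write a center summary CSV
#'
#' Columns `center_id,n,O,E,log_sir`.
#'
#' @param summary a `center_summary`.
#' @param path output path.
#' @export
write_center_summary <- function(summary, path) {
  utils::write.csv(summary[, c("center_id", "n", "O", "E", "log_sir")],
                   path, row.names = FALSE)
  invisible(path)
}
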