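#' Bootstrap configuration
#'
#' @param B replicate count (default 5000).
#' @param seed integer seed.
#' @param stratified resample within center (default `TRUE`), preserving
#'   center sizes; `FALSE` resamples from the pooled cohort, in which case a
#'   center can be absent from a replicate (that draw is marked undefined).
#' @param mode `"refit"` refits the mixed model on every replicate and
#'   recomputes marginal probabilities (the faithful but expensive choice);
#'   `"fixed_model"` keeps the baseline probabilities attached to the
#'   resampled rows and recomputes only `O*` and `E*`.
#' @param level level for the percentile interval columns.
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 5000L, seed = 1L, stratified = TRUE,
                             mode = c("refit", "fixed_model"), level = 0.95) {
  mode <- match.arg(mode)
  if (B < 2L) stop("`B` must be >= 2", call. = FALSE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 stratified = isTRUE(stratified), mode = mode, level = level),
            class = "bootstrap_config")
}

#' Nonparametric bootstrap variance of Log-SIR per center
#'
#' Resamples patient rows with replacement B times; each replicate yields a
#' per-center `Log-SIR* = log(O*/E*)`, and the bootstrap variance is the
#' sample variance of the defined draws (denominator `n_defined - 1`).
#' Replicates where a center has `O* = 0` (or, unstratified, no rows at all)
#' are marked undefined, dropped from the moments and counted; a center with
#' more than 20% undefined draws gets a warning.
#'
#' @param cohort cohort data.frame.
#' @param spec a [model_spec()] (needed when `fit` is not supplied or
#'   `mode = "refit"`).
#' @param config a [bootstrap_config()].
#' @param fit optional baseline [fit_glmm()] result (computed if omitted).
#' @param p_hat optional baseline per-patient probabilities; with
#'   `mode = "fixed_model"` this replaces the model fit entirely (useful for
#'   single-center toys and enumeration checks).
#' @param return_draws attach the full draw matrix (B x centers) as
#'   attribute `"draws"`.
#' @return data.frame of class `variance_estimate` with columns `center_id`,
#'   `method` (`"bootstrap"`), `n`, `O`, `E`, `log_sir` (baseline point),
#'   `mean_boot`, `var`, `se`, `lci`, `uci` (percentile), `n_undefined`.
#' @export
bootstrap_var_log_sir <- function(cohort, spec = NULL, config = bootstrap_config(),
                                  fit = NULL, p_hat = NULL,
                                  return_draws = FALSE) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (is.null(fit) && is.null(p_hat)) {
    if (is.null(spec)) stop("supply `spec`, a baseline `fit` or `p_hat`",
                            call. = FALSE)
    fit <- fit_glmm(cohort, spec)
  }
  if (is.null(p_hat) || !is.null(fit)) {
    spec <- spec %||% fit$spec
  } else if (config$mode == "refit") {
    stop("mode = \"refit\" needs a model `spec` or `fit`", call. = FALSE)
  }
  p0 <- p_hat %||% predict_probabilities(fit, mode = "marginal")
  base <- summarize_centers(cohort, p0)
  labels <- base$center_id
  C <- length(labels)
  idx_by_center <- split(seq_len(nrow(cohort)),
                         factor(as.character(cohort$center_id), levels = labels))
  y <- as.numeric(cohort$y)
  B <- config$B

  set.seed(config$seed)
  draws <- matrix(NA_real_, nrow = B, ncol = C,
                  dimnames = list(NULL, labels))

  if (config$mode == "fixed_model") {
    if (config$stratified) {
      for (c in seq_len(C)) {
        rows <- idx_by_center[[c]]
        nc <- length(rows)
        pick <- matrix(rows[sample.int(nc, nc * B, replace = TRUE)], nc, B)
        Ostar <- colSums(matrix(y[pick], nc, B))
        Estar <- colSums(matrix(p0[pick], nc, B))
        ok <- Ostar > 0
        draws[ok, c] <- log(Ostar[ok] / Estar[ok])
      }
    } else {
      n <- nrow(cohort)
      cidx <- match(as.character(cohort$center_id), labels)
      for (b in seq_len(B)) {
        pick <- sample.int(n, n, replace = TRUE)
        Ostar <- as.numeric(rowsum(y[pick], factor(cidx[pick], levels = seq_len(C))))
        Estar <- as.numeric(rowsum(p0[pick], factor(cidx[pick], levels = seq_len(C))))
        ok <- !is.na(Estar) & Estar > 0 & !is.na(Ostar) & Ostar > 0
        draws[b, ok] <- log(Ostar[ok] / Estar[ok])
      }
    }
  } else {  # refit
    n <- nrow(cohort)
    for (b in seq_len(B)) {
      pick <- if (config$stratified) {
        unlist(lapply(idx_by_center, function(r)
          r[sample.int(length(r), length(r), replace = TRUE)]), use.names = FALSE)
      } else {
        sample.int(n, n, replace = TRUE)
      }
      boot_cohort <- cohort[pick, , drop = FALSE]
      sb <- tryCatch({
        fb <- suppressWarnings(fit_glmm(boot_cohort, spec))
        pb <- predict_probabilities(fb, mode = "marginal")
        summarize_centers(boot_cohort, pb)
      }, error = function(e) NULL)
      if (is.null(sb)) next
      m <- match(labels, sb$center_id)
      ls <- sb$log_sir[m]
      draws[b, ] <- ls
    }
  }

  n_undef <- colSums(is.na(draws))
  mean_boot <- colMeans(draws, na.rm = TRUE)
  v <- apply(draws, 2, function(d) {
    d <- d[!is.na(d)]
    if (length(d) >= 2L) stats::var(d) else NA_real_
  })
  alpha <- (1 - config$level) / 2
  qs <- apply(draws, 2, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(c(NA_real_, NA_real_))
    stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
  high_undef <- n_undef > 0.2 * B
  if (any(high_undef))
    warning(sprintf("more than 20%% undefined bootstrap draws for center(s): %s",
                    paste(labels[high_undef], collapse = ", ")), call. = FALSE)

  out <- structure(data.frame(
    center_id = labels, method = "bootstrap",
    n = base$n, O = base$O, E = base$E, log_sir = base$log_sir,
    mean_boot = as.numeric(mean_boot), var = as.numeric(v),
    se = sqrt(as.numeric(v)),
    lci = qs[1, ], uci = qs[2, ],
    n_undefined = as.integer(n_undef), stringsAsFactors = FALSE
  ), class = c("variance_estimate", "data.frame"))
  if (return_draws) attr(out, "draws") <- draws
  out
}
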