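#' Wald confidence interval
#'
#' `point -/+ z * se` with `z` the standard normal quantile at
#' `(1 + level)/2` (1.959964 at 95%).
#'
#' @param point numeric vector of point estimates.
#' @param se numeric vector of standard errors (`>= 0`).
#' @param level confidence level in (0, 1).
#' @return list with vectors `lower`, `upper`.
#' @export
wald_interval <- function(point, se, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(se < 0, na.rm = TRUE)) stop("`se` must be >= 0", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  list(lower = point - z * se, upper = point + z * se)
}

#' False-discovery-rate control limits around Log-SIR = 0
#'
#' Per-center limits `(-z * se, +z * se)` anchored at zero: the band inside
#' which a center's Log-SIR is consistent with average performance at the
#' given level. These are the per-center funnel limits of institutional
#' comparison, not a Benjamini-Hochberg multiplicity procedure.
#'
#' @inheritParams wald_interval
#' @return list with vectors `lfdr`, `ufdr` (`lfdr == -ufdr` exactly).
#' @export
fdr_limits <- function(se, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(se < 0, na.rm = TRUE)) stop("`se` must be >= 0", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  list(lfdr = -z * se, ufdr = z * se)
}

#' Assemble funnel points from a variance estimate
#'
#' Combines a per-center variance estimate into plotting/classification rows:
#' the center-anchored 95% interval (Wald for the delta method; the
#' percentile/credible columns when the estimate carries them), the
#' zero-anchored FDR limits, and the effective sample size
#' `rho = 1 / Var(Log-SIR)` (the precision; the funnel envelope is then the
#' standard `+/- z / sqrt(rho)` curve). `x_axis = "size"` uses raw center
#' size instead.
#'
#' @param est a `variance_estimate` data.frame (from [delta_variance()],
#'   [bootstrap_var_log_sir()] or [posterior_log_sir()]).
#' @param level level for intervals and limits.
#' @param x_axis `"precision"` (default) or `"size"`.
#' @return data.frame of class `funnel_points` with columns `center_id`,
#'   `method`, `log_sir`, `se`, `lci`, `uci`, `lfdr`, `ufdr`, `rho`,
#'   `status`.
#' @export
funnel_points <- function(est, level = 0.95,
                          x_axis = c("precision", "size")) {
  x_axis <- match.arg(x_axis)
  stopifnot(is.data.frame(est),
            all(c("center_id", "method", "log_sir", "var", "se") %in% names(est)))
  lims <- fdr_limits(est$se, level)
  if (all(c("lcri", "ucri") %in% names(est))) {
    lci <- est$lcri; uci <- est$ucri
  } else if (all(c("lci", "uci") %in% names(est)) && est$method[1] != "delta") {
    lci <- est$lci; uci <- est$uci
  } else {
    w <- wald_interval(est$log_sir, est$se, level)
    lci <- w$lower; uci <- w$upper
  }
  rho <- if (x_axis == "precision") 1 / est$var else as.numeric(est$n)
  out <- data.frame(
    center_id = est$center_id, method = est$method,
    log_sir = est$log_sir, se = est$se,
    lci = lci, uci = uci, lfdr = lims$lfdr, ufdr = lims$ufdr,
    rho = rho, status = NA_character_, stringsAsFactors = FALSE
  )
  out <- classify_centers(out)
  class(out) <- c("funnel_points", "data.frame")
  attr(out, "level") <- level
  attr(out, "x_axis") <- x_axis
  out
}

#' Classify centers against their FDR limits
#'
#' `low` if `log_sir < lfdr`, `high` if `log_sir > ufdr`, `average`
#' otherwise; centers with undefined Log-SIR get `undefined`.
#'
#' @param points data.frame with `log_sir`, `lfdr`, `ufdr`.
#' @return the same data.frame with `status` filled.
#' @export
classify_centers <- function(points) {
  stopifnot(all(c("log_sir", "lfdr", "ufdr") %in% names(points)))
  status <- ifelse(is.na(points$log_sir) | is.na(points$lfdr), "undefined",
            ifelse(points$log_sir < points$lfdr, "low",
            ifelse(points$log_sir > points$ufdr, "high", "average")))
  points$status <- status
  points
}

#' Render a funnel plot
#'
#' Scatter of Log-SIR against effective sample size (precision), a solid
#' reference line at Log-SIR = 0 and the dashed `+/- z / sqrt(rho)` FDR
#' envelope. Output is deterministic for identical input.
#'
#' @param points a [funnel_points()] data.frame.
#' @param method label used in the title (defaults to the points' method).
#' @param path output file; extension selects the device (`.svg` or `.png`).
#' @param level envelope level (defaults to the level stored on `points`).
#' @return the path, invisibly.
#' @export
render_funnel <- function(points, method = NULL, path, level = NULL) {
  stopifnot(is.data.frame(points))
  level <- level %||% attr(points, "level") %||% 0.95
  method <- method %||% as.character(points$method[1])
  pts <- points[!is.na(points$log_sir) & is.finite(points$rho), , drop = FALSE]
  if (!nrow(pts)) stop("no defined funnel point to draw", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  grid <- exp(seq(log(max(min(pts$rho) * 0.8, 1e-8)),
                  log(max(pts$rho) * 1.2), length.out = 200))
  env <- data.frame(rho = grid, up = z / sqrt(grid), lo = -z / sqrt(grid))

  g <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$rho, y = .data$log_sir)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.4) +
    ggplot2::geom_line(data = env, ggplot2::aes(x = .data$rho, y = .data$up),
                       linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_line(data = env, ggplot2::aes(x = .data$rho, y = .data$lo),
                       linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::scale_colour_manual(values = c(low = "#d73027", high = "#4575b4",
                                            average = "grey30"),
                                 drop = TRUE) +
    ggplot2::labs(x = "Effective sample size (precision of Log-SIR)",
                  y = "Log-SIR",
                  title = sprintf("Funnel plot (%s method)", method),
                  colour = "status") +
    ggplot2::theme_minimal()

  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = 7, height = 5)
  } else if (ext == "png") {
    grDevices::png(path, width = 1400, height = 1000, res = 200)
  } else stop("unsupported figure format: ", ext, call. = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(g)
  invisible(path)
}

#' Wide per-center comparison tables
#'
#' Binds the per-method blocks side by side in the layout of provider
#' profiling reports: for `type = "ci"` each method contributes
#' `mean,se,lci,uci` (credible limits for the Bayesian block), for
#' `type = "fdr"` `mean,se,lfdr,ufdr`. Values are rounded to 3 decimals,
#' half away from zero.
#'
#' @param estimates named list of `variance_estimate` data.frames (names are
#'   method labels, e.g. `list(delta = ..., bootstrap = ..., bayes = ...)`).
#' @param type `"ci"` or `"fdr"`.
#' @param level level for FDR limits.
#' @param digits rounding digits (default 3); `NULL` for full precision.
#' @return a wide data.frame, one row per center.
#' @export
center_comparison_table <- function(estimates, type = c("ci", "fdr"),
                                    level = 0.95, digits = 3L) {
  type <- match.arg(type)
  stopifnot(is.list(estimates), length(estimates) >= 1L)
  ids <- estimates[[1]]$center_id
  out <- data.frame(center_id = ids, stringsAsFactors = FALSE)
  rnd <- function(x) if (is.null(digits)) x else round_half_away(x, digits)
  for (nm in names(estimates)) {
    e <- estimates[[nm]]
    m <- match(ids, e$center_id)
    if (type == "ci") {
      if ("lcri" %in% names(e)) {
        lo <- e$lcri; hi <- e$ucri
      } else if ("lci" %in% names(e)) {
        lo <- e$lci; hi <- e$uci
      } else {
        w <- wald_interval(e$log_sir, e$se, level)
        lo <- w$lower; hi <- w$upper
      }
      blk <- data.frame(rnd(e$log_sir[m]), rnd(e$se[m]), rnd(lo[m]), rnd(hi[m]))
      names(blk) <- paste(nm, c("mean", "se", "lci", "uci"), sep = "_")
    } else {
      lims <- fdr_limits(e$se[m], level)
      blk <- data.frame(rnd(e$log_sir[m]), rnd(e$se[m]),
                        rnd(lims$lfdr), rnd(lims$ufdr))
      names(blk) <- paste(nm, c("mean", "se", "lfdr", "ufdr"), sep = "_")
    }
    out <- cbind(out, blk)
  }
  out
}
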