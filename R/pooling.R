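# Rubin-style pooling of HMM fits across imputed track realizations.

.back_transform_name <- function(nm) .name_prefix(nm)

.parse_par_names <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  data.frame(
    parameter = vapply(parts, `[[`, character(1), 1),
    state = vapply(parts, function(p)
      if (length(p) >= 2 && p[2] %in% STATE_LEVELS) p[2] else "all",
      character(1)),
    sex = vapply(parts, function(p) {
      tail <- p[length(p)]
      if (length(p) >= 2 && tail %in% SEX_LEVELS) tail else "all"
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Pool HMM fits across track realizations
#'
#' Normal-theory multiple-imputation pooling on the working (link) scale:
#' the pooled estimate is the mean of the per-realization estimates, the
#' total variance is `W + (1 + 1/m) * B` with `W` the mean within-fit
#' variance and `B` the between-fit variance, and the 95% interval is
#' `mean +/- z * sqrt(total)` back-transformed to the natural scale.
#' Percentile pooling of the natural-scale estimates is available as an
#' option. Non-converged fits are excluded with a warning and `m` adjusted.
#'
#' @param fits List of `fitted_hmm` objects of identical configuration, one
#'   per track realization.
#' @param conf Confidence level (default 0.95).
#' @param method `"rubin"` (default) or `"percentile"`.
#' @param df Degrees of freedom for the interval quantile; `Inf` (default)
#'   uses the normal quantile.
#' @return An object of class `pooled_hmm`: a data frame with columns
#'   `parameter`, `state`, `sex`, `estimate`, `lo95`, `hi95`, plus
#'   attributes `m`, `within`, `between` (working scale) and `pars`, the
#'   pooled natural-scale [hmm_pars()].
#' @export
pool_fits <- function(fits, conf = 0.95, method = c("rubin", "percentile"),
                      df = Inf) {
  method <- match.arg(method)
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f)
    inherits(f, "fitted_hmm") && f$convergence == 0L, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " non-converged fit(s) excluded from pooling")
    fits <- fits[ok]
  }
  if (length(fits) == 0) stop("no converged fits to pool", call. = FALSE)
  cid <- vapply(fits, function(f) f$config$id, integer(1))
  if (length(unique(cid)) != 1)
    stop("fits mix different configurations", call. = FALSE)
  nm <- names(fits[[1]]$par)
  for (f in fits) if (!identical(names(f$par), nm))
    stop("fits have inconsistent parameter layouts", call. = FALSE)

  m <- length(fits)
  est <- t(vapply(fits, function(f) f$par, numeric(length(nm))))
  if (m > 1) {
    # turn means are circular: align every fit's lam to the first fit's
    # branch so estimates near +-pi do not cancel across realizations
    for (j in which(.name_prefix(nm) == "lam"))
      est[, j] <- est[1, j] + wrap_to_pi(est[, j] - est[1, j])
  }
  wvar <- t(vapply(fits, function(f) {
    if (is.null(f$vcov)) rep(NA_real_, length(nm)) else diag(f$vcov)
  }, numeric(length(nm))))

  qbar <- colMeans(est)
  if (all(is.na(wvar))) {
    warning("no fit supplied a working-scale covariance; ",
            "within-variance treated as 0")
    wvar[] <- 0
  }
  W <- colMeans(wvar, na.rm = TRUE)
  W[is.nan(W)] <- 0
  B <- if (m > 1) apply(est, 2, var) else rep(0, length(nm))
  Tvar <- W + (1 + 1 / m) * B
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf) / 2, df) else
    qnorm(1 - (1 - conf) / 2)

  prefix <- .back_transform_name(nm)
  bt <- function(v) vapply(seq_along(v), function(i)
    .from_working(v[i], prefix[i]), numeric(1))

  if (method == "rubin") {
    estimate <- bt(qbar)
    lo <- bt(qbar - q * sqrt(Tvar))
    hi <- bt(qbar + q * sqrt(Tvar))
  } else {
    nat <- apply(est, 1, bt)
    nat <- if (is.matrix(nat)) t(nat) else matrix(nat, ncol = 1)
    estimate <- apply(nat, 2, stats::median)
    lo <- apply(nat, 2, stats::quantile, probs = (1 - conf) / 2, names = FALSE)
    hi <- apply(nat, 2, stats::quantile, probs = 1 - (1 - conf) / 2,
                names = FALSE)
  }
  # monotone-decreasing links (none here) would swap bounds; guard anyway
  swap <- !is.na(lo) & !is.na(hi) & lo > hi
  tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp

  out <- cbind(.parse_par_names(nm),
               data.frame(estimate = estimate, lo95 = lo, hi95 = hi,
                          stringsAsFactors = FALSE))
  rownames(out) <- nm
  attr(out, "m") <- m
  attr(out, "within") <- setNames(W, nm)
  attr(out, "between") <- setNames(B, nm)
  attr(out, "total") <- setNames(Tvar, nm)
  attr(out, "working_mean") <- setNames(qbar, nm)
  # natural-scale parameter object (needs the full layout; partial fits,
  # e.g. in unit tests, simply omit it)
  attr(out, "pars") <- tryCatch(
    .working_to_pars(setNames(qbar, nm), fits[[1]]$config),
    error = function(e) NULL)
  attr(out, "config") <- fits[[1]]$config
  class(out) <- c("pooled_hmm", "data.frame")
  out
}

#' Format an estimate with its interval
#'
#' Renders `"estimate [lower, upper]"`, e.g. `"0.035 [0.025, 0.049]"`.
#'
#' @param estimate,lo,hi Numeric scalars or vectors.
#' @param digits Significant digits (default 3).
#' @export
format_estimate <- function(estimate, lo, hi, digits = 3) {
  sprintf("%s [%s, %s]",
          signif(estimate, digits), signif(lo, digits), signif(hi, digits))
}

#' @export
print.pooled_hmm <- function(x, ...) {
  cat(sprintf("pooled_hmm: %d realizations, config %d\n",
              attr(x, "m"), attr(x, "config")$id))
  df <- as.data.frame(x)
  df$`estimate [95% CI]` <- format_estimate(x$estimate, x$lo95, x$hi95)
  print(df[, c("parameter", "state", "sex", "estimate [95% CI]")],
        row.names = FALSE)
  invisible(x)
}
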