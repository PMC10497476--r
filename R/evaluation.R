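#' Mean of a parametric map over a labeled region
#'
#' @param map 3D numeric array (e.g. a Ki map).
#' @param labels Integer 3D label array on the same grid.
#' @param label Region label.
#' @return Unweighted mean over the labeled voxels.
#' @export
roi_mean <- function(map, labels, label) {
  if (!all(dim(map) == dim(labels))) stop("map and labels differ in shape")
  sel <- labels == label
  if (!any(sel)) stop("label ", label, " is empty")
  mean(map[sel])
}

#' Absolute and relative parameter differences
#'
#' `abs_diff(p1, p2) = |p1 - p2|`; `rel_diff(p1, p2) = (p1 - p2) / p2`,
#' conventionally reported in percent with `p2` the reference protocol.
#'
#' @param p1,p2 Numeric (vectorized); `p2` must be nonzero for `rel_diff`.
#' @return Numeric difference(s); `rel_diff` is a fraction (multiply by 100
#'   for percent).
#' @export
abs_diff <- function(p1, p2) abs(p1 - p2)

#' @rdname abs_diff
#' @export
rel_diff <- function(p1, p2) {
  if (any(p2 == 0)) stop("rel_diff undefined for reference value 0")
  (p1 - p2) / p2
}

#' Bland-Altman agreement analysis
#'
#' Pairwise differences against pairwise means, with the mean difference and
#' the mean +/- 1.96 SD limits of agreement. In `"relative"` mode (the
#' default) differences are `(a - b)/b` in percent.
#'
#' @param a,b Paired measurements (equal length >= 2).
#' @param mode `"relative"` or `"absolute"`.
#' @return A `bland_altman` list: `means`, `diffs`, `mean_diff`, `sd_diff`,
#'   `loa` (lower/upper limits), `mode`.
#' @export
bland_altman <- function(a, b, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  diffs <- if (mode == "relative") 100 * rel_diff(a, b) else a - b
  m <- mean(diffs); s <- stats::sd(diffs)
  structure(list(means = (a + b) / 2, diffs = diffs, mean_diff = m,
                 sd_diff = s, loa = c(lower = m - 1.96 * s,
                                      upper = m + 1.96 * s),
                 mode = mode),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "relative") "%" else ""
  cat(sprintf("Bland-Altman (%s): mean %.4g%s, limits [%.4g, %.4g]%s\n",
              x$mode, x$mean_diff, unit, x$loa[1], x$loa[2], unit))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "Mean of pair",
                              ylab = NULL) {
  if (is.null(ylab))
    ylab <- if (x$mode == "relative") "Difference (%)" else "Difference"
  graphics::plot(x$means, x$diffs, pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2),
                   col = "firebrick")
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param a,b Numeric vectors (length >= 3, nonzero variance).
#' @return R^2 in `[0, 1]`.
#' @export
correlation_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)^2
}

#' Paired t-test and variance F-test
#'
#' Thin wrappers around the standard two-sided tests, returning `(statistic,
#' p)` pairs. For the degenerate paired case of identical samples the test
#' reports `t = 0, p = 1` (no evidence of a difference); zero-variance
#' differences with nonzero mean are reported as infinite `t` with `p = 0`
#' and a warning.
#'
#' @param a,b Paired samples (t-test) or two samples (F-test).
#' @return List with elements `statistic` and `p.value` (and `df`).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, df = length(d) - 1,
                                  p.value = 1))
    warning("zero-variance nonzero paired differences; t is infinite")
    return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1,
                p.value = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' @rdname paired_t_test
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  ht <- stats::var.test(a, b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Framing-protocol comparison report
#'
#' Reproduces the protocol-comparison machinery: per-ROI parameter tables
#' (mean +/- SD over replicates), relative differences of Ki and intercept
#' versus a reference protocol, paired t-tests per ROI versus the reference,
#' variance F-tests on the relative-difference samples, and input-function
#' AUC relative errors.
#'
#' The F-test needs two non-degenerate samples; since the reference's own
#' relative differences are identically zero, each protocol's
#' relative-difference vector is compared against that of the least-sparse
#' non-reference protocol.
#'
#' @param results data.frame with columns `protocol`, `roi`, `replicate`,
#'   `Ki`, `intercept` (scalars per ROI fit, e.g. ROI means of voxelwise
#'   maps).
#' @param reference Reference protocol name (present in `results`).
#' @param idifs Optional named list of per-protocol [input_function()]s for
#'   the AUC table.
#' @param auc_window AUC window in minutes (default 0-60).
#' @return A `protocol_comparison` list of data.frames: `ki_table`,
#'   `intercept_table`, `rel_diff` (per protocol mean +/- SD %, with F-test
#'   p), `t_tests` (per ROI x protocol), `auc` (per protocol AUC and
#'   relative error % vs reference).
#' @export
protocol_comparison <- function(results, reference, idifs = NULL,
                                auc_window = c(0, 60)) {
  need <- c("protocol", "roi", "replicate", "Ki", "intercept")
  if (!all(need %in% names(results)))
    stop("results needs columns ", paste(need, collapse = ", "))
  protos <- unique(results$protocol)
  if (!reference %in% protos) stop("reference protocol absent from results")
  rois <- sort(unique(results$roi))
  for (p in protos) {
    have <- sort(unique(results$roi[results$protocol == p]))
    if (!identical(have, rois))
      stop("ROI set mismatch for protocol ", p)
  }

  agg <- function(param) {
    do.call(rbind, lapply(protos, function(p) {
      sub <- results[results$protocol == p, ]
      mu <- tapply(sub[[param]], sub$roi, mean)
      sdv <- tapply(sub[[param]], sub$roi, stats::sd)
      data.frame(protocol = p, roi = names(mu), mean = as.numeric(mu),
                 sd = as.numeric(sdv), row.names = NULL)
    }))
  }

  # per (roi, replicate) relative differences vs reference, in percent
  key <- function(d) paste(d$roi, d$replicate, sep = "\r")
  refd <- results[results$protocol == reference, ]
  refki <- refd$Ki[order(key(refd))]
  refint <- refd$intercept[order(key(refd))]
  rd_list <- lapply(protos, function(p) {
    sub <- results[results$protocol == p, ]
    sub <- sub[order(key(sub)), ]
    data.frame(protocol = p,
               rd_ki = 100 * rel_diff(sub$Ki, refki),
               rd_int = 100 * rel_diff(sub$intercept, refint))
  })
  names(rd_list) <- protos
  baseline <- setdiff(protos, reference)[1]
  rel_tab <- do.call(rbind, lapply(protos, function(p) {
    rd <- rd_list[[p]]
    f_ki <- f_int <- NA_real_
    if (p != reference && p != baseline && !is.na(baseline)) {
      f_ki <- variance_f_test(rd$rd_ki, rd_list[[baseline]]$rd_ki)$p.value
      f_int <- variance_f_test(rd$rd_int, rd_list[[baseline]]$rd_int)$p.value
    }
    data.frame(protocol = p,
               ki_mean_pct = mean(rd$rd_ki), ki_sd_pct = stats::sd(rd$rd_ki),
               int_mean_pct = mean(rd$rd_int),
               int_sd_pct = stats::sd(rd$rd_int),
               f_p_ki = f_ki, f_p_intercept = f_int)
  }))

  t_tab <- do.call(rbind, lapply(setdiff(protos, reference), function(p) {
    do.call(rbind, lapply(rois, function(r) {
      a <- results[results$protocol == p & results$roi == r, ]
      b <- results[results$protocol == reference & results$roi == r, ]
      a <- a[order(a$replicate), ]; b <- b[order(b$replicate), ]
      tt <- paired_t_test(a$Ki, b$Ki)
      data.frame(protocol = p, roi = r, t = tt$statistic, p = tt$p.value)
    }))
  }))

  auc_tab <- NULL
  if (!is.null(idifs)) {
    if (!reference %in% names(idifs)) stop("reference IDIF missing")
    aucs <- vapply(idifs, tac_auc, numeric(1),
                   t0 = auc_window[1], t1 = auc_window[2])
    auc_tab <- data.frame(
      protocol = names(idifs), auc = as.numeric(aucs),
      rel_err_pct = 100 * rel_diff(as.numeric(aucs), aucs[[reference]]),
      row.names = NULL)
  }

  structure(list(ki_table = agg("Ki"), intercept_table = agg("intercept"),
                 rel_diff = rel_tab, t_tests = t_tab, auc = auc_tab,
                 reference = reference),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, digits = 3, ...) {
  cat("Protocol comparison (reference: ", x$reference, ")\n\n", sep = "")
  cat("Relative differences vs reference (mean +/- SD %, pooled ROIs x replicates):\n")
  rd <- x$rel_diff
  for (i in seq_len(nrow(rd)))
    cat(sprintf("  %-7s Ki %6.2f +/- %5.2f %%   intercept %6.2f +/- %5.2f %%\n",
                rd$protocol[i], rd$ki_mean_pct[i], rd$ki_sd_pct[i],
                rd$int_mean_pct[i], rd$int_sd_pct[i]))
  if (!is.null(x$auc)) {
    cat("\nInput-function AUC relative error vs reference:\n")
    for (i in seq_len(nrow(x$auc)))
      cat(sprintf("  %-7s %7.3f %%\n", x$auc$protocol[i],
                  x$auc$rel_err_pct[i]))
  }
  invisible(x)
}
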