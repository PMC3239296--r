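#' Relative expression from qPCR cycle thresholds
#'
#' Computes 2^-(ct_target - ct_reference), the standard delta-Ct estimate of
#' a target's transcript level relative to the reference gene (Actb).  One
#' extra cycle of the target halves the estimate; one extra cycle of the
#' reference doubles it.
#'
#' @param ct_target,ct_reference numeric Ct vectors (recycled together).
#' @return numeric vector of relative expression levels.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (anyNA(ct_target) || anyNA(ct_reference) ||
      any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("missing or non-finite Ct value", call. = FALSE)
  }
  2^(-(ct_target - ct_reference))
}

#' Knockout-over-control fold change with a two-tailed t-test
#'
#' fold = mean(ko) / mean(control) on the per-sample relative expression
#' levels, with an unpaired two-tailed Student t-test (equal variances by
#' default; set `var_equal = FALSE` for Welch).  The test can instead be run
#' on the delta-Ct values (`on = "dct"`, supply `ko`/`control` as relative
#' levels either way; they are log2-transformed internally), which tests the
#' same null on the log scale.
#'
#' Degenerate inputs: with zero variance in both groups and equal means the
#' p-value is 1 (no evidence of a difference, exactly); zero variance
#' otherwise leaves the p-value undefined and sets `flag`.
#'
#' @param ko,control numeric vectors of per-sample relative expression
#'   levels (each n >= 1 for the fold; n >= 2 per group for a p-value).
#' @param var_equal classical Student test when `TRUE` (default), Welch
#'   otherwise.
#' @param on `"levels"` (default) tests the relative levels; `"dct"` tests
#'   their log2 (the negative delta-Ct scale).
#' @return object of class `fold_change`: list with fold, p_value, flag, and
#'   a per-group data frame of mean, sd, n.
#' @export
fold_change <- function(ko, control, var_equal = TRUE,
                        on = c("levels", "dct")) {
  on <- match.arg(on)
  ko <- ko[!is.na(ko)]
  control <- control[!is.na(control)]
  if (length(ko) < 1 || length(control) < 1) {
    stop("each group needs at least one non-missing value", call. = FALSE)
  }
  if (mean(control) == 0) {
    stop("zero control mean: fold change undefined", call. = FALSE)
  }
  fold <- mean(ko) / mean(control)
  x <- switch(on, levels = ko, dct = log2(ko))
  y <- switch(on, levels = control, dct = log2(control))
  flag <- NA_character_
  p <- NA_real_
  if (length(x) < 2 || length(y) < 2) {
    flag <- "n_too_small"
  } else if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) p <- 1 else flag <- "zero_variance"
  } else {
    p <- stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  structure(list(
    fold = fold, p_value = p, flag = flag, on = on,
    groups = data.frame(group = c("ko", "control"),
                        mean = c(mean(ko), mean(control)),
                        sd = c(stats::sd(ko), stats::sd(control)),
                        n = c(length(ko), length(control)),
                        stringsAsFactors = FALSE)),
    class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold change (ko/control): %.4g", x$fold))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g (two-tailed t)", x$p_value))
  if (!is.na(x$flag)) cat(sprintf(" [%s]", x$flag))
  cat("\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Read a Ct table
#'
#' Tab-separated with header: sample, group, target, ct_target,
#' ct_reference.  Undetected measurements may be given as NA, "u.d." or
#' "n.d."; they are treated as missing, never as zero.
#'
#' @param path file path.
#' @return data frame with those five columns.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "u.d.", "n.d."),
                          stringsAsFactors = FALSE)
  assert_cols(df, c("sample", "group", "target", "ct_target",
                    "ct_reference"), "ct table")
  df$ct_target <- as.numeric(df$ct_target)
  df$ct_reference <- as.numeric(df$ct_reference)
  df
}

#' Per-target fold-change table from a Ct table
#'
#' Converts every sample to relative expression with
#' [relative_expression()], then computes [fold_change()] per target between
#' the `ko` and `control` groups.  Samples with missing Ct (undetected) are
#' excluded from their group.
#'
#' @param ct Ct data frame (see [read_ct_table()]); `group` must contain
#'   "control" and "ko".
#' @param var_equal,on passed to [fold_change()].
#' @return data frame with one row per target: fold, p_value, per-group
#'   mean/sd/n, flag.
#' @export
fold_change_table <- function(ct, var_equal = TRUE,
                              on = c("levels", "dct")) {
  on <- match.arg(on)
  assert_cols(ct, c("group", "target", "ct_target", "ct_reference"), "ct")
  stopifnot(all(ct$group %in% c("control", "ko")))
  rows <- lapply(split(ct, ct$target), function(d) {
    ok <- !is.na(d$ct_target) & !is.na(d$ct_reference)
    d <- d[ok, , drop = FALSE]
    lev <- relative_expression(d$ct_target, d$ct_reference)
    fc <- fold_change(lev[d$group == "ko"], lev[d$group == "control"],
                      var_equal = var_equal, on = on)
    data.frame(target = d$target[1], fold = fc$fold, p_value = fc$p_value,
               mean_ko = fc$groups$mean[1], sd_ko = fc$groups$sd[1],
               n_ko = fc$groups$n[1],
               mean_control = fc$groups$mean[2],
               sd_control = fc$groups$sd[2], n_control = fc$groups$n[2],
               flag = fc$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ChIP-qPCR fold enrichment over an intergenic control region
#'
#' Enrichment of a region is the input-normalized IP signal
#' 2^-(ip_ct - input_ct); the reported fold enrichment normalizes the target
#' region's enrichment to that of a negative-control intergenic region.  The
#' control region evaluated against itself gives exactly 1.
#'
#' @param ip_target,input_target Ct values at the target region.
#' @param ip_intergenic,input_intergenic Ct values at the intergenic
#'   negative-control region.
#' @return fold enrichment (positive numeric).
#' @export
chip_enrichment <- function(ip_target, input_target,
                            ip_intergenic, input_intergenic) {
  vals <- c(ip_target, input_target, ip_intergenic, input_intergenic)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("missing or non-finite Ct value", call. = FALSE)
  }
  enr <- function(ip, input) 2^(-(ip - input))
  enr(ip_target, input_target) / enr(ip_intergenic, input_intergenic)
}
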