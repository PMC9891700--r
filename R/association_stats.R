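# Gene-versus-score association statistics, two-group comparisons, and the
# small quantification formulas (delta-delta-Ct, densitometry).

#' Correlate two per-sample quantities
#'
#' Computes the Pearson product-moment correlation and the Spearman rank
#' correlation (average ranks for ties) after pairwise deletion of missing
#' pairs. The two-sided p-value for the chosen `method`'s coefficient comes
#' from `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (e.g. a gene's log2 expression
#'   and a per-sample score). Pairs with missing entries are dropped.
#' @param method `"pearson"` (default) or `"spearman"`: which coefficient the
#'   t statistic and p-value refer to. Both coefficients are always reported.
#' @param x_name,y_name Labels carried into the result.
#' @return A one-row `data.frame` (class `association_result`) with columns
#'   `x_name`, `y_name`, `n`, `r`, `r_squared`, `spearman_rho`, `t_stat`,
#'   `df`, `p_value`, `method`. `r`/`r_squared` are always the Pearson
#'   coefficient and its square.
#' @examples
#' correlate(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      x_name = deparse1(substitute(x)),
                      y_name = deparse1(substitute(y))) {
  method <- match.arg(method)
  force(x_name)
  force(y_name)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance in x or y", call. = FALSE)
  }
  r <- pearson_r(x, y)
  rho <- pearson_r(rank(x), rank(y))
  r_used <- if (method == "pearson") r else rho
  if (abs(r_used) >= 1) {
    t_stat <- sign(r_used) * Inf
    p <- 0
  } else {
    t_stat <- r_used * sqrt((n - 2) / (1 - r_used^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  out <- data.frame(
    x_name = x_name, y_name = y_name, n = n,
    r = r, r_squared = r^2, spearman_rho = rho,
    t_stat = t_stat, df = n - 2L, p_value = p, method = method,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

#' Two-group comparison of a per-sample quantity
#'
#' Two-sided two-sample t test with group means and the fold change of means
#' (second group over first). `variant = "welch"` (default) uses the
#' Welch–Satterthwaite degrees of freedom; `"pooled"` the Student statistic.
#'
#' @param values Numeric vector.
#' @param labels Two-level factor (or coercible) aligned with `values`; the
#'   first level is the reference group `a`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A one-row `data.frame` (class `group_comparison`) with columns
#'   `group_a`, `group_b`, `mean_a`, `mean_b`, `n_a`, `n_b`, `fold_change`
#'   (`mean_b / mean_a`), `t_stat`, `df`, `p_value`, `variant`.
#' @examples
#' group_ttest(c(2, 4, 6, 1, 2, 3), rep(c("up", "dn"), each = 3), variant = "pooled")
#' @export
group_ttest <- function(values, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("`labels` must have exactly 2 levels", call. = FALSE)
  }
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L) {
    stop("`labels` must have exactly 2 levels after removing missing values",
      call. = FALSE
    )
  }
  a <- values[labels == levels(labels)[1L]]
  b <- values[labels == levels(labels)[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # t.test() refuses constant data; the limit is well defined.
    t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(b) - mean(a)) * Inf
    df <- length(a) + length(b) - 2
    p <- if (t_stat == 0) 1 else 0
  } else {
    ht <- stats::t.test(b, a, var.equal = (variant == "pooled"))
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  fold <- if (mean(a) != 0) mean(b) / mean(a) else NA_real_
  out <- data.frame(
    group_a = levels(labels)[1L], group_b = levels(labels)[2L],
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    fold_change = fold,
    t_stat = t_stat, df = df, p_value = p, variant = variant,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' `dCt = mean(Ct_target) - mean(Ct_housekeeper)` within each condition;
#' `ddCt = dCt_treatment - dCt_control`; `fold = 2^(-ddCt)`. Replicate
#' standard deviations are propagated through the means
#' (`sd_ddct = sqrt(sum(sd_i^2 / n_i))`) and reported as a fold range.
#'
#' @param ct_target_treat,ct_hk_treat Target and housekeeper Ct replicates in
#'   the treatment condition.
#' @param ct_target_ctrl,ct_hk_ctrl The same in the control condition.
#' @return A list with `fold`, `ddct`, `dct_treat`, `dct_ctrl`, `sd_ddct`,
#'   `fold_lo`, `fold_hi` (fold at `ddct +/- sd_ddct`; `NA` when any
#'   replicate vector has a single observation).
#' @examples
#' fold_change_ddct(c(25, 25.2), c(20, 20.1), c(24, 24.1), c(20, 19.9))
#' @export
fold_change_ddct <- function(ct_target_treat, ct_hk_treat,
                             ct_target_ctrl, ct_hk_ctrl) {
  vecs <- list(
    ct_target_treat = ct_target_treat, ct_hk_treat = ct_hk_treat,
    ct_target_ctrl = ct_target_ctrl, ct_hk_ctrl = ct_hk_ctrl
  )
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) == 0L) stop(sprintf("`%s` is empty", nm), call. = FALSE)
    if (any(!is.finite(v))) stop(sprintf("`%s` has non-finite Ct values", nm), call. = FALSE)
  }
  dct_treat <- mean(ct_target_treat) - mean(ct_hk_treat)
  dct_ctrl <- mean(ct_target_ctrl) - mean(ct_hk_ctrl)
  ddct <- dct_treat - dct_ctrl
  se2 <- vapply(vecs, function(v) {
    if (length(v) < 2L) NA_real_ else stats::var(v) / length(v)
  }, numeric(1))
  sd_ddct <- sqrt(sum(se2))
  list(
    fold = 2^(-ddct),
    ddct = ddct,
    dct_treat = dct_treat,
    dct_ctrl = dct_ctrl,
    sd_ddct = sd_ddct,
    fold_lo = 2^(-(ddct + sd_ddct)),
    fold_hi = 2^(-(ddct - sd_ddct))
  )
}

#' Housekeeper- and control-normalized densitometry fold
#'
#' Western blot band densitometry convention: each band is divided by its
#' lane's housekeeper band, then expressed relative to the same ratio in a
#' designated control lane, so the control maps to exactly 1.
#'
#' @param band,hk Band and housekeeper densities for the lane(s) of interest
#'   (vectorized).
#' @param ctrl_band,ctrl_hk The same for the control lane.
#' @return `fold = (band / hk) / (ctrl_band / ctrl_hk)`.
#' @examples
#' densitometry_normalize(50, 100, 100, 100) # 0.5
#' @export
densitometry_normalize <- function(band, hk, ctrl_band, ctrl_hk) {
  vals <- c(band, hk, ctrl_band, ctrl_hk)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all densitometry inputs must be positive", call. = FALSE)
  }
  (band / hk) / (ctrl_band / ctrl_hk)
}
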