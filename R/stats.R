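#' Pearson correlation between two channels of a raw image
#'
#' Whole-image pixelwise Pearson correlation, computed on the raw
#' (pre-8-bit) intensities — the conventional global colocalization score.
#' Z-stacks are reduced by maximum-intensity projection by default, or a
#' single plane can be selected.
#'
#' @param stack A raw [image_stack()].
#' @param channel_a,channel_b Channel names or indices.
#' @param mask Optional logical `(y, x)` matrix restricting the pixels used
#'   (must select at least 2).
#' @param projection `"max"` (maximum-intensity projection over z) or
#'   `"plane"`.
#' @param z Plane index when `projection = "plane"`.
#' @return Pearson `r` in `[-1, 1]`, or `NA` with a warning when a channel
#'   is constant over the mask (undefined, reported as missing).
#' @export
pearson_coloc <- function(stack, channel_a, channel_b, mask = NULL,
                          projection = c("max", "plane"), z = 1) {
  stopifnot(inherits(stack, "image_stack"))
  projection <- match.arg(projection)
  grab <- function(channel) {
    ca <- channel_index(stack, channel)
    if (projection == "max" && n_planes(stack) > 1) {
      apply(stack$pixels[ca, , , , drop = TRUE], c(2, 3), max)
    } else {
      get_plane(stack, channel, if (projection == "max") 1 else z)
    }
  }
  a <- grab(channel_a); b <- grab(channel_b)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  if (sum(mask) < 2) {
    abort("Mask must select at least 2 pixels.", class = "vesicoloc_parameter_error")
  }
  av <- a[mask]; bv <- b[mask]
  if (sd(av) == 0 || sd(bv) == 0) {
    warn("Constant channel over the mask; Pearson r is undefined.")
    return(NA_real_)
  }
  cor(av, bv)
}

#' Two-sided unpaired Student's t-test
#'
#' Classic pooled-variance Student's t with `df = n_a + n_b - 2` and a
#' two-sided p-value (Welch's unequal-variance form available via
#' `welch = TRUE`). Degenerate inputs are resolved explicitly: zero pooled
#' variance with equal means gives `t = 0, p = 1`; with unequal means the
#' statistic is infinite and `p = 0`, flagged `degenerate`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `mean_diff`, `n_a`, `n_b`, `method`, `degenerate`.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) {
    abort("Each group needs at least 2 values.", class = "vesicoloc_parameter_error")
  }
  ma <- mean(group_a); mb <- mean(group_b)
  method <- if (welch) "Welch two-sample t-test" else "Student's pooled-variance t-test"
  pooled_var <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (!welch && pooled_var == 0) {
    if (ma == mb) {
      return(tibble(t = 0, df = na + nb - 2, p_value = 1, mean_a = ma,
                    mean_b = mb, mean_diff = 0, n_a = na, n_b = nb,
                    method = method, degenerate = TRUE))
    }
    return(tibble(t = sign(ma - mb) * Inf, df = na + nb - 2, p_value = 0,
                  mean_a = ma, mean_b = mb, mean_diff = ma - mb,
                  n_a = na, n_b = nb, method = method, degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch,
                       alternative = "two.sided")
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value, mean_a = ma, mean_b = mb,
         mean_diff = ma - mb, n_a = na, n_b = nb, method = method,
         degenerate = FALSE)
}

#' Per-group mean and standard deviation summaries
#'
#' The reporting convention for all quantifications is mean plus/minus
#' standard deviation over cells.
#'
#' @param data A data frame.
#' @param value Column (tidy-eval) holding the per-cell values.
#' @param group Column (tidy-eval) holding group labels.
#' @return Tibble: `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(data, value, group) {
  data |>
    group_by(group = {{ group }}) |>
    summarise(n = dplyr::n(), mean = mean({{ value }}, na.rm = TRUE),
              sd = sd({{ value }}, na.rm = TRUE), .groups = "drop")
}
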