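#' Per-individual percent change
#'
#' The paired response statistic `V = 100 * (post - pre) / pre`. A zero
#' pre-value yields an explicit `NA` (percent change undefined).
#'
#' @param pre,post Paired numeric vectors (pre- and post-treatment).
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(90.0, 77.2) # -14.22
#' percent_change(24.48, 9.79) # -60
#' @export
percent_change <- function(pre, post) {
  ifelse(is.finite(pre) & pre != 0, 100 * (post - pre) / pre, NA_real_)
}

#' Paired CTL/CR response table
#'
#' Pivots a tidy per-animal metric table into one row per animal x
#' variable with the control value, the restricted value and the
#' per-individual percent change.
#'
#' @param metrics Tidy tibble with columns `animal_id`, `sex`,
#'   `condition` (`"CTL"`/`"CR"`), `variable`, `value`.
#' @return A tibble: `animal_id`, `sex`, `variable`, `value_ctl`,
#'   `value_cr`, `v_pct`.
#' @export
response_table <- function(metrics) {
  stopifnot(all(c("animal_id", "sex", "condition", "variable", "value")
  %in% names(metrics)))
  if (!all(metrics$condition %in% c("CTL", "CR"))) {
    abort("`condition` must be \"CTL\" or \"CR\"")
  }
  metrics |>
    tidyr::pivot_wider(
      id_cols = c("animal_id", "sex", "variable"),
      names_from = "condition", values_from = "value"
    ) |>
    dplyr::rename(value_ctl = "CTL", value_cr = "CR") |>
    dplyr::mutate(v_pct = percent_change(.data$value_ctl, .data$value_cr))
}

#' Group summaries and contrasts of a response table
#'
#' Builds a report in the layout of a sex-stratified caloric-restriction
#' summary table: per variable, mean and SD for each sex x condition
#' group, the per-sex mean and SD of the per-individual percent change
#' (`V°f`, `V°m`), and exact nonparametric contrasts — a paired exact
#' signed-rank test of the CR effect within each sex, an unpaired exact
#' rank-sum test of the initial (CTL) sex difference, and an unpaired
#' exact rank-sum test of the sex difference in the percent-change
#' response. p-values carry the conventional annotation ladder
#' (`***` < 0.001, `**` < 0.01, `*` < 0.05, `°` < 0.1).
#'
#' @param resp A [response_table()].
#' @return A tibble, one row per variable.
#' @export
response_summary <- function(resp) {
  resp |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(df, key) {
      g <- function(sex, col) df[[col]][df$sex == sex]
      msd <- function(x) {
        c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
      }
      safe_p <- function(expr) {
        tryCatch(expr$p.value, error = function(e) NA_real_)
      }
      cc <- function(x, y) {
        ok <- complete.cases(x, y)
        list(x = x[ok], y = y[ok])
      }
      pf <- cc(g("F", "value_ctl"), g("F", "value_cr"))
      pm <- cc(g("M", "value_ctl"), g("M", "value_cr"))
      p_cr_f <- safe_p(exact_signed_rank(pf$x, pf$y))
      p_cr_m <- safe_p(exact_signed_rank(pm$x, pm$y))
      p_sex_ctl <- safe_p(exact_rank_sum(
        g("F", "value_ctl")[is.finite(g("F", "value_ctl"))],
        g("M", "value_ctl")[is.finite(g("M", "value_ctl"))]
      ))
      p_sex_resp <- safe_p(exact_rank_sum(
        g("F", "v_pct")[is.finite(g("F", "v_pct"))],
        g("M", "v_pct")[is.finite(g("M", "v_pct"))]
      ))
      fc <- msd(g("F", "value_ctl"))
      mc <- msd(g("M", "value_ctl"))
      fr <- msd(g("F", "value_cr"))
      mr <- msd(g("M", "value_cr"))
      vf <- msd(g("F", "v_pct"))
      vm <- msd(g("M", "v_pct"))
      tibble::tibble(
        ctl_f_mean = fc[["mean"]], ctl_f_sd = fc[["sd"]],
        ctl_m_mean = mc[["mean"]], ctl_m_sd = mc[["sd"]],
        cr_f_mean = fr[["mean"]], cr_f_sd = fr[["sd"]],
        cr_m_mean = mr[["mean"]], cr_m_sd = mr[["sd"]],
        v_f_mean = vf[["mean"]], v_f_sd = vf[["sd"]],
        v_m_mean = vm[["mean"]], v_m_sd = vm[["sd"]],
        p_sex_ctl = p_sex_ctl, p_cr_f = p_cr_f, p_cr_m = p_cr_m,
        p_sex_resp = p_sex_resp,
        sig_sex_ctl = sig_ladder(p_sex_ctl),
        sig_cr_f = sig_ladder(p_cr_f),
        sig_cr_m = sig_ladder(p_cr_m),
        sig_sex_resp = sig_ladder(p_sex_resp)
      )
    }) |>
    dplyr::ungroup()
}

## ---- Dixon's Q outlier screen -----------------------------------------

# two-tailed 95% critical values, r10 (n 3-7), r11 (n 8-10), r22 (n 11-13)
dixon_crit_05 <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.615, `9` = 0.570, `10` = 0.534,
  `11` = 0.625, `12` = 0.592, `13` = 0.565
)

#' Dixon's Q outlier test
#'
#' Screens a small sample (3 <= n <= 13) for a single outlier at either
#' extreme using the ratio variant recommended for the sample size:
#' `r10` (gap/range) for n <= 7, `r11` for 8--10, `r22` for 11--13,
#' compared against the embedded two-tailed critical values at
#' alpha = 0.05. Both extremes are tested; the larger ratio is the
#' suspect.
#'
#' @param values Numeric vector, 3 to 13 finite values.
#' @return A one-row tibble: `n`, `variant`, `q` (the larger of the two
#'   one-sided ratios), `q_crit`, `outlier` (verdict), `suspect` (the
#'   suspect value, `NA` when the sample is constant).
#' @examples
#' dixon_q(c(1, 2, 3, 4, 100)) # outlier (Q ~ 0.970 > 0.710)
#' dixon_q(c(1, 2, 3, 4, 5)) # no outlier (Q = 0.25)
#' @export
dixon_q <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 13) abort("Dixon's Q requires 3 <= n <= 13")
  x <- sort(values)
  variant <- if (n <= 7) "r10" else if (n <= 10) "r11" else "r22"
  if (x[n] == x[1]) {
    return(tibble::tibble(
      n = n, variant = variant, q = NA_real_,
      q_crit = unname(dixon_crit_05[as.character(n)]),
      outlier = FALSE, suspect = NA_real_
    ))
  }
  ratios <- switch(variant,
    r10 = c(
      low = (x[2] - x[1]) / (x[n] - x[1]),
      high = (x[n] - x[n - 1]) / (x[n] - x[1])
    ),
    r11 = c(
      low = (x[2] - x[1]) / (x[n - 1] - x[1]),
      high = (x[n] - x[n - 1]) / (x[n] - x[2])
    ),
    r22 = c(
      low = (x[3] - x[1]) / (x[n - 2] - x[1]),
      high = (x[n] - x[n - 2]) / (x[n] - x[3])
    )
  )
  ratios[!is.finite(ratios)] <- NA_real_
  side <- which.max(ratios)
  q <- ratios[side]
  crit <- unname(dixon_crit_05[as.character(n)])
  tibble::tibble(
    n = n, variant = variant, q = unname(q), q_crit = crit,
    outlier = is.finite(q) && q > crit,
    suspect = if (names(ratios)[side] == "low") x[1] else x[n]
  )
}

## ---- exact rank tests -------------------------------------------------

# distribution of a sum over subsets, by generating-function convolution
# on a half-unit grid (midranks are multiples of 1/2)
subset_sum_dist <- function(weights) {
  w2 <- round(2 * weights)
  total <- sum(w2)
  dist <- numeric(total + 1) # counts for sums 0..total (in half-units)
  dist[1] <- 1
  for (w in w2) {
    shifted <- c(rep(0, w), dist[seq_len(total + 1 - w)])
    dist <- dist + shifted
  }
  dist
}

two_sided_p <- function(dist, stat2) {
  # dist: counts over statistic values 0..(len-1) in half-units
  tot <- sum(dist)
  lo <- sum(dist[seq_len(stat2 + 1)]) / tot
  hi <- sum(dist[(stat2 + 1):length(dist)]) / tot
  min(1, 2 * min(lo, hi))
}

new_exact_test <- function(statistic, p, method, n, degenerate = FALSE) {
  structure(
    list(
      statistic = statistic, p.value = p, method = method, n = n,
      degenerate = degenerate
    ),
    class = c("exact_rank_test", "htest")
  )
}

#' Exact Wilcoxon signed-rank test (full enumeration)
#'
#' Two-sided paired test computed from the exact null distribution of the
#' positive-rank sum over all `2^m` sign assignments of the nonzero
#' differences (midranks for tied absolute differences, zeros dropped).
#' With at most a dozen pairs the full enumeration is both feasible and
#' free of large-sample approximation. All-zero differences give p = 1
#' with a degeneracy flag.
#'
#' @param x,y Paired samples; or a single vector of differences via `x`
#'   with `y = NULL`.
#' @return An object of classes `exact_rank_test`/`htest` with
#'   `statistic` (W+), `p.value`, `n` (nonzero pairs) and `degenerate`.
#' @examples
#' exact_signed_rank(c(2, 3, 1, 4, 2, 5), rep(0, 6))$p.value # 2/64
#' @export
exact_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y)) abort("`x`, `y` must be paired")
  d <- d[is.finite(d)]
  d0 <- d[d != 0]
  if (length(d0) == 0) {
    return(new_exact_test(
      NA_real_, 1, "exact Wilcoxon signed-rank (all differences zero)",
      0L,
      degenerate = TRUE
    ))
  }
  if (length(d0) > 20) abort("exact enumeration supported for <= 20 pairs")
  r <- rank(abs(d0))
  w <- sum(r[d0 > 0])
  dist <- subset_sum_dist(r)
  p <- two_sided_p(dist, round(2 * w))
  new_exact_test(w, p, "exact Wilcoxon signed-rank", length(d0))
}

#' Exact Wilcoxon rank-sum test (full enumeration)
#'
#' Two-sided unpaired test from the exact null distribution of the
#' first-group rank sum over all `choose(n1 + n2, n1)` assignments of the
#' pooled midranks.
#'
#' @param x,y Two independent samples.
#' @return An `exact_rank_test`/`htest` object.
#' @examples
#' exact_rank_sum(1:6, 7:12)$p.value # 2/924
#' @export
exact_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  if (n1 + n2 > 24) abort("exact enumeration supported for n1 + n2 <= 24")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  combos <- combn(n1 + n2, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  lo <- mean(sums <= w + 1e-9)
  hi <- mean(sums >= w - 1e-9)
  p <- min(1, 2 * min(lo, hi))
  new_exact_test(w, p, "exact Wilcoxon rank-sum", c(n1 = n1, n2 = n2))
}

#' @export
print.exact_rank_test <- function(x, ...) {
  cat("<", x$method, "> W = ", x$statistic,
    ", p = ", signif(x$p.value, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.exact_rank_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$statistic), p.value = x$p.value,
    method = x$method, degenerate = x$degenerate
  )
}

## ---- correlation network ----------------------------------------------

#' Pairwise correlation network
#'
#' Pairwise correlations between variables on pooled pre/post rows,
#' computed within each group (typically each sex) separately. Edges are
#' retained where `|r|` meets the threshold; the sign is kept. Constant
#' variables are excluded with a notice, and pairs with fewer than 3
#' complete observations are dropped.
#'
#' @param data Wide tibble, rows = observations, numeric variable
#'   columns.
#' @param vars Variable columns to correlate (default: all numeric).
#' @param group_col Optional grouping column name (e.g. `"sex"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param threshold Minimum `|r|` for an edge (default 0.5).
#' @return Edge-list tibble: (`group`,) `var1`, `var2`, `r`, `n`.
#' @export
correlation_network <- function(data, vars = NULL, group_col = NULL,
                                method = c("pearson", "spearman"),
                                threshold = 0.5) {
  method <- match.arg(method)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, group_col)
  }
  one_group <- function(df, label) {
    m <- as.matrix(df[vars])
    const <- apply(m, 2, function(col) {
      v <- col[is.finite(col)]
      length(v) > 0 && var(v) == 0
    })
    if (any(const)) {
      inform(paste0(
        "excluding constant variable(s): ",
        paste(vars[const], collapse = ", ")
      ))
    }
    use <- vars[!const]
    pairs <- utils::combn(use, 2)
    purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- m[, pairs[1, k]]
      b <- m[, pairs[2, k]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3) {
        return(NULL)
      }
      tibble::tibble(
        group = label, var1 = pairs[1, k], var2 = pairs[2, k],
        r = cor(a[ok], b[ok], method = method), n = sum(ok)
      )
    }) |>
      purrr::list_rbind()
  }
  edges <- if (is.null(group_col)) {
    one_group(data, NA_character_)
  } else {
    split(data, data[[group_col]]) |>
      purrr::imap(one_group) |>
      purrr::list_rbind()
  }
  dplyr::filter(edges, abs(.data$r) >= threshold)
}

## ---- PCA with dimension description ------------------------------------

#' PCA with variable and category description
#'
#' Standardised principal component analysis of an
#' observation-by-variable matrix with simple column-mean imputation of
#' missing cells. Besides scores, loadings and percent variance it
#' reports, for each component, the Pearson correlation of every variable
#' with the component scores (with its two-sided p-value) and, for each
#' level of a grouping factor, the v-statistic
#' \deqn{v = (\bar x_{cat} - \bar x) / \sqrt{\frac{N-n}{N-1}\,\frac{\sigma^2}{n}}}
#' comparing the category's mean score with the grand mean.
#'
#' @param data Wide tibble/matrix of numeric variables (rows =
#'   observations); missing entries allowed.
#' @param groups Optional factor/character vector of row categories.
#' @param n_components Number of components to describe (default all).
#' @return An object of class `pca_desc`: list with `scores`, `loadings`,
#'   `pct_var`, `var_cor` (variable x component `r` and `p`), `cat_v`
#'   (category x component v-statistic and p), `imputed` (logical matrix),
#'   `dropped` (zero-variance columns).
#' @export
pca_describe <- function(data, groups = NULL, n_components = NULL) {
  m <- as.matrix(as.data.frame(data))
  if (!is.numeric(m)) abort("`data` must be numeric")
  if (ncol(m) < 2 || nrow(m) < 3) abort("need >= 2 variables and >= 3 rows")
  imputed <- !is.finite(m)
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[is.finite(m[, j]), j])
    m[imputed[, j], j] <- mu
  }
  v <- apply(m, 2, var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped) > 0) {
    inform(paste0(
      "dropping zero-variance column(s): ", paste(dropped, collapse = ", ")
    ))
    m <- m[, v > 0, drop = FALSE]
    imputed <- imputed[, v > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- n_components %||% ncol(pc$x)
  k <- min(k, ncol(pc$x))
  pct_var <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  comp <- colnames(pc$x)[seq_len(k)]
  n <- nrow(m)
  var_cor <- purrr::map(comp, function(pcname) {
    purrr::map(colnames(m), function(vn) {
      ct <- suppressWarnings(cor.test(m[, vn], pc$x[, pcname]))
      tibble::tibble(
        component = pcname, variable = vn,
        r = unname(ct$estimate), p = ct$p.value
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  cat_v <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    cat_v <- purrr::map(comp, function(pcname) {
      s <- pc$x[, pcname]
      sig2 <- sum((s - mean(s))^2) / n # population variance of the scores
      purrr::map(unique(groups), function(gr) {
        idx <- groups == gr
        ng <- sum(idx)
        se <- sqrt((n - ng) / (n - 1) * sig2 / ng)
        vstat <- (mean(s[idx]) - mean(s)) / se
        tibble::tibble(
          component = pcname, category = gr, n = ng,
          v = vstat, p = 2 * pnorm(-abs(vstat))
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  structure(
    list(
      scores = pc$x, loadings = pc$rotation, pct_var = pct_var,
      var_cor = var_cor, cat_v = cat_v, imputed = imputed,
      dropped = dropped, groups = groups,
      center = pc$center, scale = pc$scale
    ),
    class = "pca_desc"
  )
}

#' @export
print.pca_desc <- function(x, ...) {
  cat(
    "<pca_desc> ", nrow(x$scores), " observations, ",
    ncol(x$loadings), " variables\n",
    "  variance: ", paste0(
      sprintf("PC%d %.1f%%", seq_len(min(4, length(x$pct_var))),
        x$pct_var[seq_len(min(4, length(x$pct_var)))]
      ),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn pca_describe Loadings and per-component variance in long
#'   form (broom convention).
#' @param x A `pca_desc` object.
#' @param ... Unused.
#' @export
tidy.pca_desc <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable",
      names_to = "component", values_to = "loading"
    ) |>
    dplyr::left_join(
      tibble::tibble(
        component = colnames(x$loadings), pct_var = x$pct_var
      ),
      by = "component"
    )
}

#' @describeIn pca_describe One-row summary.
#' @export
glance.pca_desc <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$scores), n_vars = ncol(x$loadings),
    pct_var_pc1 = x$pct_var[1],
    pct_var_pc2 = if (length(x$pct_var) > 1) x$pct_var[2] else NA_real_,
    n_imputed = sum(x$imputed)
  )
}

#' @describeIn pca_describe Score plot on the first two components,
#'   coloured by category.
#' @param object A `pca_desc` object.
#' @export
autoplot.pca_desc <- function(object, ...) {
  df <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE])
  names(df) <- c("PC1", "PC2")
  if (!is.null(object$groups)) df$group <- object$groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pct_var[1]),
      y = sprintf("PC2 (%.1f%%)", object$pct_var[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
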