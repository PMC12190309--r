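#' Tukey-fence (1.5 x IQR) participant exclusion
#'
#' Screens participant summaries for outliers the way gait studies usually
#' do: for each group and each screened metric, quartiles (type-7) and the
#' interquartile range are computed on the reference speed condition, and
#' fences placed at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`. A participant falling
#' strictly outside any fence is removed from *all* conditions. With zero
#' IQR (all values equal) every value sits on the fence and nobody is
#' excluded, since exclusion requires a strict exceedance.
#'
#' @param summaries participant-level tibble with columns `participant`,
#'   `group`, `speed_cond` and the metric columns.
#' @param metrics character vector of metric columns to screen (default MARP
#'   and DP).
#' @param reference_cond speed condition on which fences are computed.
#' @param k fence multiplier (1.5 = Tukey's rule).
#' @return list with `retained` (filtered summaries) and `excluded`
#'   (log tibble: participant, group, metric, value, fence bounds).
#' @export
iqr_exclude <- function(summaries, metrics = c("marp_deg", "dp_deg"),
                        reference_cond = "preferred", k = 1.5) {
  stopifnot(all(c("participant", "group", "speed_cond") %in% names(summaries)))
  missing <- setdiff(metrics, names(summaries))
  if (length(missing) > 0) {
    abort(sprintf("metric column(s) not found: %s", paste(missing, collapse = ", ")))
  }
  ref <- dplyr::filter(summaries, .data$speed_cond == reference_cond)
  counts <- dplyr::count(dplyr::distinct(ref, .data$participant, .data$group),
                         .data$group)
  if (any(counts$n < 4)) {
    abort("need at least 4 participants per group to place Tukey fences")
  }
  logs <- list()
  for (g in unique(ref$group)) {
    sub <- dplyr::filter(ref, .data$group == g)
    for (m in metrics) {
      v <- sub[[m]]
      q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
      iqr <- q[2] - q[1]
      lo <- q[1] - k * iqr
      hi <- q[2] + k * iqr
      out <- which(v < lo | v > hi)
      if (length(out) > 0) {
        logs[[length(logs) + 1]] <- tibble::tibble(
          participant = sub$participant[out], group = g, metric = m,
          value = v[out], fence_low = unname(lo), fence_high = unname(hi)
        )
      }
    }
  }
  excluded <- if (length(logs) > 0) dplyr::bind_rows(logs) else
    tibble::tibble(participant = character(), group = character(),
                   metric = character(), value = numeric(),
                   fence_low = numeric(), fence_high = numeric())
  retained <- dplyr::filter(summaries,
                            !.data$participant %in% unique(excluded$participant))
  if (nrow(retained) == 0) abort("Tukey-fence screening excluded every participant")
  list(retained = retained, excluded = excluded)
}

check_cells <- function(data, f1, f2) {
  for (f in c(f1, f2)) {
    if (length(unique(data[[f]])) < 2) {
      abort(sprintf("factor '%s' has a single level: every cell of the other level is empty", f))
    }
  }
  tab <- table(data[[f1]], data[[f2]])
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("design cell %s x %s is empty",
                  rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  invisible(tab)
}

anova_table <- function(model) {
  a3 <- car::Anova(model, type = 3)
  tab <- as.data.frame(a3)
  terms <- rownames(tab)
  keep <- !terms %in% c("(Intercept)", "Residuals")
  ss_res <- tab["Residuals", "Sum Sq"]
  df_res <- tab["Residuals", "Df"]
  tibble::tibble(
    term = terms[keep],
    df1 = tab$Df[keep],
    df2 = df_res,
    sum_sq = tab$`Sum Sq`[keep],
    statistic = tab$`F value`[keep],
    p_value = tab$`Pr(>F)`[keep],
    partial_eta2 = tab$`Sum Sq`[keep] / (tab$`Sum Sq`[keep] + ss_res)
  )
}

bonferroni_posthoc <- function(model, factors, which_terms) {
  ph <- list()
  for (f in which_terms) {
    emm <- suppressMessages(
      emmeans::emmeans(model, stats::as.formula(paste("~", f))))
    cmp <- summary(emmeans::contrast(emm, method = "pairwise"),
                   adjust = "bonferroni")
    ph[[length(ph) + 1]] <- tibble::tibble(
      effect = f,
      contrast = as.character(cmp$contrast),
      estimate = cmp$estimate,
      se = cmp$SE,
      df = cmp$df,
      t_ratio = cmp$t.ratio,
      p_adjusted = cmp$p.value
    )
  }
  if (length(ph) > 0) dplyr::bind_rows(ph) else
    tibble::tibble(effect = character(), contrast = character(),
                   estimate = numeric(), se = numeric(), df = numeric(),
                   t_ratio = numeric(), p_adjusted = numeric())
}

#' Two-way ANOVA on pooled observations
#'
#' Fits `response ~ group * condition` on observations pooled across
#' participants (fixed effects only, matching the denominator degrees of
#' freedom conventionally reported for this design) with type-III sums of
#' squares and sum-to-zero contrasts, reporting F, p and partial eta squared
#' per term, plus Bonferroni-adjusted pairwise post hocs for significant
#' main effects.
#'
#' @param data tibble of observations.
#' @param response response column name (e.g. `"walking_speed_mps"`).
#' @param factors length-2 character vector of factor column names.
#' @param alpha significance level gating the post hocs.
#' @return a `gait_anova` object: `table` (per-term tibble), `posthoc`,
#'   `model` (the underlying `lm`), with `tidy()`/`glance()` methods.
#' @export
two_way_anova <- function(data, response, factors = c("group", "speed_cond"),
                          alpha = 0.05) {
  f1 <- factors[1]; f2 <- factors[2]
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(factors), as.factor))
  check_cells(data, f1, f2)
  fml <- stats::as.formula(sprintf("%s ~ %s * %s", response, f1, f2))
  ctr <- stats::setNames(list("contr.sum", "contr.sum"), factors)
  model <- stats::lm(fml, data = data, contrasts = ctr)
  tab <- anova_table(model)
  mains <- tab$term %in% factors & tab$p_value < alpha
  posthoc <- bonferroni_posthoc(model, factors, tab$term[mains])
  structure(list(table = tab, posthoc = posthoc, model = model,
                 alpha = alpha, response = response, kind = "anova"),
            class = "gait_anova")
}

#' Two-way ANCOVA with a walking-speed covariate
#'
#' Fits `response ~ group * condition + covariate` on pooled observations
#' (type-III sums of squares, sum-to-zero contrasts). The interaction is
#' examined first: only when it is significant at `alpha` are simple main
#' effects (pairwise group contrasts within each condition and vice versa)
#' computed; otherwise post hocs are reported for significant main effects,
#' mirroring the usual gating logic. Effect sizes are partial eta squared.
#'
#' @inheritParams two_way_anova
#' @param covariate covariate column name (actual walking speed, m/s).
#' @return a `gait_anova` object (see [two_way_anova()]).
#' @export
two_way_ancova <- function(data, response, covariate = "walking_speed_mps",
                           factors = c("group", "speed_cond"), alpha = 0.05) {
  f1 <- factors[1]; f2 <- factors[2]
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(factors), as.factor))
  check_cells(data, f1, f2)
  wv <- dplyr::summarise(
    dplyr::group_by(data, .data[[f1]], .data[[f2]]),
    v = stats::var(.data[[covariate]]), .groups = "drop")
  if (all(is.na(wv$v) | wv$v == 0)) {
    abort("covariate has zero within-cell variance: it is collinear with the design")
  }
  fml <- stats::as.formula(sprintf("%s ~ %s * %s + %s", response, f1, f2, covariate))
  ctr <- stats::setNames(list("contr.sum", "contr.sum"), factors)
  model <- stats::lm(fml, data = data, contrasts = ctr)
  tab <- anova_table(model)
  int_term <- paste0(f1, ":", f2)
  int_p <- tab$p_value[tab$term == int_term]
  if (length(int_p) == 1 && !is.na(int_p) && int_p < alpha) {
    # simple main effects: factor contrasts within levels of the other factor
    ph <- list()
    for (f in factors) {
      other <- setdiff(factors, f)
      emm <- suppressMessages(
        emmeans::emmeans(model, stats::as.formula(paste("~", f, "|", other))))
      cmp <- summary(emmeans::contrast(emm, method = "pairwise"),
                     adjust = "bonferroni")
      ph[[length(ph) + 1]] <- tibble::tibble(
        effect = paste0("simple:", f, "|", other),
        contrast = paste(as.character(cmp$contrast), as.character(cmp[[other]]),
                         sep = " @ "),
        estimate = cmp$estimate, se = cmp$SE, df = cmp$df,
        t_ratio = cmp$t.ratio, p_adjusted = cmp$p.value)
    }
    posthoc <- dplyr::bind_rows(ph)
  } else {
    mains <- tab$term %in% factors & tab$p_value < alpha
    posthoc <- bonferroni_posthoc(model, factors, tab$term[mains])
  }
  structure(list(table = tab, posthoc = posthoc, model = model,
                 alpha = alpha, response = response, kind = "ancova"),
            class = "gait_anova")
}

#' @export
print.gait_anova <- function(x, ...) {
  cat(sprintf("<gait_anova> %s on %s\n", x$kind, x$response))
  print(as.data.frame(x$table), digits = 4)
  if (nrow(x$posthoc) > 0) {
    cat("post hoc (Bonferroni):\n")
    print(as.data.frame(x$posthoc), digits = 4)
  }
  invisible(x)
}

#' @rdname two_way_anova
#' @param x a `gait_anova`.
#' @param ... unused.
#' @export
tidy.gait_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @export
glance.gait_anova <- function(x, ...) {
  tibble::tibble(
    response = x$response, kind = x$kind,
    r_squared = summary(x$model)$r.squared,
    df_residual = x$table$df2[1],
    n = stats::nobs(x$model)
  )
}

# Pointwise pooled two-sample t statistics over waveform nodes, with an
# epsilon floor on the pooled SD so zero-variance nodes yield large finite t.
pointwise_t <- function(sumA, sqA, nA, sumB, sqB, nB) {
  mA <- sumA / nA
  mB <- sumB / nB
  vA <- pmax(0, (sqA - sumA^2 / nA) / (nA - 1))
  vB <- pmax(0, (sqB - sumB^2 / nB) / (nB - 1))
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  eps <- 1e-8 * pmax(1, abs(mA), abs(mB))
  (mA - mB) / pmax(sqrt(sp2 * (1 / nA + 1 / nB)), eps)
}

#' Permutation-based 1-D statistical parametric mapping (two-sample t)
#'
#' Compares two groups of gait-cycle waveforms (rows = participants,
#' columns = 101 nodes) pointwise with a pooled two-sample t statistic, and
#' controls the family-wise error over the whole cycle with the max-statistic
#' permutation method: group labels are randomly permuted `n_perm` times (the
#' observed labelling is always included), the maximum of `|t|` over nodes is
#' collected for each permutation, and the critical threshold `t*` is the
#' `ceiling((1 - alpha) n_perm)`-th order statistic of that distribution.
#' Maximal runs of nodes with `|t| > t*` form supra-threshold clusters.
#'
#' Nodes where both groups have zero variance fall back to an epsilon-floored
#' pooled SD (`1e-8` times the response scale), so a genuine mean difference
#' at a degenerate node still registers as a (large, finite) t value.
#'
#' @param ya,yb numeric matrices of waveforms (n_subjects x 101), one per
#'   group.
#' @param alpha family-wise significance level.
#' @param n_perm number of permutations (>= 100 recommended; fewer warns).
#' @param seed optional RNG seed for the permutation draw.
#' @return an `spm_result`: `t` (101 node t values), `t_star`, `clusters`
#'   (tibble: start/end/extent in % gait cycle, peak t), `p_max` (global
#'   permutation p for the max statistic), `alpha`, `n_perm`.
#' @export
spm_ttest2 <- function(ya, yb, alpha = 0.05, n_perm = 1000, seed = NULL) {
  ya <- as.matrix(ya)
  yb <- as.matrix(yb)
  if (ncol(ya) != ncol(yb)) abort("waveform matrices differ in node count")
  nA <- nrow(ya); nB <- nrow(yb)
  if (nA < 2 || nB < 2) abort("need at least 2 waveforms per group")
  if (nA < 3 || nB < 3) warn("fewer than 3 waveforms in a group: the permutation distribution is very coarse")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (n_perm < 100) warn("fewer than 100 permutations: the critical threshold is unstable")
  if (!is.null(seed)) set.seed(seed)
  X <- rbind(ya, yb)
  X2 <- X^2
  n <- nA + nB
  totS <- colSums(X)
  totQ <- colSums(X2)
  t_obs <- pointwise_t(colSums(ya), colSums(ya^2), nA,
                       colSums(yb), colSums(yb^2), nB)
  max_t <- numeric(n_perm)
  max_t[1] <- max(abs(t_obs))
  for (p in seq_len(n_perm - 1)) {
    idx <- sample.int(n, nA)
    sA <- colSums(X[idx, , drop = FALSE])
    qA <- colSums(X2[idx, , drop = FALSE])
    tp <- pointwise_t(sA, qA, nA, totS - sA, totQ - qA, nB)
    max_t[p + 1] <- max(abs(tp))
  }
  t_star <- sort(max_t)[ceiling((1 - alpha) * n_perm)]
  supra <- abs(t_obs) > t_star
  clusters <- cluster_runs(supra, t_obs)
  structure(
    list(t = t_obs, t_star = t_star, clusters = clusters,
         p_max = mean(max_t >= max(abs(t_obs))),
         alpha = alpha, n_perm = n_perm, n = c(nA = nA, nB = nB)),
    class = "spm_result"
  )
}

cluster_runs <- function(supra, t_obs) {
  pct <- seq(0, 100, length.out = length(supra))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(
    cluster = seq_along(keep),
    start_pct = pct[starts[keep]],
    end_pct = pct[ends[keep]],
    extent_pct = pct[ends[keep]] - pct[starts[keep]],
    peak_t = vapply(keep, function(i) {
      seg <- t_obs[starts[i]:ends[i]]
      seg[which.max(abs(seg))]
    }, numeric(1))
  )
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> two-sample permutation SPM: n = %d + %d, %d permutations\n",
              x$n[1], x$n[2], x$n_perm))
  cat(sprintf("  t* = %.3f (alpha %.2f), max |t| = %.3f, p = %.4f\n",
              x$t_star, x$alpha, max(abs(x$t)), x$p_max))
  if (nrow(x$clusters) > 0) {
    print(as.data.frame(x$clusters), digits = 3)
  } else {
    cat("  no supra-threshold clusters\n")
  }
  invisible(x)
}

#' @rdname spm_ttest2
#' @param x an `spm_result`.
#' @param ... unused.
#' @export
tidy.spm_result <- function(x, ...) {
  tibble::tibble(
    pct = seq(0, 100, length.out = length(x$t)),
    t = x$t,
    t_star = x$t_star,
    supra_threshold = abs(x$t) > x$t_star
  )
}

#' @rdname spm_ttest2
#' @export
glance.spm_result <- function(x, ...) {
  tibble::tibble(
    t_star = x$t_star, max_abs_t = max(abs(x$t)), p_max = x$p_max,
    n_clusters = nrow(x$clusters), alpha = x$alpha, n_perm = x$n_perm,
    n_a = x$n[1], n_b = x$n[2]
  )
}
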