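#' Group-comparison statistics for hair-cell cohorts
#'
#' Implementations of the comparison battery used for nuclear-position,
#' recruitment and gap-length cohorts: normality pre-tests, Kruskal-Wallis
#' with Dunn's post hoc, one/two-way ANOVA with Tukey HSD, per-condition
#' Welch t tests under two-stage step-up FDR control, Mann-Whitney, and
#' per-region cell counting. All tests return an `hcm_test` object carrying
#' the statistic, raw and adjusted p values, and per-group summaries.
#'
#' @name cohort_stats
NULL

.hcm_test <- function(method, statistic, p_value, groups = NULL,
                      comparisons = NULL, details = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 groups = groups, comparisons = comparisons,
                 details = details),
            class = "hcm_test")
}

#' @export
print.hcm_test <- function(x, ...) {
  cat(x$method, "\n")
  if (length(x$statistic))
    cat("  ", paste(names(x$statistic), signif(x$statistic, 5),
                    sep = " = ", collapse = ", "), "\n")
  cat("  p =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.null(x$comparisons)) {
    cat("  pairwise comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

.group_summary <- function(values, groups) {
  lv <- unique(groups)
  data.frame(group = lv,
             n = vapply(lv, function(g) sum(is.finite(values[groups == g])), 0L),
             mean = vapply(lv, function(g) mean(values[groups == g], na.rm = TRUE), 0),
             sd = vapply(lv, function(g) sd(values[groups == g], na.rm = TRUE), 0),
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact by full enumeration of group assignments when both arms have at
#' most `exact_max` observations (ties handled exactly through midranks);
#' otherwise the tie-corrected normal approximation with continuity
#' correction. The statistic U counts pairs where `a` exceeds `b` (ties
#' count half), so identical samples give U = n1*n2/2.
#'
#' @param a,b numeric vectors (non-empty).
#' @param labels length-2 labels for the two arms.
#' @param exact_max enumeration cutoff per arm.
#' @return an `hcm_test`.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b"), exact_max = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both arms must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    mode <- "exact enumeration"
  } else {
    N <- n1 + n2
    t <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      mode <- "degenerate (all tied)"
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(0, z)))
      mode <- "tie-corrected normal approximation"
    }
  }
  .hcm_test(method = paste0("Mann-Whitney U (two-sided, ", mode, ")"),
            statistic = c(U = U), p_value = p,
            groups = .group_summary(pooled, rep(labels, c(n1, n2))),
            details = list(mode = mode, n = c(n1, n2)))
}

#' Kruskal-Wallis test with Dunn's pairwise post hoc
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (delegated to [stats::kruskal.test()]), followed by Dunn's z tests on
#' mean ranks for every pair of groups, with Bonferroni adjustment over all
#' pairs by default. Identical constant data is degenerate by convention:
#' H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, parallel to `values`.
#' @param p_adjust adjustment across pairs, any [stats::p.adjust()] method.
#' @return an `hcm_test`; `$comparisons` has one row per pair with `z`,
#'   `p_raw` and `p_adj`.
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "bonferroni") {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least two non-empty groups", call. = FALSE)
  gsum <- .group_summary(values, groups)
  pairs <- combn(lv, 2)
  if (length(unique(values)) == 1L) {
    comparisons <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                              z = 0, p_raw = 1, p_adj = 1,
                              stringsAsFactors = FALSE)
    return(.hcm_test("Kruskal-Wallis with Dunn's post hoc (degenerate: all values tied)",
                     c(H = 0), 1, gsum, comparisons,
                     details = list(degenerate = TRUE, p_adjust = p_adjust)))
  }
  kw <- kruskal.test(values, factor(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- vapply(lv, function(g) mean(r[groups == g]), 0)
  n <- vapply(lv, function(g) sum(groups == g), 0L)
  ties <- table(values)
  S2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(S2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  comparisons <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                            z = z, p_raw = p_raw,
                            p_adj = p.adjust(p_raw, method = p_adjust),
                            stringsAsFactors = FALSE)
  .hcm_test("Kruskal-Wallis with Dunn's post hoc",
            c(H = unname(kw$statistic)), kw$p.value, gsum, comparisons,
            details = list(df = unname(kw$parameter), p_adjust = p_adjust))
}

#' One- or two-way ANOVA with Tukey HSD post hoc
#'
#' One factor: classical one-way ANOVA. Two factors: the full factorial
#' model with type-II sums of squares (via [car::Anova()]) so near-balanced
#' designs with attrition are handled sensibly; balanced designs reproduce
#' the classical table. Tukey HSD (Tukey-Kramer for unequal n) adjusted
#' pairwise comparisons are reported per factor.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param factors character vector of one or two factor column names.
#' @return an `hcm_test`; `$details$effects` holds per-effect F and p,
#'   `$comparisons` the Tukey-adjusted pairwise differences.
#' @export
anova_tukey <- function(data, response = "value", factors) {
  stopifnot(length(factors) %in% 1:2,
            all(c(response, factors) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(response, factors)]), ]
  for (f in factors) d[[f]] <- factor(d[[f]])
  for (f in factors)
    if (nlevels(d[[f]]) < 2L)
      stop("factor '", f, "' needs at least two levels", call. = FALSE)
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- tryCatch(aov(fml, data = d), error = function(e)
    stop("singular design: ", conditionMessage(e), call. = FALSE))
  if (length(factors) == 1L) {
    tab <- summary(fit)[[1]]
    effects <- data.frame(effect = trimws(rownames(tab)[1]),
                          F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
                          stringsAsFactors = FALSE)
  } else {
    a2 <- car::Anova(stats::lm(fml, data = d), type = 2)
    keep <- !rownames(a2) %in% "Residuals"
    effects <- data.frame(effect = rownames(a2)[keep],
                          F = a2[keep, "F value"], p = a2[keep, "Pr(>F)"],
                          stringsAsFactors = FALSE)
  }
  tk <- TukeyHSD(fit, which = factors)
  comparisons <- do.call(rbind, lapply(names(tk), function(f) {
    m <- tk[[f]]
    data.frame(factor = f, comparison = rownames(m), diff = m[, "diff"],
               p_adj = m[, "p adj"], stringsAsFactors = FALSE)
  }))
  rownames(comparisons) <- NULL
  main <- effects[1, ]
  .hcm_test(sprintf("%d-way ANOVA (type %s) with Tukey HSD", length(factors),
                    if (length(factors) == 1L) "I" else "II"),
            c(F = main$F), main$p,
            groups = .group_summary(d[[response]],
                                    interaction(d[, factors, drop = FALSE],
                                                drop = TRUE, sep = ":")),
            comparisons = comparisons,
            details = list(effects = effects, n = nrow(d)))
}

#' Two-stage linear step-up FDR procedure
#'
#' The adaptive two-stage step-up procedure: a first Benjamini-Hochberg pass
#' at level q' = q/(1+q) estimates the number of true nulls as
#' m0 = m - r1 (r1 = first-pass rejections); a second pass at level
#' q'm/m0 yields the discoveries. Reported `q_value`s are the monotonised
#' step-up quantities m0*p(i)/i; a condition is a discovery when its
#' `q_value` is at most q' (equivalent to the second-pass rejection rule).
#'
#' @param p numeric vector of raw p values (NA allowed, never discovered).
#' @param q target false-discovery rate.
#' @return list: `discovery` (logical), `q_value`, `r1`, `m0_hat`,
#'   `stage1_level`, `stage2_level`.
#' @export
bky_step_up <- function(p, q = 0.05) {
  m <- sum(!is.na(p))
  discovery <- rep(FALSE, length(p))
  q_value <- rep(NA_real_, length(p))
  if (m == 0L)
    return(list(discovery = discovery, q_value = q_value, r1 = 0L,
                m0_hat = 0L, stage1_level = q / (1 + q), stage2_level = NA))
  q1 <- q / (1 + q)
  ok <- which(!is.na(p))
  ps <- p[ok]
  bh_count <- function(pv, level) {
    o <- order(pv)
    k <- which(pv[o] <= seq_along(pv) * level / length(pv))
    if (length(k)) max(k) else 0L
  }
  r1 <- bh_count(ps, q1)
  if (r1 == m) {
    discovery[ok] <- TRUE
    q_value[ok] <- 0
    return(list(discovery = discovery, q_value = q_value, r1 = r1,
                m0_hat = 0L, stage1_level = q1, stage2_level = Inf))
  }
  m0 <- m - r1
  o <- order(ps)
  qv <- rev(cummin(rev(m0 * ps[o] / seq_len(m))))
  q_value[ok[o]] <- qv
  discovery[ok[o]] <- qv <= q1
  list(discovery = discovery, q_value = q_value, r1 = r1, m0_hat = m0,
       stage1_level = q1, stage2_level = q1 * m / m0)
}

#' Per-condition Welch t tests with two-stage step-up FDR control
#'
#' For each condition (e.g. each age), compares the two groups with a
#' two-sided Welch (unequal-variance) t test; the resulting p values are
#' fed to [bky_step_up()] across conditions. Conditions with fewer than two
#' observations in either arm get `NA` and are never discoveries.
#'
#' @param data data frame in long format.
#' @param condition,group,value column names.
#' @param q target FDR.
#' @return data frame, one row per condition: group ns and means, `t`, `p`,
#'   `q_value`, `discovery`; the BKY bookkeeping is in attribute
#'   `"procedure"`.
#' @export
multiple_t_bky <- function(data, condition = "age", group = "group",
                           value = "value", q = 0.05) {
  stopifnot(all(c(condition, group, value) %in% names(data)))
  lv <- unique(as.character(data[[group]]))
  if (length(lv) != 2L)
    stop("exactly two groups are required, got ", length(lv), call. = FALSE)
  conds <- unique(as.character(data[[condition]]))
  rows <- lapply(conds, function(cd) {
    d <- data[as.character(data[[condition]]) == cd, ]
    x <- d[[value]][d[[group]] == lv[1]]; x <- x[is.finite(x)]
    y <- d[[value]][d[[group]] == lv[2]]; y <- y[is.finite(y)]
    rec <- data.frame(condition = cd, n1 = length(x), n2 = length(y),
                      mean1 = mean(x), mean2 = mean(y),
                      t = NA_real_, p = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) {
      rec$note <- "n < 2 in a group"
    } else {
      tt <- t.test(x, y)  # Welch by default
      rec$t <- unname(tt$statistic); rec$p <- tt$p.value
    }
    rec
  })
  out <- do.call(rbind, rows)
  proc <- bky_step_up(out$p, q = q)
  out$q_value <- proc$q_value
  out$discovery <- proc$discovery
  attr(out, "procedure") <- c(proc[c("r1", "m0_hat", "stage1_level",
                                     "stage2_level")],
                              list(q = q, groups = lv,
                                   method = "Welch t + two-stage step-up FDR"))
  out
}

#' Normality pre-tests per group
#'
#' Shapiro-Wilk and the Lilliefors-corrected Kolmogorov-Smirnov test per
#' group; a group "passes" when both p values exceed `alpha`. Groups with
#' n < 3 are reported as `NA` with a reason; constant groups fail with a
#' degenerate flag.
#'
#' @param values numeric vector.
#' @param groups labels parallel to `values`.
#' @param alpha significance level for the pass/fail call.
#' @return data frame: `group`, `n`, `shapiro_p`, `ks_p`, `pass`, `note`.
#' @export
normality_check <- function(values, groups, alpha = 0.05) {
  lv <- unique(as.character(groups))
  rows <- lapply(lv, function(g) {
    v <- values[groups == g]; v <- v[is.finite(v)]
    rec <- data.frame(group = g, n = length(v), shapiro_p = NA_real_,
                      ks_p = NA_real_, pass = NA, note = "",
                      stringsAsFactors = FALSE)
    if (length(v) < 3L) { rec$note <- "n < 3"; return(rec) }
    if (length(unique(v)) == 1L) {
      rec$pass <- FALSE; rec$note <- "degenerate: constant values"
      return(rec)
    }
    rec$shapiro_p <- shapiro.test(v)$p.value
    if (length(v) >= 4L)
      rec$ks_p <- nortest::lillie.test(v)$p.value
    else rec$note <- "Lilliefors needs n >= 4; Shapiro-Wilk only"
    rec$pass <- rec$shapiro_p > alpha &&
      (is.na(rec$ks_p) || rec$ks_p > alpha)
    rec
  })
  do.call(rbind, rows)
}

#' Count hair cells of each type within a region along the cochlear axis
#'
#' Counts cells whose position falls in the half-open window
#' `[center - span/2, center + span/2)` -- half-open so a cell on a shared
#' boundary is counted exactly once when tiling adjacent regions. The
#' conventional report is counts per 200 um at a tonotopic place such as
#' the 12 kHz region.
#'
#' @param positions numeric positions along the cochlear axis, um.
#' @param types optional cell-type labels (e.g. `"OHC"`/`"IHC"`) parallel to
#'   `positions`.
#' @param region_center window centre, um.
#' @param region_span window width, um (> 0), default 200.
#' @return named integer vector of counts per type (a single unnamed count
#'   if `types` is `NULL`).
#' @export
count_cells_per_region <- function(positions, types = NULL, region_center = 0,
                                   region_span = 200) {
  if (region_span <= 0) stop("region_span must be > 0", call. = FALSE)
  lo <- region_center - region_span / 2
  hi <- region_center + region_span / 2
  inside <- positions >= lo & positions < hi
  if (is.null(types)) return(sum(inside))
  f <- factor(types)
  vapply(levels(f), function(tp) sum(inside & f == tp), 0L)
}

#' Phenotype-onset analysis across ages
#'
#' Runs [multiple_t_bky()] over a cohort measured at several ages and
#' reports the earliest age (in the given chronological order) at which the
#' two genotypes differ at FDR `q` -- the phenotype onset.
#'
#' @param data long-format cohort: columns `age`, `group`, `value` (names
#'   configurable).
#' @param ages chronological order of age labels; defaults to order of
#'   appearance.
#' @inheritParams multiple_t_bky
#' @return list: `table` (per-age test results in chronological order) and
#'   `onset_age` (label, or `NA` if no discovery).
#' @export
onset_analysis <- function(data, ages = NULL, condition = "age",
                           group = "group", value = "value", q = 0.05) {
  if (is.null(ages)) ages <- unique(as.character(data[[condition]]))
  tab <- multiple_t_bky(data, condition, group, value, q)
  tab <- tab[match(ages, tab$condition), ]
  rownames(tab) <- NULL
  hit <- which(tab$discovery)
  list(table = tab,
       onset_age = if (length(hit)) tab$condition[min(hit)] else NA_character_)
}
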