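test_that("Mann-Whitney: exact enumeration on canonical small cases", {
  # identical multisets: U at its null centre, p = 1
  r <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(unname(r$statistic["U"]), 8)
  expect_equal(r$p_value, 1)
  # full separation at n = 2 vs 2: 2 of 6 assignments are as extreme
  r2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r2$p_value, 1 / 3)
  # agrees with wilcox.test exact p where that is available (no ties)
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(mann_whitney(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation tracks exact enumeration for mid-size arms", {
  set.seed(14)
  for (i in 1:15) {
    n1 <- sample(8:12, 1); n2 <- sample(8:12, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.3)
    p_exact <- mann_whitney(a, b, exact_max = 12)$p_value
    p_approx <- mann_whitney(a, b, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula; Dunn output is coherent", {
  # groups {1,2,3},{4,5,6},{7,8,9}: rank sums 6/15/24, no ties
  # H = 12/(9*10) * (36 + 225 + 576)/3 - 3*10 = 7.2
  r <- kruskal_dunn(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(r$statistic["H"]), 7.2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(nrow(r$comparisons), 3)
  expect_true(all(r$comparisons$p_adj >= r$comparisons$p_raw))
  expect_true(all(r$comparisons$p_adj <= 1))
  # extreme pair is the most significant
  ord <- order(r$comparisons$p_adj)
  expect_setequal(unlist(r$comparisons[ord[1], c("group1", "group2")]), c("a", "c"))
})

test_that("Kruskal-Wallis degenerates gracefully on constant data", {
  r <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(r$statistic["H"]), 0)
  expect_equal(r$p_value, 1)
  expect_true(r$details$degenerate)
  expect_error(kruskal_dunn(1:5, rep("only", 5)), "two non-empty groups")
})

test_that("Kruskal-Wallis p agrees with a permutation null on a fixed small dataset", {
  set.seed(15)
  vals <- round(rnorm(30, 5, 2), 2)
  grp <- rep(c("a", "b", "c"), each = 10)
  H_obs <- unname(kruskal_dunn(vals, grp)$statistic["H"])
  p_obs <- kruskal_dunn(vals, grp)$p_value
  perm <- replicate(2e4, {
    g <- sample(grp)
    unname(kruskal.test(vals, factor(g))$statistic)
  })
  p_perm <- mean(perm >= H_obs - 1e-12)
  # band: Monte-Carlo error plus the chi-square approximation error at n = 30
  expect_lt(abs(p_obs - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 2e4) + 0.02)
})

test_that("ANOVA with Tukey: identical groups give F ~ 0 and the oracle F is reproduced", {
  d0 <- data.frame(value = rep(c(1, 2, 3, 4), 2),
                   g = rep(c("a", "b"), each = 4))
  r0 <- anova_tukey(d0, "value", "g")
  expect_equal(unname(r0$statistic["F"]), 0, tolerance = 1e-12)
  expect_gt(r0$p_value, 0.99)
  # independent normal-equations oracle for one-way F
  set.seed(16)
  d <- data.frame(value = c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 3)),
                  g = rep(c("a", "b", "c"), each = 6))
  r <- anova_tukey(d, "value", "g")
  gm <- mean(d$value)
  mns <- tapply(d$value, d$g, mean)
  ssb <- sum(6 * (mns - gm)^2)
  ssw <- sum((d$value - mns[d$g])^2)
  F_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(unname(r$statistic["F"]), F_oracle, tolerance = 1e-10)
  expect_equal(r$p_value, pf(F_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(all(r$comparisons$p_adj >= 0 & r$comparisons$p_adj <= 1))
})

test_that("two-way ANOVA reports both effects and the interaction with Tukey comparisons", {
  set.seed(17)
  d <- expand.grid(geno = c("wt", "ko"), age = c("P8", "P12"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$value <- with(d, ifelse(geno == "ko" & age == "P12", 2, 0)) + rnorm(nrow(d), 0, 0.5)
  r <- anova_tukey(d, "value", c("geno", "age"))
  eff <- r$details$effects
  expect_setequal(eff$effect, c("geno", "age", "geno:age"))
  expect_lt(eff$p[eff$effect == "geno:age"], 0.01)
  # balanced design: type-II equals the classical aov table
  cl <- summary(aov(value ~ geno * age, data = d))[[1]]
  expect_equal(eff$F, cl[1:3, "F value"], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(anova_tukey(data.frame(value = 1:4, g = "a"), "value", "g"),
               "two levels")
})

test_that("two-stage step-up discoveries match a literal implementation", {
  cases <- list(c(0.001, 0.2, 0.3, 0.9),
                c(1e-8, 1e-8, 1e-8, 1e-8),
                c(0.9, 0.95, 0.99),
                c(0.01, 0.012, 0.3, 0.02, 0.8),
                c(0.051, 0.049))
  for (p in cases)
    expect_equal(bky_step_up(p)$discovery, bky_literal(p))
  set.seed(18)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1))^sample(1:3, 1)
    expect_equal(bky_step_up(p)$discovery, bky_literal(p))
  }
  # all-tiny vector: every condition discovered
  expect_true(all(bky_step_up(rep(1e-8, 4))$discovery))
  # q-values are monotone in raw p
  p <- runif(12)
  qv <- bky_step_up(p)$q_value
  expect_true(all(diff(qv[order(p)]) >= -1e-12))
})

test_that("multiple_t_bky runs Welch tests per condition and handles tiny arms", {
  set.seed(19)
  d <- rbind(
    data.frame(age = "P8", group = rep(c("het", "ko"), each = 10),
               value = rnorm(20, 0.75, 0.05)),
    data.frame(age = "P12", group = rep(c("het", "ko"), each = 10),
               value = c(rnorm(10, 0.75, 0.05), rnorm(10, 0.50, 0.08))),
    data.frame(age = "P14", group = c("het", "het", "ko"),
               value = c(0.7, 0.72, 0.5)))
  out <- multiple_t_bky(d)
  expect_equal(out$condition, c("P8", "P12", "P14"))
  expect_true(is.na(out$p[3]) && !out$discovery[3])
  expect_match(out$note[3], "n < 2")
  # Welch p equals t.test's
  het <- d$value[d$age == "P12" & d$group == "het"]
  ko <- d$value[d$age == "P12" & d$group == "ko"]
  expect_equal(out$p[2], t.test(het, ko)$p.value)
  expect_true(out$discovery[2])
  expect_false(out$discovery[1])
})

test_that("normality pre-tests are calibrated and flag degenerate input", {
  nc <- normality_check(c(rep(1, 5), rnorm(20)), rep(c("const", "ok"), c(5, 20)))
  expect_false(nc$pass[nc$group == "const"])
  expect_match(nc$note[nc$group == "const"], "degenerate")
  tiny <- normality_check(c(1, 2), rep("tiny", 2))
  expect_true(is.na(tiny$pass))
  expect_match(tiny$note, "n < 3")
  # Shapiro-Wilk: ~5% false-fail rate on genuinely normal samples
  set.seed(20)
  res <- replicate(400, normality_check(rnorm(50), rep("g", 50))$shapiro_p > 0.05)
  expect_gt(mean(res), 0.92); expect_lt(mean(res), 0.98)
  # joint pass (two correlated tests) is a stricter call but stays near 1 - 2*alpha
  set.seed(21)
  joint <- replicate(300, normality_check(rnorm(50), rep("g", 50))$pass)
  expect_gt(mean(joint), 0.85)
  # strong non-normality is caught
  set.seed(22)
  expf <- replicate(200, isTRUE(normality_check(rexp(100), rep("g", 100))$pass))
  expect_lt(mean(expf), 0.1)
})

test_that("per-region counts use the half-open window convention", {
  expect_equal(count_cells_per_region(numeric(0)), 0)
  pos <- c(-100, 0, 99.999, 100)
  expect_equal(count_cells_per_region(pos, region_center = 0, region_span = 200), 3)
  # a synthetic row of 40 OHC at 5 um pitch spanning 200 um
  row_pos <- seq(0, by = 5, length.out = 40)
  expect_equal(unname(count_cells_per_region(row_pos, rep("OHC", 40),
                                             region_center = 97.5)["OHC"]), 40)
  mixed <- count_cells_per_region(c(row_pos, 10, 50), c(rep("OHC", 40), "IHC", "IHC"),
                                  region_center = 97.5)
  expect_equal(unname(mixed[c("IHC", "OHC")]), c(2, 40))
  expect_error(count_cells_per_region(1, region_span = 0), "region_span")
})

test_that("onset analysis finds the first discovered age; one age reduces to a Welch t-test", {
  co <- generate_cohort(cohort_spec(10,
    group_means = list(het = c(P8 = .75, P10 = .75, P12 = .75, P14 = .75),
                       ko = c(P8 = .75, P10 = .75, P12 = .50, P14 = .50)),
    group_sds = list(het = .05, ko = .08),
    ages = c("P8", "P10", "P12", "P14"), seed = 77))$table
  on <- onset_analysis(co, ages = c("P8", "P10", "P12", "P14"))
  expect_equal(on$onset_age, "P12")
  # single age: the BKY layer is the identity on one p value at stage 1 != 0
  one <- co[co$age == "P12", ]
  o1 <- onset_analysis(one, ages = "P12")
  expect_equal(o1$table$p,
               t.test(one$value[one$group == "het"],
                      one$value[one$group == "ko"])$p.value)
})

test_that("every adjustment procedure is monotone in raw p", {
  set.seed(23)
  vals <- rnorm(40); grp <- rep(letters[1:4], each = 10)
  kd <- kruskal_dunn(vals, grp)$comparisons
  o <- order(kd$p_raw)
  expect_true(all(diff(kd$p_adj[o]) >= -1e-12))
})
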