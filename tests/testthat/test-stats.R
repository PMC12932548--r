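mk_timeline <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(compound = "cpd", dose = r[1], timepoint = r[2],
               metric = "mfr", value = r[3])
  }))
}

test_that("baseline normalization matches the worked examples", {
  tl <- mk_timeline(c(10, 0, 5), c(10, 24, 5))
  expect_equal(normalize_to_baseline(tl)$relative, 1.0)
  tl2 <- mk_timeline(c(10, 0, 4), c(10, 72, 0))
  expect_equal(normalize_to_baseline(tl2)$relative, 0.0)
  tl3 <- mk_timeline(c(10, 0, 0), c(10, 24, 0), c(10, 72, 3))
  expect_warning(out <- normalize_to_baseline(tl3), "undefined")
  expect_equal(out$relative, 0)        # the 24 h silent row survives
  expect_equal(nrow(out), 1)
  expect_error(normalize_to_baseline(mk_timeline(c(10, 24, 5))),
               "baseline")
})

test_that("baseline normalization is invariant to rescaling a series", {
  set.seed(2)
  v <- runif(3, 1, 10)
  tl <- mk_timeline(c(5, 0, v[1]), c(5, 24, v[2]), c(5, 72, v[3]))
  tl_scaled <- tl; tl_scaled$value <- tl$value * 7.3
  expect_equal(normalize_to_baseline(tl)$relative,
               normalize_to_baseline(tl_scaled)$relative)
})

test_that("dunnett_test agrees with the multcomp reference", {
  skip_if_not_installed("multcomp")
  set.seed(14)
  for (rep in 1:3) {
    n <- c(4, 4, 5, 4)
    g <- factor(rep(c("0", "a", "b", "c"), times = n))
    y <- rnorm(sum(n)) + (g == "c") * 1.2
    mine <- dunnett_test(y, g, control = "0")
    fit <- stats::aov(y ~ g)
    ref <- summary(multcomp::glht(fit,
                                  linfct = multcomp::mcp(g = "Dunnett")))
    expect_equal(mine$p_adj, as.numeric(ref$test$pvalues),
                 tolerance = 2e-3)
    expect_equal(mine$estimate, as.numeric(ref$test$coefficients),
                 tolerance = 1e-10)
  }
})

test_that("adjusted p-values dominate the unadjusted pairwise contrast", {
  set.seed(3)
  for (rep in 1:20) {
    g <- factor(rep(0:3, each = 4))
    y <- rnorm(16)
    d <- dunnett_test(y, g)
    for (k in seq_len(nrow(d))) {
      raw <- 2 * stats::pt(-abs(d$t[k]), df = d$df[k])
      expect_gte(d$p_adj[k] + 1e-9, raw)
    }
  }
})

test_that("the testing chain reports all components and flags a strong
           effect", {
  set.seed(6)
  tab <- data.frame(dose = rep(c(0, 10, 25, 50), each = 4),
                    value = rnorm(16))
  tab$value[tab$dose == 50] <- tab$value[tab$dose == 50] + 5
  res <- test_dose_groups(tab)
  r <- res[[1]]
  expect_equal(r$status, "ok")
  expect_length(r$normality_p, 4)
  expect_true(r$homogeneity_p >= 0 && r$homogeneity_p <= 1)
  expect_lt(r$anova_p, 0.01)
  expect_true(r$dunnett$sig_01[r$dunnett$group == "50"])
  expect_false(any(r$dunnett$sig_05[r$dunnett$group %in% c("10", "25")]))
})

test_that("degenerate all-constant endpoints are reported, not tested", {
  tab <- data.frame(dose = rep(c(0, 10), each = 3), value = 1)
  res <- test_dose_groups(tab)
  expect_equal(res[[1]]$status, "degenerate")
  expect_true(is.na(res[[1]]$anova_p))
})

test_that("effect classification follows the margin and builds
           trajectories", {
  rel <- data.frame(compound = "cpd", dose = 10, timepoint = c(24, 72),
                    metric = "mfr", relative = c(0.4, 1.6))
  out <- classify_effects(rel)
  expect_equal(out$calls$direction, c("inhibitory", "excitatory"))
  expect_equal(out$trajectories$trajectory, "inhibition->excitation")
  rel2 <- data.frame(compound = "cpd", dose = 10, timepoint = c(24, 72),
                     metric = "mfr", relative = c(1.0, 1.0))
  expect_equal(classify_effects(rel2)$trajectories$trajectory, "none")
  rel3 <- data.frame(compound = "cpd", dose = 10, timepoint = c(24, 72),
                     metric = "mfr", relative = c(0.5, 0.1))
  expect_equal(classify_effects(rel3)$trajectories$trajectory,
               "inhibition")
})

test_that("delta-delta-Ct matches its definition and a spreadsheet-style
           oracle", {
  ct <- data.frame(condition = rep(c("cal", "d7"), each = 2),
                   gene = rep(c("actb", "nes"), 2),
                   ct = c(18, 24, 18, 23))
  out <- delta_delta_ct(ct, "actb", "cal")
  expect_equal(out$minus_ddct[out$condition == "cal"], 0)
  expect_equal(out$minus_ddct[out$condition == "d7"], 1)
  expect_equal(out$fold_change[out$condition == "d7"], 2)
  ## random table vs an independent loop-based recomputation
  set.seed(9)
  conds <- paste0("c", 1:4); genes <- c("ref", "g1", "g2", "g3")
  tab <- expand.grid(condition = conds, gene = genes,
                     stringsAsFactors = FALSE)
  tab <- tab[rep(seq_len(nrow(tab)), each = 3), ]       # 3 replicates
  tab$ct <- runif(nrow(tab), 15, 30)
  got <- delta_delta_ct(tab, "ref", "c1")
  for (i in seq_len(nrow(got))) {
    mct <- function(co, ge) mean(tab$ct[tab$condition == co &
                                          tab$gene == ge])
    dct <- mct(got$condition[i], got$gene[i]) - mct(got$condition[i], "ref")
    dct_cal <- mct("c1", got$gene[i]) - mct("c1", "ref")
    expect_equal(got$minus_ddct[i], -(dct - dct_cal), tolerance = 1e-9)
  }
  expect_error(delta_delta_ct(ct, "gapdh", "cal"), "reference")
  expect_error(delta_delta_ct(ct, "actb", "nope"), "calibrator")
})
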