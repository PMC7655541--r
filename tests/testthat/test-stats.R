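# Independent sums-of-squares oracle: explicit group-mean arithmetic,
# no shared code with the implementation.
ss_oracle <- function(tab, trait, log_transform = FALSE) {
  y <- tab[[trait]]
  if (log_transform) y <- log(y)
  blocks <- unique(tab$block); trts <- unique(tab$treatment)
  b <- length(blocks); t <- length(trts)
  s <- nrow(tab) / (b * t)
  gm <- mean(y)
  ss_b <- 0
  for (bl in blocks) ss_b <- ss_b + t * s * (mean(y[tab$block == bl]) - gm)^2
  ss_t <- 0
  for (tr in trts) ss_t <- ss_t + b * s * (mean(y[tab$treatment == tr]) - gm)^2
  ss_e <- 0
  ss_s <- 0
  for (bl in blocks) for (tr in trts) {
    sel <- tab$block == bl & tab$treatment == tr
    pm <- mean(y[sel])
    ss_e <- ss_e + s * (pm - mean(y[tab$block == bl]) -
                          mean(y[tab$treatment == tr]) + gm)^2
    ss_s <- ss_s + sum((y[sel] - pm)^2)
  }
  c(blocks = ss_b, treatments = ss_t, experimental = ss_e, sampling = ss_s)
}

test_that("ANOVA strata match the brute-force oracle to 1e-8 relative", {
  ph <- generate_phenotypes(design_spec(seed = 41L), trait = "count")
  fit <- fit_rcbd_subsampling(ph, "count", log_transform = TRUE)
  oracle <- ss_oracle(ph, "count", log_transform = TRUE)
  expect_equal(fit$table$sumsq, unname(oracle), tolerance = 1e-8)
  expect_equal(fit$table$df, c(2, 2, 4, 261))
  expect_equal(sum(fit$table$df), 270 - 1)
  y <- log(ph$count)
  expect_equal(sum(fit$table$sumsq), sum((y - mean(y))^2),
               tolerance = 1e-8)
  # treatment F uses the experimental-error stratum, never sampling error
  expect_equal(fit$table$statistic[2],
               fit$table$meansq[2] / fit$table$meansq[3])
})

test_that("ANOVA agrees with aov()'s error stratum decomposition", {
  ph <- generate_phenotypes(design_spec(seed = 43L))
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  df <- transform(as.data.frame(ph), logy = log(trait))
  a <- summary(stats::aov(logy ~ block + treatment + Error(plot), data = df))
  plot_stratum <- a[["Error: plot"]][[1L]]
  within <- a[["Error: Within"]][[1L]]
  expect_equal(fit$table$sumsq[1], plot_stratum["block", "Sum Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$table$sumsq[2], plot_stratum["treatment", "Sum Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$table$sumsq[3], plot_stratum["Residuals", "Sum Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$table$sumsq[4], within["Residuals", "Sum Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("validation: balance, log domain, design minima", {
  ph <- generate_phenotypes(design_spec(seed = 2L))
  expect_error(fit_rcbd_subsampling(ph[-1, ], "trait"), "unbalanced")
  ph2 <- ph
  ph2$trait[5] <- -1
  expect_error(fit_rcbd_subsampling(ph2, "trait", log_transform = TRUE),
               "row\\(s\\) 5")
  expect_error(fit_rcbd_subsampling(ph[, -1], "trait"), "missing column")
})

test_that("zero subsample noise sends the sampling mean square to zero", {
  spec <- design_spec(subsample_sd = 0, n_subsamples = 4L, seed = 3L)
  ph <- generate_phenotypes(spec)
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  expect_equal(fit$table$meansq[4], 0, tolerance = 1e-20)
  # the other strata match the analysis of the subsample means
  ph_first <- ph[ph$subsample == 1L, ]
  ph_rep <- do.call(rbind, replicate(4, ph_first, simplify = FALSE))
  ph_rep$subsample <- rep(1:4, each = nrow(ph_first))
  fit2 <- fit_rcbd_subsampling(ph_rep, "trait", log_transform = TRUE)
  expect_equal(fit$table$sumsq[1:3], fit2$table$sumsq[1:3],
               tolerance = 1e-10)
})

test_that("log-transform equivariance: trait rescaling leaves F unchanged", {
  ph <- generate_phenotypes(design_spec(seed = 47L))
  f1 <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  ph$trait <- ph$trait * 37.5
  f2 <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  expect_equal(f1$table$statistic[1:2], f2$table$statistic[1:2],
               tolerance = 1e-10)
  expect_equal(f1$table$sumsq[2:4], f2$table$sumsq[2:4], tolerance = 1e-8)
})

test_that("Tukey comparisons use the experimental-error stratum", {
  ph <- generate_phenotypes(design_spec(seed = 53L))
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  pm <- tukey_pairwise(fit)
  expect_equal(pm, t(pm))
  expect_equal(unname(diag(pm)), rep(1, 3))
  # oracle: TukeyHSD on the plot means (equivalent error stratum)
  d <- fit$data
  plot_means <- aggregate(y ~ block + treatment, data = d, FUN = mean)
  hsd <- stats::TukeyHSD(stats::aov(y ~ block + treatment,
                                    data = plot_means))$treatment
  comps <- attr(pm, "comparisons")
  for (k in seq_len(nrow(hsd))) {
    pair <- strsplit(rownames(hsd)[k], "-")[[1L]]
    mine <- comps$p.value[comps$contrast == paste(pair[1], "-", pair[2])]
    if (length(mine) == 0L) {
      mine <- comps$p.value[comps$contrast == paste(pair[2], "-", pair[1])]
    }
    expect_equal(mine, unname(hsd[k, "p adj"]), tolerance = 1e-6)
  }
})

test_that("Tukey p-values respond to true mean differences", {
  # exactly equal treatment means (plot-level shifts cancel across blocks):
  # the observed difference is zero, so q = 0 and p = 1
  ph <- generate_phenotypes(design_spec(n_treatments = 2L,
                                        treatment_effects = c(0, 0),
                                        seed = 59L))
  sel1 <- ph$treatment == "T1"
  ph$trait[!sel1] <- ph$trait[sel1]
  shift <- c(B1 = 0.3, B2 = -0.3, B3 = 0)
  ph$trait[!sel1] <- ph$trait[!sel1] *
    exp(shift[as.character(ph$block[!sel1])])
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  pm <- tukey_pairwise(fit)
  expect_gt(pm[1, 2], 0.9)

  # one treatment shifted far beyond the experimental error
  spec <- design_spec(treatment_effects = c(0, 0, 3), block_sd = 0.1,
                      plot_sd = 0.05, subsample_sd = 0.3, seed = 61L)
  fit2 <- fit_rcbd_subsampling(generate_phenotypes(spec), "trait",
                               log_transform = TRUE)
  pm2 <- tukey_pairwise(fit2)
  expect_lt(pm2["T3", "T1"], 0.01)
  expect_lt(pm2["T3", "T2"], 0.01)
  expect_gt(pm2["T1", "T2"], 0.05)
})

test_that("per-treatment correlations: exact, hand-computed and null cases", {
  ph <- generate_phenotypes(design_spec(seed = 67L), trait = "a")
  ph$b <- 2 * ph$a
  cors <- treatment_correlations(ph, c("a", "b"))
  expect_equal(nrow(cors), 3L)
  expect_equal(cors$r, rep(1, 3), tolerance = 1e-12)

  # hand table: r = 0.8
  hand <- data.frame(treatment = "T1",
                     x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  expect_equal(treatment_correlations(hand, c("x", "y"))$r, 0.8,
               tolerance = 1e-12)

  # constant trait: missing r
  ph$c <- 1
  cc <- treatment_correlations(ph, c("a", "c"))
  expect_true(all(is.na(cc$r)))
  expect_equal(cc$stars, rep("", 3L))
})

test_that("independent traits rarely show |r| >= 0.5 at n = 30", {
  set.seed(71)
  hits <- replicate(1000, {
    abs(cor(rnorm(30), rnorm(30))) < 0.5
  })
  expect_gte(mean(hits), 0.95)
  # and the significance stars follow the 0.05/0.01/0.001 convention
  ph <- data.frame(treatment = rep("T1", 30), x = rnorm(30))
  ph$y <- ph$x + rnorm(30, 0, 0.2)
  out <- treatment_correlations(ph, c("x", "y"))
  expect_equal(out$stars, "***")
})

test_that("diagnostics expose residual structure and normality", {
  ph <- generate_phenotypes(design_spec(seed = 73L))
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  di <- rcbd_diagnostics(fit)
  # subsample residuals sum to zero within every plot
  sub <- di$fitted_resid[di$fitted_resid$level == "subsample", ]
  sums <- tapply(sub$residual, fit$data$plot_mean, sum)
  expect_true(all(abs(sums) < 1e-10))
  expect_equal(nrow(di$qq), 9L)
  expect_true(is.finite(di$shapiro_p))
  p <- ggplot2::autoplot(di)
  expect_s3_class(p, "ggplot")
})

test_that("normality p-values are uniform under a normal model", {
  set.seed(1)
  ps <- replicate(500, {
    spec <- design_spec(n_blocks = 6L, n_treatments = 6L,
                        n_subsamples = 5L, treatment_effects = rep(0, 6),
                        seed = sample.int(1e6, 1))
    fit <- fit_rcbd_subsampling(generate_phenotypes(spec), "trait",
                                log_transform = TRUE)
    rcbd_diagnostics(fit)$shapiro_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("log transform repairs heavy-tailed traits", {
  set.seed(2)
  raw_p <- log_p <- numeric(40)
  for (i in 1:40) {
    spec <- design_spec(treatment_effects = rep(0, 3), subsample_sd = 1,
                        seed = 10000L + i)
    ph <- generate_phenotypes(spec)  # lognormal on the natural scale
    raw_p[i] <- rcbd_diagnostics(
      fit_rcbd_subsampling(ph, "trait", log_transform = FALSE))$shapiro_p
    log_p[i] <- rcbd_diagnostics(
      fit_rcbd_subsampling(ph, "trait", log_transform = TRUE))$shapiro_p
  }
  expect_lt(median(raw_p), median(log_p))
})

test_that("tidy and glance provide the broom-style views", {
  fit <- fit_rcbd_subsampling(generate_phenotypes(design_spec(seed = 79L)),
                              "trait", log_transform = TRUE)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$source,
               c("blocks", "treatments", "experimental_error",
                 "sampling_error"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$statistic, td$statistic[2])
})

test_that("simulated block dominance reproduces the field ANOVA structure", {
  # default generator: block variance exceeds treatment variance
  ph <- generate_phenotypes(design_spec(seed = 83L))
  fit <- fit_rcbd_subsampling(ph, "trait", log_transform = TRUE)
  ms <- fit$table$meansq
  expect_gt(ms[1], ms[2])          # blocks > treatments
  expect_gt(ms[2], ms[3])          # treatments > experimental error
  expect_gt(ms[3], ms[4] * 0.5)    # experimental error >= sampling error scale
})
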