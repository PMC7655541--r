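check_phenotype_table <- function(table, trait) {
  need <- c("block", "treatment", "subsample", trait)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  table$block <- factor(table$block)
  table$treatment <- factor(table$treatment)
  counts <- table(table$block, table$treatment)
  if (any(counts == 0)) stop("empty block x treatment cells", call. = FALSE)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: unequal subsample counts per plot; ",
         "the classical sums-of-squares analysis requires balance",
         call. = FALSE)
  }
  table
}

#' Randomized-complete-block ANOVA with subsampling
#'
#' Classical nested analysis of variance for a balanced design in which each
#' block x treatment plot is measured on several subsampled plants:
#' `y_ijk = mu + beta_j + alpha_i + delta_ij + eps_ijk`. Sums of squares are
#' computed explicitly from the stratum means, and the treatment F statistic
#' uses the plot-level experimental error (`delta`) as its denominator --
#' never the subsample-level sampling error, which would overstate the
#' effective replication. Blocks are tested against the same stratum.
#'
#' @param table Data frame with columns `block`, `treatment`, `subsample`
#'   and the trait; one row per subsampled plant.
#' @param trait Name of the trait column to analyse.
#' @param log_transform Analyse `log(trait)`; all values must be positive.
#' @return An object of class `rcbd_anova`: the ANOVA table (via
#'   [generics::tidy()]), the design dimensions, treatment means on the
#'   analysis scale and the analysis-scale data.
#' @export
fit_rcbd_subsampling <- function(table, trait, log_transform = FALSE) {
  table <- check_phenotype_table(table, trait)
  y <- table[[trait]]
  if (log_transform) {
    bad <- which(y <= 0)
    if (length(bad)) {
      stop("log transform requested but trait has non-positive values in ",
           "row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "", call. = FALSE)
    }
    y <- log(y)
  }
  b <- nlevels(table$block)
  t <- nlevels(table$treatment)
  s <- nrow(table) / (b * t)
  if (b < 2L || t < 2L || s < 2L) {
    stop("need >= 2 blocks, >= 2 treatments and >= 2 subsamples",
         call. = FALSE)
  }
  gm <- mean(y)
  block_means <- tapply(y, table$block, mean)
  trt_means <- tapply(y, table$treatment, mean)
  plot_means <- tapply(y, list(table$block, table$treatment), mean)

  ss_block <- t * s * sum((block_means - gm)^2)
  ss_trt <- b * s * sum((trt_means - gm)^2)
  plot_dev <- sweep(sweep(plot_means, 1, block_means), 2, trt_means) + gm
  ss_exp <- s * sum(plot_dev^2)
  fitted_plot <- plot_means[cbind(as.integer(table$block),
                                  as.integer(table$treatment))]
  ss_samp <- sum((y - fitted_plot)^2)

  df <- c(b - 1, t - 1, (b - 1) * (t - 1), b * t * (s - 1))
  ss <- c(ss_block, ss_trt, ss_exp, ss_samp)
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3], NA, NA)
  p <- c(pf(f[1], df[1], df[3], lower.tail = FALSE),
         pf(f[2], df[2], df[3], lower.tail = FALSE), NA, NA)
  tab <- tibble::tibble(
    source = c("blocks", "treatments", "experimental_error",
               "sampling_error"),
    df = df, sumsq = ss, meansq = ms, statistic = f, p.value = p
  )
  structure(list(
    table = tab, trait = trait, log_transform = log_transform,
    n_blocks = b, n_treatments = t, n_subsamples = s,
    treatment_means = trt_means,
    data = tibble::tibble(block = table$block, treatment = table$treatment,
                          subsample = table$subsample, y = y,
                          plot_mean = fitted_plot)
  ), class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf("RCBD with subsampling: %s%s (%d blocks x %d treatments x %d subsamples)\n",
              if (x$log_transform) "log " else "", x$trait,
              x$n_blocks, x$n_treatments, x$n_subsamples))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy rcbd_anova
#' @export
tidy.rcbd_anova <- function(x, ...) x$table

#' @method glance rcbd_anova
#' @export
glance.rcbd_anova <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, log_transform = x$log_transform,
    statistic = x$table$statistic[2], p.value = x$table$p.value[2],
    df_treatment = x$table$df[2], df_error = x$table$df[3],
    ms_experimental = x$table$meansq[3], ms_sampling = x$table$meansq[4]
  )
}

#' Tukey pairwise comparisons of treatment means
#'
#' Studentized-range comparisons of the treatment means on the analysis
#' scale, with the experimental-error (plot-level) mean square and degrees
#' of freedom as the error term -- consistent with the stratum used for the
#' treatment F test.
#'
#' @param fit An [fit_rcbd_subsampling()] object.
#' @return Symmetric matrix of p-values with unit diagonal; the tibble of
#'   pairwise comparisons (difference, standard error, q, p) is attached as
#'   attribute `"comparisons"`.
#' @export
tukey_pairwise <- function(fit) {
  stopifnot(inherits(fit, "rcbd_anova"))
  t <- fit$n_treatments
  if (t < 2L) stop("need >= 2 treatments", call. = FALSE)
  ms_exp <- fit$table$meansq[3]
  df_exp <- fit$table$df[3]
  reps <- fit$n_blocks * fit$n_subsamples
  se_mean <- sqrt(ms_exp / reps)
  means <- fit$treatment_means
  lv <- names(means)
  pm <- matrix(1, t, t, dimnames = list(lv, lv))
  comps <- list()
  for (i in seq_len(t - 1)) {
    for (j in (i + 1):t) {
      diff <- means[j] - means[i]
      q <- abs(diff) / se_mean
      p <- ptukey(q, nmeans = t, df = df_exp, lower.tail = FALSE)
      pm[i, j] <- pm[j, i] <- p
      comps[[length(comps) + 1L]] <- tibble::tibble(
        contrast = paste(lv[j], "-", lv[i]), estimate = unname(diff),
        se = se_mean, q = unname(q), p.value = unname(p)
      )
    }
  }
  attr(pm, "comparisons") <- dplyr::bind_rows(comps)
  pm
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Per-treatment Pearson correlations between traits
#'
#' For each treatment group, the Pearson correlation of every trait pair is
#' computed over the subsample-level observations, with significance stars
#' at 0.05 / 0.01 / 0.001. A trait that is constant within a group yields a
#' missing correlation.
#'
#' @param table Phenotype data frame (`block`, `treatment`, `subsample`,
#'   traits).
#' @param traits Character vector (>= 2) of trait column names.
#' @return Tibble `treatment`, `trait1`, `trait2`, `n`, `r`, `p.value`,
#'   `stars`.
#' @export
treatment_correlations <- function(table, traits) {
  stopifnot(length(traits) >= 2L)
  miss <- setdiff(c("treatment", traits), names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  groups <- split(table, factor(table$treatment))
  rows <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    if (nrow(df) < 3L) {
      stop("need >= 3 observations per treatment group", call. = FALSE)
    }
    for (i in seq_len(length(traits) - 1L)) {
      for (j in (i + 1L):length(traits)) {
        x <- df[[traits[i]]]; y <- df[[traits[j]]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- cor.test(x, y, method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          treatment = g, trait1 = traits[i], trait2 = traits[j],
          n = nrow(df), r = r, p.value = p, stars = p_stars(p)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Residual diagnostics for a fitted RCBD model
#'
#' Returns the data behind the two standard checks: a normal
#' quantile-quantile layout of the plot-level (experimental-error)
#' residuals, fitted-versus-residual pairs at both the plot and the
#' subsample level, and a Shapiro-Wilk normality p-value computed on the
#' plot-level residuals.
#'
#' @param fit An [fit_rcbd_subsampling()] object.
#' @return An object of class `rcbd_diagnostics`: list with `qq` (tibble
#'   `theoretical`, `sample`), `fitted_resid` (tibble `level`, `fitted`,
#'   `residual`), `shapiro_p`.
#' @export
rcbd_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rcbd_anova"))
  d <- fit$data
  gm <- mean(d$y)
  block_means <- tapply(d$y, d$block, mean)
  trt_means <- tapply(d$y, d$treatment, mean)
  plot_means <- tapply(d$y, list(d$block, d$treatment), mean)
  plot_resid <- sweep(sweep(plot_means, 1, block_means), 2, trt_means) + gm
  plot_fitted <- plot_means - plot_resid
  pr <- as.vector(plot_resid)
  qq <- tibble::tibble(
    theoretical = qnorm(ppoints(length(pr))),
    sample = sort(pr)
  )
  fr <- dplyr::bind_rows(
    tibble::tibble(level = "plot", fitted = as.vector(plot_fitted),
                   residual = pr),
    tibble::tibble(level = "subsample", fitted = d$plot_mean,
                   residual = d$y - d$plot_mean)
  )
  sw <- if (length(pr) >= 3L && stats::sd(pr) > 0) {
    shapiro.test(pr)$p.value
  } else {
    NA_real_
  }
  structure(list(qq = qq, fitted_resid = fr, shapiro_p = sw,
                 trait = fit$trait),
            class = "rcbd_diagnostics")
}

#' @export
print.rcbd_diagnostics <- function(x, ...) {
  cat(sprintf("<rcbd_diagnostics> %s: Shapiro p = %.4g on %d plot residuals\n",
              x$trait, x$shapiro_p, nrow(x$qq)))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot rcbd_diagnostics
#' @export
autoplot.rcbd_diagnostics <- function(object, ...) {
  qq <- dplyr::mutate(object$qq, panel = "Normal Q-Q (plot residuals)")
  fr <- dplyr::mutate(
    dplyr::filter(object$fitted_resid, .data$level == "plot"),
    panel = "Fitted vs residuals (plot level)"
  )
  dat <- dplyr::bind_rows(
    dplyr::transmute(qq, x = .data$theoretical, y = .data$sample,
                     panel = .data$panel),
    dplyr::transmute(fr, x = .data$fitted, y = .data$residual,
                     panel = .data$panel)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Diagnostics: %s", object$trait)) +
    ggplot2::theme_minimal()
}

#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, ...) {
  sm <- summarize_learning_curve(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$size, y = .data$mean_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_f1 - .data$sd_f1,
      ymax = .data$mean_f1 + .data$sd_f1
    )) +
    ggplot2::labs(x = "training scenes", y = "held-out pixel F1") +
    ggplot2::theme_minimal()
}
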