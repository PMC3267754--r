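# Genotype-to-phenotype association for inbred strain panels.
#
# The model is a fixed-effects least-squares fit of
#
#   y_ijkl = mu + G_i + L_j(i) + S_k + e_ijkl
#
# where G_i is the genotype of the miRNA seed variant (two levels, e.g. CC
# vs TT), L_j(i) the effect of strain nested within genotype (strains are
# inbred, so genotype is constant within strain), S_k the sex effect, and
# e_ijkl random error. The reported genotype effect is the difference of the
# two genotype least-squares means, which is coding-invariant; here the
# design matrix uses sum-to-zero coding for strain-within-genotype and sex,
# so the genotype coefficient *is* that difference.

.assoc_empty <- function(note) {
  structure(list(
    genotype_levels = character(), effect = NA_real_, se = NA_real_,
    statistic = NA_real_, df = c(NA_real_, NA_real_), p_value = NA_real_,
    n_used = 0L, lsmeans = tibble(genotype = character(), lsmean = numeric()),
    dropped_terms = character(), error_type = NA_character_,
    sigma = NA_real_, r_squared = NA_real_,
    estimable = FALSE, note = note, fit = NULL
  ), class = "seedvar_assoc")
}

# Sum-to-zero columns for strains nested within genotype: for a genotype
# with strains s_1..s_m (m >= 2), m-1 columns with +1 for s_j, -1 for s_m.
# Their within-genotype effects average to zero, so genotype LS-means do not
# depend on them.
.strain_columns <- function(genotype, strain) {
  cols <- list()
  for (g in sort(unique(genotype))) {
    ss <- sort(unique(strain[genotype == g]))
    if (length(ss) < 2L) next
    last <- ss[length(ss)]
    for (s in ss[-length(ss)]) {
      v <- numeric(length(strain))
      v[genotype == g & strain == s] <- 1
      v[genotype == g & strain == last] <- -1
      cols[[sprintf("strain_%s_%s", g, s)]] <- v
    }
  }
  cols
}

#' Fit the nested fixed-effects genotype model for one trait
#'
#' Ordinary least squares of `value ~ mean + genotype + strain-within-
#' genotype + sex` with sum-to-zero coding of the nested strain and sex
#' terms, so the genotype coefficient equals the difference of genotype
#' least-squares means (second sorted genotype level minus first). Traits
#' observed in a single sex drop the sex term with a note; a trait with only
#' one genotype level yields a non-estimable result rather than an error;
#' zero-variance traits return effect 0 and p = 1 by convention.
#'
#' @param records tibble with columns `strain, sex, genotype, value` (rows of
#'   one trait; extra columns are ignored).
#' @param error denominator of the genotype F-test: `"residual"` uses the
#'   residual mean square (the default of general linear model software);
#'   `"strain"` uses the strain-within-genotype mean square, the classical
#'   choice when strains are the experimental units. With fewer than two
#'   strains per genotype the strain denominator is unavailable and the fit
#'   falls back to `"residual"` with a note.
#' @return object of class `seedvar_assoc`; see [tidy.seedvar_assoc()] and
#'   [glance.seedvar_assoc()].
#' @export
fit_nested_model <- function(records, error = c("residual", "strain")) {
  error <- match.arg(error)
  d <- as_tibble(records)
  stopifnot(all(c("strain", "sex", "genotype", "value") %in% names(d)))
  d <- d[is.finite(d$value), , drop = FALSE]
  n <- nrow(d)
  if (n == 0) return(.assoc_empty("no observations"))
  glev <- sort(unique(d$genotype))
  if (length(glev) < 2L) {
    out <- .assoc_empty("only one genotype level observed; effect not estimable")
    out$genotype_levels <- glev
    out$n_used <- n
    return(out)
  }
  if (length(glev) > 2L) {
    abort("fit_nested_model() expects exactly two genotype levels")
  }
  dropped <- character()
  if (stats::var(d$value) == 0) {
    out <- .assoc_empty("zero-variance trait; p = 1 by convention")
    out$genotype_levels <- glev
    out$effect <- 0
    out$p_value <- 1
    out$n_used <- n
    out$estimable <- TRUE
    return(out)
  }

  # design matrix
  X <- list(`(Intercept)` = rep(1, n),
            genotype = as.numeric(d$genotype == glev[2L]))
  strain_cols <- .strain_columns(d$genotype, d$strain)
  if (length(strain_cols) == 0L) {
    dropped <- c(dropped, "strain (single strain per genotype)")
  }
  X <- c(X, strain_cols)
  sexes <- sort(unique(d$sex))
  if (length(sexes) >= 2L) {
    X$sex <- ifelse(d$sex == sexes[1L], 1, -1)
  } else {
    dropped <- c(dropped, "sex (single-sex trait)")
  }
  Xm <- do.call(cbind, X)
  fit <- lm(d$value ~ Xm - 1)
  cf <- coef(fit)
  names(cf) <- colnames(Xm)
  geno_i <- which(colnames(Xm) == "genotype")
  if (is.na(cf[geno_i])) {
    out <- .assoc_empty("genotype effect aliased in the design; not estimable")
    out$genotype_levels <- glev
    out$n_used <- n
    return(out)
  }
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased) > 0) dropped <- c(dropped, paste("aliased:", aliased))

  rss <- sum(stats::residuals(fit)^2)
  rank_full <- fit$rank
  df_res <- n - rank_full
  sm <- summary(fit)
  keep <- !is.na(cf)
  se_res <- sm$coefficients[match("Xmgenotype", rownames(sm$coefficients)), "Std. Error"]
  effect <- unname(cf[geno_i])

  error_used <- error
  note <- NA_character_
  if (error == "strain") {
    if (length(strain_cols) == 0L) {
      error_used <- "residual"
      note <- "fewer than 2 strains per genotype; strain-level error unavailable, residual error used"
    } else {
      red_cols <- setdiff(colnames(Xm), names(strain_cols))
      fit_red <- lm(d$value ~ Xm[, red_cols, drop = FALSE] - 1)
      ss_strain <- sum(stats::residuals(fit_red)^2) - rss
      df_strain <- rank_full - fit_red$rank
      if (df_strain <= 0 || df_res <= 0) {
        error_used <- "residual"
        note <- "strain mean square not estimable; residual error used"
      }
    }
  }
  if (error_used == "strain") {
    ms_strain <- ss_strain / df_strain
    ms_res <- rss / df_res
    se <- se_res * sqrt(ms_strain / ms_res)
    df2 <- df_strain
  } else {
    se <- se_res
    df2 <- df_res
  }
  f_stat <- (effect / se)^2
  p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)

  structure(list(
    genotype_levels = glev,
    effect = effect, se = unname(se), statistic = unname(f_stat),
    df = c(1, df2), p_value = unname(p), n_used = n,
    lsmeans = tibble(genotype = glev,
                     lsmean = c(unname(cf[1L]), unname(cf[1L]) + effect)),
    dropped_terms = dropped, error_type = error_used,
    sigma = sqrt(rss / max(df_res, 1L)),
    r_squared = 1 - rss / sum((d$value - mean(d$value))^2),
    estimable = TRUE, note = note, fit = fit
  ), class = "seedvar_assoc")
}

#' @export
print.seedvar_assoc <- function(x, ...) {
  cat("Nested fixed-effects genotype model\n")
  if (!x$estimable || is.na(x$effect)) {
    cat("  not estimable:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  genotype effect (%s - %s): %.4g (SE %.4g)\n",
              x$genotype_levels[2], x$genotype_levels[1], x$effect, x$se))
  cat(sprintf("  F(1, %g) = %.4g, p = %.3g  [%s error]\n",
              x$df[2], x$statistic, x$p_value, x$error_type))
  cat(sprintf("  n = %d", x$n_used))
  if (length(x$dropped_terms) > 0) {
    cat("; dropped:", paste(x$dropped_terms, collapse = "; "))
  }
  cat("\n")
  invisible(x)
}

#' Tidy the genotype contrast of a fitted nested model
#'
#' @param x a `seedvar_assoc` object from [fit_nested_model()].
#' @param ... unused.
#' @return one-row tibble with `term, estimate, std.error, statistic,
#'   p.value` for the genotype least-squares-mean difference.
#' @exportS3Method generics::tidy
#' @export
tidy.seedvar_assoc <- function(x, ...) {
  term <- if (length(x$genotype_levels) == 2L) {
    sprintf("genotype %s - %s", x$genotype_levels[2], x$genotype_levels[1])
  } else "genotype"
  tibble(term = term, estimate = x$effect, std.error = x$se,
         statistic = x$statistic, p.value = x$p_value)
}

#' One-row model summary of a fitted nested model
#'
#' @inheritParams tidy.seedvar_assoc
#' @return one-row tibble with `n_used, r.squared, sigma, df.residual,
#'   p.value, error_type, estimable, note`.
#' @export
glance.seedvar_assoc <- function(x, ...) {
  tibble(n_used = x$n_used, r.squared = x$r_squared, sigma = x$sigma,
         df.residual = x$df[2], p.value = x$p_value,
         error_type = x$error_type, estimable = x$estimable,
         note = if (length(x$dropped_terms) > 0)
           paste(x$dropped_terms, collapse = "; ") else x$note)
}

#' Scan all traits for genotype associations
#'
#' Fits the nested model per trait and flags significant associations at
#' unadjusted `p < alpha` (the conventional screen; such associations mark
#' potential groups of affected traits, not causal effects). An optional
#' Benjamini-Hochberg column is available for modern FDR control.
#'
#' @param records phenotype tibble ([read_phenotypes()]): columns `strain,
#'   sex, genotype, trait, group, value`.
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @param error passed to [fit_nested_model()].
#' @param bh also compute a Benjamini-Hochberg adjusted p-value column
#'   (`p_adjusted`); the `significant` flag stays on the raw p-value.
#' @return tibble with one row per trait: `trait, group, n_used, effect, se,
#'   p_value, significant, note` (plus `p_adjusted` when `bh = TRUE`).
#'   Traits with a single observed genotype are retained with `NA` effect
#'   and a note rather than silently dropped.
#' @export
scan_traits <- function(records, alpha = 0.01, error = c("residual", "strain"),
                        bh = FALSE) {
  error <- match.arg(error)
  d <- as_tibble(records)
  if (!"group" %in% names(d)) d$group <- NA_character_
  if (nrow(d) == 0) {
    out <- tibble(trait = character(), group = character(), n_used = integer(),
                  effect = numeric(), se = numeric(), p_value = numeric(),
                  significant = logical(), note = character())
    return(out)
  }
  out <- d %>%
    group_by(.data$trait) %>%
    dplyr::group_modify(function(rows, key) {
      f <- fit_nested_model(rows, error = error)
      tibble(
        group = rows$group[1], n_used = f$n_used,
        effect = f$effect, se = f$se, p_value = f$p_value,
        note = if (!f$estimable) f$note else f$note %||% NA_character_
      )
    }) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
  if (bh) {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  }
  out <- arrange(out, .data$trait)
  attr(out, "alpha") <- alpha
  class(out) <- c("seedvar_scan", class(out))
  out
}

#' Count significant associations per trait group
#'
#' @param scan result of [scan_traits()].
#' @return tibble with columns `group, n_traits, n_significant`, sorted by
#'   group.
#' @export
summarize_scan <- function(scan) {
  scan %>%
    group_by(.data$group) %>%
    summarise(n_traits = n(), n_significant = sum(.data$significant),
              .groups = "drop") %>%
    arrange(.data$group)
}

#' Per-genotype, per-sex cell summaries for one trait
#'
#' The tabular artifact behind a lean-vs-fat style genotype/phenotype figure:
#' observation count, mean and standard deviation per (genotype, sex) cell.
#' For a single-sex trait the sex dimension is collapsed.
#'
#' @param records phenotype tibble.
#' @param trait trait identifier to summarize; NULL uses all rows as one
#'   trait.
#' @return tibble with columns `genotype` (, `sex`) `, n, mean, sd`.
#' @export
genotype_group_summary <- function(records, trait = NULL) {
  d <- as_tibble(records)
  if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble(genotype = character(), sex = character(), n = integer(),
                  mean = numeric(), sd = numeric()))
  }
  keys <- if (n_distinct(d$sex) > 1L) c("genotype", "sex") else "genotype"
  d %>%
    group_by(across(all_of(keys))) %>%
    summarise(n = n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") %>%
    arrange(across(all_of(keys)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
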