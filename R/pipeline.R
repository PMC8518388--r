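# End-to-end workflow: score -> screen -> separation fix -> stepwise model ->
# interactions -> diagnostics -> report tables. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Blood-in-mouth by breed contingency table
#'
#' 2 x 2 counts of blood presence for Standardbreds vs Finnhorses (the two
#' modelled breeds), rows = breed, columns = blood yes/no.
#'
#' @param exams Exam table.
#' @return A 2 x 2 integer matrix with dimnames.
#' @export
blood_by_breed_table <- function(exams) {
  x <- exams[exams$breed %in% c("finnhorse", "standardbred"), ]
  tab <- rbind(
    finnhorse = c(sum(x$blood & x$breed == "finnhorse"),
                  sum(!x$blood & x$breed == "finnhorse")),
    standardbred = c(sum(x$blood & x$breed == "standardbred"),
                     sum(!x$blood & x$breed == "standardbred")))
  colnames(tab) <- c("blood", "no_blood")
  tab
}

#' Bar-lesion occurrence by bit jointedness (or by named bit type)
#'
#' Counts horses with at least one acute bar lesion against the rest. The
#' primary comparison collapses bits to unjointed vs jointed; the
#' heterogeneous "other" group has no assignable jointedness and is
#' excluded from that 2 x 2. `by = "bit_type"` instead returns the full
#' r x 2 table over named bit types.
#'
#' @param cohort A cohort list (`exams` + `lesions`).
#' @param by `"jointedness"` (default) or `"bit_type"`.
#' @return An integer matrix, rows = groups, columns = bar lesion yes/no.
#' @export
bar_lesion_table <- function(cohort, by = c("jointedness", "bit_type")) {
  by <- match.arg(by)
  ex <- bin_covariates(cohort$exams, other_jointed = NA)
  bar <- has_bar_lesion(cohort)
  if (by == "jointedness") {
    keep <- !is.na(ex$jointedness)
    g <- factor(ex$jointedness[keep], levels = c("unjointed", "jointed"))
    bar <- bar[keep]
  } else {
    g <- factor(ex$bit_type, levels = bit_types())
    g <- droplevels(g)
  }
  tab <- cbind(bar = tapply(bar, g, sum), no_bar = tapply(!bar, g, sum))
  storage.mode(tab) <- "integer"
  tab
}

#' Detect factor levels causing quasi-complete separation
#'
#' @param exams Scored exam table.
#' @param factors Factor columns to inspect.
#' @param outcome Outcome column.
#' @return A tibble `factor`, `level`, `n`, `outcome_value` (one row per
#'   constant-outcome level); zero rows when none.
#' @export
detect_separation <- function(exams, factors, outcome = "merged") {
  rows <- lapply(factors, function(f) {
    tab <- table(as.character(exams[[f]]), exams[[outcome]])
    if (ncol(tab) < 2) {
      lev <- rownames(tab)
    } else {
      lev <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
    }
    if (!length(lev)) return(NULL)
    tibble::tibble(factor = f, level = lev,
                   n = as.integer(rowSums(tab)[lev]),
                   outcome_value = vapply(lev, function(l) {
                     names(which.max(tab[l, ]))
                   }, character(1)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(factor = character(), level = character(),
                          n = integer(), outcome_value = character())
  }
  out
}

#' Summary table in the style of a risk-factor results table
#'
#' One row per factor level of the final model: group size, count and
#' percentage with the CD outcome, adjusted odds ratio with Wald interval
#' (reference levels marked), per-level Wald p, and the factor-level joint
#' Wald p.
#'
#' @param fit A [fit_logistic()] result.
#' @return A tibble.
#' @export
table1 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  dat <- fit$data
  y <- dat$.y
  rows <- lapply(fit$terms, function(f) {
    lev <- levels(dat[[f]])
    cf <- fit$coef[fit$coef$term == f, ]
    fp <- fit$factor_tests$p_value[fit$factor_tests$term == f]
    dplyr::bind_rows(lapply(seq_along(lev), function(i) {
      l <- lev[i]
      sel <- dat[[f]] == l
      n <- sum(sel); cd <- sum(y[sel])
      if (i == 1) {
        tibble::tibble(variable = f, level = as.character(l), n = n,
                       cd_count = cd, cd_pct = round(100 * cd / n),
                       or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                       p_level = NA_real_, p_factor = fp,
                       reference = TRUE)
      } else {
        r <- cf[cf$level == as.character(l), ]
        tibble::tibble(variable = f, level = as.character(l), n = n,
                       cd_count = cd, cd_pct = round(100 * cd / n),
                       or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
                       p_level = r$p_value, p_factor = fp,
                       reference = FALSE)
      }
    }))
  })
  dplyr::bind_rows(rows)
}

#' Descriptive summary of a cohort subset
#'
#' Severity-category distribution, lesion kinds, blood and equipment rates,
#' and the bit-type spectrum — the descriptive-only reporting applied to
#' groups excluded from modelling (ponies, in the study this package
#' emulates).
#'
#' @param cohort A scored cohort list.
#' @param breeds_keep Breeds to summarise (default: the pony breeds).
#' @return A list of small tibbles (`categories`, `bits`, `rates`).
#' @export
descriptive_summary <- function(cohort,
                                breeds_keep = c("pony_shetland", "pony_gotland")) {
  ex <- cohort$exams[cohort$exams$breed %in% breeds_keep, ]
  n <- nrow(ex)
  if (n == 0) {
    return(list(n = 0L, categories = tibble::tibble(),
                bits = tibble::tibble(), rates = tibble::tibble()))
  }
  les <- cohort$lesions[cohort$lesions$horse_id %in% ex$horse_id, ]
  categories <- dplyr::count(ex, .data$category, name = "n_horses")
  categories$pct <- round(100 * categories$n_horses / n)
  bits <- dplyr::count(ex, .data$bit_type, name = "n_horses", sort = TRUE)
  rates <- tibble::tibble(
    measure = c("wounds", "bruises", "blood", "tongue_tie", "overcheck"),
    n_horses = c(length(unique(les$horse_id[les$kind == "wound"])),
                 length(unique(les$horse_id[les$kind == "bruise"])),
                 sum(ex$blood), sum(ex$tongue_tie), sum(ex$overcheck)),
  )
  rates$pct <- round(100 * rates$n_horses / n)
  list(n = n, categories = categories, bits = bits, rates = rates)
}

#' Run the full risk-factor analysis pipeline
#'
#' Scores the cohort (if not already scored), bins covariates, runs the
#' univariable chi-square screen, repairs any quasi-complete separation by
#' reassigning one borderline record per constant level, builds the
#' multivariable model by manual stepwise elimination with breed forced,
#' screens the requested interactions, and computes covariate-pattern
#' diagnostics. Modelling uses Standardbreds and Finnhorses only; pony
#' breeds are summarised descriptively.
#'
#' @param cohort A cohort list (`exams` + `lesions`).
#' @param candidates Candidate factors for the model (default: bit type,
#'   sex, age group, plus the equipment and performance flags).
#' @param forced Factors never removed (default breed).
#' @param alpha Retention threshold.
#' @param interactions List of pairs for [interaction_scan()]; defaults to
#'   the conventional pairs among the final-model terms.
#' @param outcome Outcome column.
#' @return A list of class `pipeline_result` with `screen`,
#'   `separation_fixes`, `stepwise`, `fit`, `interactions`, `diagnostics`,
#'   `table1`, `pony_summary`, `accounting`.
#' @export
run_pipeline <- function(cohort,
                         candidates = c("bit_type", "sex", "age_group",
                                        "tongue_tie", "overcheck", "galloped",
                                        "top_three", "money_won",
                                        "raced_within_2wk", "start_type"),
                         forced = "breed", alpha = 0.05,
                         interactions = NULL, outcome = "merged") {
  exams <- cohort$exams
  if (!"merged" %in% names(exams) || !"total_points" %in% names(exams)) {
    exams <- score_cohort(exams, cohort$lesions)
  }
  exams <- bin_covariates(exams)
  n_all <- nrow(exams)
  modelled <- exams[exams$breed %in% c("standardbred", "finnhorse"), ]
  n_model <- nrow(modelled)

  screen <- univariable_screen(modelled, c(forced, candidates), outcome = outcome)

  sep <- detect_separation(modelled, c(forced, candidates), outcome = outcome)
  for (i in seq_len(nrow(sep))) {
    modelled <- apply_separation_fix(modelled, sep$factor[i], sep$level[i],
                                     outcome = outcome)
  }
  fixes <- attr(modelled, "separation_fix")

  sw <- stepwise_build(modelled, candidates, forced = forced, alpha = alpha,
                       outcome = outcome)
  fit <- sw$fit

  if (is.null(interactions)) {
    tm <- setdiff(sw$final_terms, NULL)
    interactions <- utils::combn(tm, 2, simplify = FALSE)
  }
  inter <- interaction_scan(fit, interactions)
  diag <- diagnostics(fit)
  structure(list(
    screen = screen,
    separation_fixes = fixes,
    stepwise = sw, fit = fit,
    interactions = inter, diagnostics = diag,
    table1 = table1(fit),
    pony_summary = descriptive_summary(cohort),
    accounting = tibble::tibble(
      stage = c("examined", "modelled (ponies excluded)", "separation fixes"),
      n = c(n_all, n_model, length(fixes)))
  ), class = "pipeline_result")
}

#' Render a plain-text report of a pipeline result
#'
#' @param result A [run_pipeline()] result.
#' @return Character vector of report lines, invisibly printed with `cat`
#'   when `print = TRUE`.
#' @param print Emit the report to the console.
#' @export
render_report <- function(result, print = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  f <- result$fit
  d <- result$diagnostics
  fmt_or <- function(r) {
    if (r$reference) "Reference" else {
      sprintf("%.1f (%.1f-%.1f) p=%.2g", r$or, r$ci_lo, r$ci_hi, r$p_level)
    }
  }
  lines <- c(
    "Risk-factor analysis report",
    "===========================",
    sprintf("Horses examined: %d; modelled: %d; separation fixes applied: %d",
            result$accounting$n[1], result$accounting$n[2],
            result$accounting$n[3]),
    "",
    sprintf("Final model: %s ~ %s", f$outcome, paste(f$terms, collapse = " + ")),
    sprintf("Model LR chi-square %.2f on %d df, p %s", f$lr_chisq, f$lr_df,
            format.pval(f$lr_p, eps = .001)),
    sprintf("Sensitivity %.0f%%, specificity %.0f%%, correctly classified %.0f%%",
            100 * d$sensitivity, 100 * d$specificity, 100 * d$percent_correct),
    sprintf("ROC AUC %.0f%% (CI %.0f%%-%.0f%%); GOF p %s", 100 * d$auc,
            100 * d$auc_ci[1], 100 * d$auc_ci[2],
            if (is.na(d$gof_p)) "NA" else format.pval(d$gof_p, digits = 2)),
    "",
    "Adjusted odds ratios (merged CD vs AB outcome):")
  t1 <- result$table1
  for (i in seq_len(nrow(t1))) {
    r <- t1[i, ]
    lines <- c(lines, sprintf("  %-16s %-24s n=%3d CD=%3d (%d%%)  %s",
                              r$variable, r$level, r$n, r$cd_count, r$cd_pct,
                              fmt_or(r)))
  }
  if (length(result$separation_fixes)) {
    lines <- c(lines, "", "Separation-fix audit:")
    for (a in result$separation_fixes) {
      lines <- c(lines, sprintf(
        "  %s = %s: horse %s (%d points) reassigned %s -> %s",
        a$factor, a$level, a$horse_id, a$total_points, a$from, a$to))
    }
  }
  ps <- result$pony_summary
  if (ps$n > 0) {
    lines <- c(lines, "", sprintf(
      "Pony descriptives (n=%d, excluded from modelling):", ps$n))
    lines <- c(lines, paste0("  category ", ps$categories$category, ": ",
                             ps$categories$n_horses, " (",
                             ps$categories$pct, "%)"))
    lines <- c(lines, sprintf("  %s: %d (%d%%)", ps$rates$measure,
                              ps$rates$n_horses, ps$rates$pct))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
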