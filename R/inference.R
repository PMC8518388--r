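# Contingency tests, logistic modelling, stepwise building and separation
# handling for the merged AB/CD lesion outcome.

.check_table <- function(counts, min_rows = 2) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  }
  if (nrow(counts) < min_rows || ncol(counts) < 2) {
    stop(sprintf("contingency table must be at least %dx2", min_rows), call. = FALSE)
  }
  counts
}

#' Pearson chi-square test on an r x 2 contingency table
#'
#' Uncorrected (no Yates continuity correction), as used for the
#' blood-by-breed comparison.
#'
#' @param counts An r x 2 matrix of counts.
#' @return A list with `statistic`, `df`, `p_value` and `expected`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- .check_table(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Fisher's exact test on an r x 2 contingency table
#'
#' Two-sided p-value under the fixed-margins hypergeometric null, summing
#' the probabilities of all tables no more probable than the observed one.
#' Tables beyond 2 x 2 with a grand total above `exact_limit` are evaluated
#' by Monte-Carlo permutation with a fixed seed.
#'
#' @param counts An r x 2 matrix of counts.
#' @param exact_limit Largest grand total of an r > 2 table still evaluated
#'   exactly (default 60).
#' @param b Number of Monte-Carlo permutations for large tables.
#' @param mc_seed Seed for the Monte-Carlo branch (the caller's RNG state is
#'   restored afterwards).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(counts, exact_limit = 60, b = 1e5, mc_seed = 1L) {
  counts <- .check_table(counts)
  if (any(rowSums(counts) == 0)) {
    stop("table has an all-zero row; drop empty levels first", call. = FALSE)
  }
  if (nrow(counts) == 2 && ncol(counts) == 2 || sum(counts) <= exact_limit) {
    return(stats::fisher.test(counts)$p.value)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(mc_seed)
  stats::fisher.test(counts, simulate.p.value = TRUE, B = as.integer(b))$p.value
}

#' Crude odds ratio with Woolf confidence interval for a 2 x 2 table
#'
#' OR = ad/bc with `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When a
#' cell is zero a 0.5 continuity correction is added to every cell (flagged
#' in the result).
#'
#' @param counts A 2 x 2 matrix `rbind(c(a, b), c(c, d))`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or`, `ci` (length 2), and `corrected`.
#' @export
odds_ratio_2x2 <- function(counts, conf_level = 0.95) {
  counts <- .check_table(counts)
  if (nrow(counts) != 2 || ncol(counts) != 2) stop("need a 2x2 table", call. = FALSE)
  corrected <- any(counts == 0)
  x <- counts + if (corrected) 0.5 else 0
  or <- unname((x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / x))
  list(or = or, ci = unname(exp(log(or) + c(-1, 1) * z * se)),
       corrected = corrected)
}

.ref_levels <- c(bit_type = "snaffle_trotting", sex = "gelding",
                 breed = "standardbred", age_group = "y3_5",
                 thickness_class = "thin", jointedness = "jointed",
                 start_type = "auto")

# Coerce a covariate column to a factor with its canonical reference level
# first; logicals become FALSE/TRUE factors.
.as_model_factor <- function(x, name) {
  if (is.logical(x)) return(factor(x, levels = c(FALSE, TRUE)))
  x <- as.character(x)
  ref <- .ref_levels[name]
  lev <- unique(x)
  if (!is.na(ref) && ref %in% lev) lev <- c(ref, setdiff(sort(lev), ref))
  else lev <- sort(lev)
  factor(x, levels = lev)
}

.outcome01 <- function(exams, outcome) {
  y <- exams[[outcome]]
  if (is.logical(y)) return(as.integer(y))
  if (all(y %in% c("AB", "CD"))) return(as.integer(y == "CD"))
  stop("outcome must be logical or AB/CD", call. = FALSE)
}

#' Univariable chi-square screening of candidate risk factors
#'
#' Cross-tabulates each factor against the binary outcome and applies the
#' uncorrected Pearson chi-square test, one factor at a time. Factors with
#' a single observed level are skipped with a warning.
#'
#' @param exams Scored exam table (needs the outcome column).
#' @param factors Character vector of column names to screen.
#' @param outcome Outcome column, `"merged"` (AB/CD) by default.
#' @return A tibble with one row per screened factor: `factor`, `n_levels`,
#'   `statistic`, `df`, `p_value`, and the count table in list-column
#'   `table`.
#' @export
univariable_screen <- function(exams, factors, outcome = "merged") {
  y <- .outcome01(exams, outcome)
  rows <- lapply(factors, function(f) {
    x <- .as_model_factor(exams[[f]], f)
    x <- droplevels(x)
    if (nlevels(x) < 2) {
      warning("factor '", f, "' has a single observed level; skipped",
              call. = FALSE)
      return(NULL)
    }
    tab <- table(x, factor(y, levels = 0:1, labels = c("AB", "CD")))
    ht <- pearson_chi_square(unclass(tab))
    tibble::tibble(factor = f, n_levels = nlevels(x),
                   statistic = ht$statistic, df = ht$df,
                   p_value = ht$p_value, table = list(tab))
  })
  dplyr::bind_rows(rows)
}

# Joint Wald test that all coefficients belonging to one factor are zero.
.joint_wald <- function(b, V) {
  W <- drop(t(b) %*% solve(V, b))
  list(statistic = W, df = length(b), p_value = stats::pchisq(W, length(b), lower.tail = FALSE))
}

#' Fit a multivariable logistic regression with Wald inference
#'
#' Maximum-likelihood fit (iteratively reweighted least squares) of the
#' binary outcome on the given categorical terms, expanded against the
#' field's reference levels (snaffle trotting bit, gelding, Standardbred).
#' Reports per-level Wald tests and odds ratios with 95% Wald intervals,
#' a joint Wald test per factor, and the likelihood-ratio chi-square
#' against the intercept-only model. Quasi-complete separation (a factor
#' level with constant outcome) and non-convergence raise distinct
#' conditions (`bitlesion_separation_error`, `bitlesion_convergence_error`).
#'
#' @param exams Scored exam table.
#' @param terms Character vector of covariate column names.
#' @param outcome Outcome column (`"merged"` by default).
#' @param conf_level Wald interval coverage.
#' @return An object of class `logistic_fit`.
#' @export
fit_logistic <- function(exams, terms, outcome = "merged", conf_level = 0.95) {
  y <- .outcome01(exams, outcome)
  if (length(unique(y)) < 2) {
    rlang::abort("outcome is constant; model is degenerate",
                 class = "bitlesion_separation_error")
  }
  dat <- tibble::as_tibble(stats::setNames(
    lapply(terms, function(f) droplevels(.as_model_factor(exams[[f]], f))), terms))
  dat$.y <- y
  for (f in terms) {
    tab <- table(dat[[f]], y)
    const <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
    if (length(const)) {
      rlang::abort(
        sprintf("quasi-complete separation: level(s) %s of '%s' have constant outcome; see apply_separation_fix()",
                paste(const, collapse = ", "), f),
        class = "bitlesion_separation_error", factor = f, levels = const)
    }
  }
  form <- stats::reformulate(terms, response = ".y")
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    rlang::abort("IRLS did not converge within 100 iterations",
                 class = "bitlesion_convergence_error")
  }
  if (anyNA(stats::coef(fit))) {
    rlang::abort("collinear terms: some coefficients are aliased",
                 class = "bitlesion_collinearity_error")
  }
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  asg <- attr(stats::model.matrix(fit), "assign")
  term_of <- c("(Intercept)", terms)[asg + 1]
  level_of <- sub("^\\((Intercept)\\)$", "", rownames(cf))
  for (f in terms) level_of <- sub(paste0("^", f), "", level_of)
  coef_tbl <- tibble::tibble(
    term = term_of, level = unname(level_of),
    estimate = unname(cf[, 1]), se = unname(cf[, 2]),
    or = exp(unname(cf[, 1])),
    ci_lo = exp(unname(cf[, 1] - z * cf[, 2])),
    ci_hi = exp(unname(cf[, 1] + z * cf[, 2])),
    p_value = unname(cf[, 4])
  )
  V <- stats::vcov(fit)
  factor_tests <- dplyr::bind_rows(lapply(terms, function(f) {
    idx <- which(term_of == f)
    jw <- .joint_wald(cf[idx, 1], V[idx, idx, drop = FALSE])
    tibble::tibble(term = f, df = jw$df, wald_chisq = jw$statistic,
                   p_value = jw$p_value)
  }))
  lr <- unname(fit$null.deviance - fit$deviance)
  lr_df <- unname(fit$df.null - fit$df.residual)
  structure(list(
    model = fit, data = dat, terms = terms, outcome = outcome,
    coef = coef_tbl, factor_tests = factor_tests,
    lr_chisq = lr, lr_df = lr_df,
    lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
    loglik = as.numeric(stats::logLik(fit)), n = nrow(dat)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %s ~ %s  (n = %d)\n", x$outcome,
              paste(x$terms, collapse = " + "), x$n))
  cat(sprintf("  model LR chi-square %.2f on %d df, p = %.3g\n",
              x$lr_chisq, x$lr_df, x$lr_p))
  print(as.data.frame(x$coef), digits = 3)
  invisible(x)
}

#' Resolve quasi-complete separation by reassigning one borderline record
#'
#' When every horse at one factor level shares the same outcome, the record
#' at that level with the lowest total lesion points (ties broken by lowest
#' `horse_id`) is moved to the other outcome group, mirroring the handling
#' of an all-CD bit-type group in the study this package models. The
#' reassignment is recorded in the `"separation_fix"` attribute.
#'
#' @param exams Scored exam table.
#' @param factor Column name of the offending factor.
#' @param level The level whose outcome is constant.
#' @param outcome Outcome column (`"merged"`).
#' @return `exams` with one record's outcome flipped and an audit attribute;
#'   unchanged (with a warning) if the level's outcome is not constant.
#' @export
apply_separation_fix <- function(exams, factor, level, outcome = "merged") {
  idx <- which(as.character(exams[[factor]]) == level)
  if (!length(idx)) stop("no records at level '", level, "'", call. = FALSE)
  y <- exams[[outcome]][idx]
  if (length(unique(y)) > 1) {
    warning("level '", level, "' already has mixed outcomes; nothing to fix",
            call. = FALSE)
    return(exams)
  }
  pts <- exams$total_points[idx]
  ord <- order(pts, exams$horse_id[idx])
  move <- idx[ord[1]]
  from <- exams[[outcome]][move]
  to <- if (from == "CD") "AB" else "CD"
  exams[[outcome]][move] <- to
  audit <- list(factor = factor, level = level,
                horse_id = exams$horse_id[move],
                total_points = exams$total_points[move],
                from = from, to = to)
  attr(exams, "separation_fix") <- c(attr(exams, "separation_fix"), list(audit))
  exams
}

#' Manual stepwise model building with confounding checks
#'
#' Backward elimination: starting from forced terms plus all candidates,
#' the candidate with the largest joint Wald p-value above `alpha` is
#' removed, one at a time; at each removal the retained coefficients are
#' compared with their previous values and a relative change beyond
#' `confound_threshold` is flagged as possible confounding. Dropped terms
#' are then offered forward re-entry (kept if their joint p is at most
#' `alpha`), and the cycle repeats until stable. Forced terms (breed, by
#' default) are never removed. Every step is recorded in the build log.
#'
#' @param exams Scored exam table.
#' @param candidates Candidate factor columns.
#' @param forced Factors kept regardless of significance.
#' @param alpha Retention threshold on the joint Wald p-value.
#' @param confound_threshold Relative coefficient change flagged as
#'   confounding (default 0.20).
#' @param outcome Outcome column.
#' @return A list of class `stepwise_result`: `fit` (the final
#'   [fit_logistic()] object), `log` (tibble of steps), `final_terms`,
#'   `removed`.
#' @export
stepwise_build <- function(exams, candidates, forced = "breed", alpha = 0.05,
                           confound_threshold = 0.20, outcome = "merged") {
  candidates <- setdiff(candidates, forced)
  current <- candidates
  removed <- character(0)
  log <- list()
  note <- function(action, term, p = NA_real_, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(
      step = length(log) + 1L, action = action, term = term,
      p_value = p, detail = detail)
  }
  note("notice", NA_character_,
       detail = "random-intercept check for trainer/driver not performed (out of scope)")
  fit <- fit_logistic(exams, c(forced, current), outcome = outcome)
  repeat {
    # backward passes
    repeat {
      ft <- fit$factor_tests
      cand <- ft[ft$term %in% current, ]
      if (nrow(cand) == 0 || max(cand$p_value) <= alpha) break
      worst <- cand$term[which.max(cand$p_value)]
      old_coef <- fit$coef
      current <- setdiff(current, worst)
      removed <- union(removed, worst)
      fit <- fit_logistic(exams, c(forced, current), outcome = outcome)
      shared <- dplyr::inner_join(
        old_coef[old_coef$term != "(Intercept)", c("term", "level", "estimate")],
        fit$coef[, c("term", "level", "estimate")],
        by = c("term", "level"), suffix = c("_old", "_new"))
      rel <- abs(shared$estimate_new - shared$estimate_old) /
        pmax(abs(shared$estimate_old), 1e-8)
      conf <- shared[rel > confound_threshold & abs(shared$estimate_old) > 0.05, ]
      detail <- if (nrow(conf)) {
        paste0("confounding flag: ", paste(
          sprintf("%s[%s] %.2f->%.2f", conf$term, conf$level,
                  conf$estimate_old, conf$estimate_new), collapse = "; "))
      } else ""
      note("remove", worst, max(cand$p_value), detail)
    }
    # forward re-entry
    readded <- FALSE
    for (term in removed) {
      trial <- fit_logistic(exams, c(forced, current, term), outcome = outcome)
      p <- trial$factor_tests$p_value[trial$factor_tests$term == term]
      if (p <= alpha) {
        current <- c(current, term)
        removed <- setdiff(removed, term)
        fit <- trial
        note("re-enter", term, p)
        readded <- TRUE
      }
    }
    if (!readded) break
  }
  for (f in forced) {
    p <- fit$factor_tests$p_value[fit$factor_tests$term == f]
    note("retain-forced", f, p,
         if (p > alpha) "retained despite p > alpha (forced)" else "")
  }
  structure(list(fit = fit, log = dplyr::bind_rows(log),
                 final_terms = c(forced, current), removed = removed,
                 forced = forced, alpha = alpha),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise build: final terms", paste(x$final_terms, collapse = " + "), "\n")
  print(as.data.frame(x$log))
  print(x$fit)
  invisible(x)
}

#' Screen pairwise interactions against a fitted model
#'
#' Adds each interaction singly to the model and reports the
#' likelihood-ratio test against the base fit. Interactions whose product
#' columns are inestimable (collinear or empty cells) are reported as `NA`
#' with the reason.
#'
#' @param fit A [fit_logistic()] result.
#' @param pairs List of character pairs, e.g. `list(c("sex", "age_group"))`;
#'   both main effects must be in the fitted model.
#' @return A tibble: `pair`, `lr_chisq`, `df`, `p_value`, `note`.
#' @export
interaction_scan <- function(fit, pairs) {
  stopifnot(inherits(fit, "logistic_fit"))
  base <- fit$model
  dat <- fit$data
  rows <- lapply(pairs, function(pr) {
    lbl <- paste(pr, collapse = " x ")
    if (!all(pr %in% fit$terms)) {
      return(tibble::tibble(pair = lbl, lr_chisq = NA_real_, df = NA_integer_,
                            p_value = NA_real_, note = "main effect not in model"))
    }
    form <- stats::update(stats::formula(base),
                          paste(". ~ . +", pr[1], ":", pr[2]))
    trial <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = dat,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    new_coef <- stats::coef(trial)
    int_idx <- grepl(":", names(new_coef))
    if (any(is.na(new_coef[int_idx])) || !any(int_idx)) {
      return(tibble::tibble(pair = lbl, lr_chisq = NA_real_, df = NA_integer_,
                            p_value = NA_real_,
                            note = "interaction inestimable (collinear or empty cells)"))
    }
    lr <- unname(base$deviance - trial$deviance)
    df <- unname(base$df.residual - trial$df.residual)
    tibble::tibble(pair = lbl, lr_chisq = lr, df = df,
                   p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                   note = "")
  })
  dplyr::bind_rows(rows)
}
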