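# Builders for small in-code fixtures and independent oracles.

lesion_rows <- function(kind, size_class, deep = FALSE, location = "bar",
                        horse_id = "H0001", acute = TRUE) {
  n <- max(length(kind), length(size_class), length(deep))
  tibble::tibble(horse_id = rep_len(horse_id, n),
                 location = rep_len(location, n),
                 kind = rep_len(kind, n),
                 size_class = rep_len(size_class, n),
                 deep = rep_len(deep, n),
                 acute = rep_len(acute, n))
}

make_exams <- function(n, breed = "standardbred", sex = "gelding",
                       age_years = 6L, bit_type = "snaffle_trotting",
                       bit_thickness_mm = 14L, merged = "AB",
                       total_points = 0L) {
  tibble::tibble(
    horse_id = sprintf("H%04d", seq_len(n)),
    breed = rep_len(breed, n), sex = rep_len(sex, n),
    age_years = rep_len(age_years, n),
    bit_type = rep_len(bit_type, n),
    bit_thickness_mm = rep_len(bit_thickness_mm, n),
    tongue_tie = FALSE, overcheck = FALSE, check_bit = FALSE,
    jaw_strap = FALSE, galloped = FALSE, top_three = FALSE,
    money_won = FALSE, raced_within_2wk = FALSE,
    distance_m = 2100L, start_type = "auto", blood = FALSE,
    total_points = rep_len(as.integer(total_points), n),
    max_single_lesion_points = rep_len(as.integer(total_points), n),
    category = NA_character_, merged = rep_len(merged, n))
}

# Exam table whose CD counts per level of a two-level predictor equal a 2x2
# table rbind(c(cd1, ab1), c(cd0, ab0)); rows are predictor levels.
exams_from_2x2 <- function(counts, factor_name = "bit_type",
                           levels = c("crescendo", "snaffle_trotting")) {
  n <- sum(counts)
  ex <- make_exams(n)
  lev <- rep(levels, rowSums(counts))
  out <- rep(c("CD", "AB", "CD", "AB"), c(counts[1, 1], counts[1, 2],
                                          counts[2, 1], counts[2, 2]))
  ex[[factor_name]] <- lev
  ex$merged <- out
  ex
}

# Independent chi-square statistic from the defining formula.
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Exhaustive two-sided Fisher p for a 2x2: sum of hypergeometric
# probabilities of all tables with the same margins that are no more
# probable than the observed table.
fisher_oracle_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(a, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# O(n^2) concordance AUC: fraction of (case, control) pairs where the case
# has the higher fitted probability, ties counted one half.
auc_oracle <- function(y, p) {
  cases <- p[y == 1]; ctrls <- p[y == 0]
  s <- 0
  for (pc in cases) s <- s + sum(pc > ctrls) + 0.5 * sum(pc == ctrls)
  s / (length(cases) * length(ctrls))
}
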