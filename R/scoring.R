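# Lesion point-scoring, severity categorisation and covariate binning.

#' Controlled vocabularies for examination records
#'
#' Factor levels used throughout the package. Reference levels for modelling
#' (snaffle trotting bit, gelding, Standardbred) come first in their vectors.
#'
#' @return A character vector of admissible values.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
lesion_locations <- function() {
  c("inner_commissure", "outer_commissure", "bar", "buccal", "tongue", "palate")
}

#' @rdname vocabularies
#' @export
lesion_kinds <- function() c("bruise", "wound")

#' @rdname vocabularies
#' @export
size_classes <- function() {
  c("lt_half_cm", "half_to_one_cm", "one_to_three_cm", "ge_three_cm")
}

#' @rdname vocabularies
#' @export
breeds <- function() c("standardbred", "finnhorse", "pony_shetland", "pony_gotland")

#' @rdname vocabularies
#' @export
sexes <- function() c("gelding", "mare", "stallion")

#' @rdname vocabularies
#' @export
bit_types <- function() {
  c("snaffle_trotting", "crescendo", "mullen_mouth_regulator",
    "straight_plastic", "nurmos", "dr_bristol", "other")
}

.bruise_points <- c(lt_half_cm = 1L, half_to_one_cm = 2L,
                    one_to_three_cm = 3L, ge_three_cm = 4L)
.wound_points <- c(lt_half_cm = 2L, half_to_one_cm = 4L,
                   one_to_three_cm = 6L, ge_three_cm = 8L)

.check_enum <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s (must be one of %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Map a raw lesion size in centimetres to its size class
#'
#' Bin boundaries: < 0.5 cm; 0.5-1 cm (inclusive of both ends); > 1 but
#' < 3 cm; >= 3 cm. Exactly 1.0 cm falls in the second bin, exactly 3.0 cm
#' in the fourth.
#'
#' @param cm Numeric vector of sizes in cm, non-negative.
#' @return Character vector of size classes.
#' @export
size_class_from_cm <- function(cm) {
  stopifnot(is.numeric(cm))
  if (any(is.na(cm)) || any(cm < 0)) stop("lesion size must be non-negative", call. = FALSE)
  dplyr::case_when(
    cm < 0.5 ~ "lt_half_cm",
    cm <= 1  ~ "half_to_one_cm",
    cm < 3   ~ "one_to_three_cm",
    TRUE     ~ "ge_three_cm"
  )
}

#' Score a single acute lesion
#'
#' Bruises (submucosal bleeding, surface intact) score 1/2/3/4 points by
#' size class; wounds (mucosal surface damaged) score 2/4/6/8; a deep wound
#' receives two additional points. Vectorised over all arguments.
#'
#' @param kind `"bruise"` or `"wound"`.
#' @param size_class One of [size_classes()].
#' @param deep Logical; only wounds may be deep.
#' @return Integer vector of points.
#' @export
#' @examples
#' score_lesion("wound", "lt_half_cm")                  # 2
#' score_lesion("bruise", "one_to_three_cm")            # 3
#' score_lesion("wound", "one_to_three_cm", deep = TRUE) # 8
score_lesion <- function(kind, size_class, deep = FALSE) {
  .check_enum(kind, lesion_kinds(), "lesion kind")
  .check_enum(size_class, size_classes(), "size class")
  n <- max(length(kind), length(size_class), length(deep))
  kind <- rep_len(kind, n); size_class <- rep_len(size_class, n)
  deep <- rep_len(as.logical(deep), n)
  if (any(is.na(deep))) stop("deep flag must be TRUE or FALSE", call. = FALSE)
  if (any(deep & kind == "bruise")) {
    stop("a bruise cannot be deep: only wounds carry the deep-wound bonus", call. = FALSE)
  }
  pts <- ifelse(kind == "bruise",
                .bruise_points[size_class],
                .wound_points[size_class])
  as.integer(pts + 2L * deep)
}

#' Classify total lesion points into severity categories A-D
#'
#' A: no acute lesions (0 points). B (mild): 1-2 points. C (moderate):
#' 3-11 points, excluding horses with eight or more points from one single
#' lesion. D (severe): 12 or more points, or at least eight points from a
#' single lesion.
#'
#' @param total_points Integer vector, sum of per-lesion points.
#' @param max_single_lesion_points Integer vector, largest single-lesion
#'   score (0 when there are no lesions).
#' @return Character vector in `c("A","B","C","D")`.
#' @export
classify_severity <- function(total_points, max_single_lesion_points = total_points) {
  if (any(total_points < 0) || any(max_single_lesion_points < 0)) {
    stop("lesion points cannot be negative", call. = FALSE)
  }
  if (any(max_single_lesion_points > total_points)) {
    stop("a single lesion cannot exceed the total score", call. = FALSE)
  }
  dplyr::case_when(
    total_points == 0 ~ "A",
    total_points <= 2 ~ "B",
    total_points >= 12 | max_single_lesion_points >= 8 ~ "D",
    TRUE ~ "C"
  )
}

#' Merge severity categories into the binary analysis outcome
#'
#' A and B collapse to `"AB"` (no lesions or mild status); C and D to
#' `"CD"` (moderate or severe status), the outcome modelled downstream.
#'
#' @param category Character vector in `c("A","B","C","D")`.
#' @return Character vector in `c("AB","CD")`.
#' @export
merge_severity <- function(category) {
  .check_enum(category, c("A", "B", "C", "D"), "severity category")
  ifelse(category %in% c("A", "B"), "AB", "CD")
}

#' Score one horse's lesion list
#'
#' Sums per-lesion points over the acute lesions of one horse and derives
#' the severity category and merged AB/CD status. Old lesions (rows with
#' `acute = FALSE`) are excluded from scoring.
#'
#' @param lesions A data frame with columns `kind`, `size_class`, `deep`
#'   and optionally `acute`; zero rows means no acute lesions.
#' @return An object of class `score_result`: a list with
#'   `per_lesion_points`, `total_points`, `max_single_lesion_points`,
#'   `category` and `merged`.
#' @export
score_horse <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  if (nrow(lesions) > 0 && "acute" %in% names(lesions)) {
    lesions <- lesions[as.logical(lesions$acute), , drop = FALSE]
  }
  if (nrow(lesions) == 0) {
    pts <- integer(0)
  } else {
    deep <- if ("deep" %in% names(lesions)) lesions$deep else FALSE
    pts <- score_lesion(lesions$kind, lesions$size_class, deep)
  }
  total <- sum(pts)
  max_single <- if (length(pts)) max(pts) else 0L
  category <- classify_severity(total, max_single)
  structure(
    list(per_lesion_points = pts,
         total_points = as.integer(total),
         max_single_lesion_points = as.integer(max_single),
         category = category,
         merged = merge_severity(category)),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Lesion score: %d point(s) from %d lesion(s) (max single %d) -> category %s (%s)\n",
              x$total_points, length(x$per_lesion_points),
              x$max_single_lesion_points, x$category, x$merged))
  invisible(x)
}

#' Score every horse in a cohort
#'
#' Joins the lesion table to the exam table on `horse_id` and appends the
#' scoring columns. Horses absent from the lesion table score 0 (category A).
#'
#' @param exams One row per horse; must contain `horse_id`.
#' @param lesions One row per acute lesion; must contain `horse_id`, `kind`,
#'   `size_class`, `deep` and optionally `acute`.
#' @return `exams` with `total_points`, `max_single_lesion_points`,
#'   `category` and `merged` columns appended (recomputed if present).
#' @export
score_cohort <- function(exams, lesions) {
  stopifnot(is.data.frame(exams), "horse_id" %in% names(exams))
  exams <- dplyr::select(exams, -dplyr::any_of(
    c("total_points", "max_single_lesion_points", "category", "merged")))
  if (nrow(lesions) > 0 && "acute" %in% names(lesions)) {
    lesions <- lesions[as.logical(lesions$acute), , drop = FALSE]
  }
  if (nrow(lesions) > 0) {
    orphan <- setdiff(lesions$horse_id, exams$horse_id)
    if (length(orphan)) {
      stop("lesion records for unknown horse_id: ", paste(orphan, collapse = ", "),
           call. = FALSE)
    }
    deep <- if ("deep" %in% names(lesions)) lesions$deep else FALSE
    per <- tibble::tibble(horse_id = lesions$horse_id,
                          pts = score_lesion(lesions$kind, lesions$size_class, deep))
    agg <- dplyr::summarise(dplyr::group_by(per, .data$horse_id),
                            total_points = sum(.data$pts),
                            max_single_lesion_points = max(.data$pts),
                            .groups = "drop")
  } else {
    agg <- tibble::tibble(horse_id = character(), total_points = integer(),
                          max_single_lesion_points = integer())
  }
  out <- dplyr::left_join(exams, agg, by = "horse_id")
  out$total_points <- as.integer(dplyr::coalesce(out$total_points, 0L))
  out$max_single_lesion_points <-
    as.integer(dplyr::coalesce(out$max_single_lesion_points, 0L))
  out$category <- classify_severity(out$total_points, out$max_single_lesion_points)
  out$merged <- merge_severity(out$category)
  out
}

#' Bin continuous covariates for modelling
#'
#' Age groups 3-5, 6-9 and 10-15 years; bit thickness classes thin
#' (12-13 mm), basic (14-17 mm), thick (18-22 mm) and extra thick
#' (23-30 mm); bit jointedness (straight plastic, mullen mouth regulator
#' and Nurmos bits are unjointed; snaffle trotting, Crescendo and
#' Dr. Bristol are jointed).
#'
#' @param exams Exam table with `age_years`, `bit_thickness_mm`, `bit_type`.
#' @param other_jointed How to class the heterogeneous `"other"` bit group:
#'   `"jointed"` (default), `"unjointed"`, or `NA` to leave it unassigned
#'   (it is then excluded from jointedness-based contrasts).
#' @return `exams` with `age_group`, `thickness_class` and `jointedness`
#'   columns appended.
#' @export
bin_covariates <- function(exams, other_jointed = c("jointed", "unjointed", NA)) {
  other_jointed <- if (length(other_jointed) > 1) other_jointed[[1]] else other_jointed
  if (!is.na(other_jointed)) match.arg(other_jointed, c("jointed", "unjointed"))
  age <- exams$age_years
  thick <- exams$bit_thickness_mm
  if (any(age < 3 | age > 15)) stop("age_years must be within 3-15", call. = FALSE)
  if (any(thick < 12 | thick > 30)) {
    stop("bit_thickness_mm must be within 12-30", call. = FALSE)
  }
  .check_enum(exams$bit_type, bit_types(), "bit type")
  exams$age_group <- dplyr::case_when(
    age <= 5 ~ "y3_5",
    age <= 9 ~ "y6_9",
    TRUE     ~ "y10_15"
  )
  exams$thickness_class <- dplyr::case_when(
    thick <= 13 ~ "thin",
    thick <= 17 ~ "basic",
    thick <= 22 ~ "thick",
    TRUE        ~ "extra_thick"
  )
  unjointed <- c("straight_plastic", "mullen_mouth_regulator", "nurmos")
  jointed <- c("snaffle_trotting", "crescendo", "dr_bristol")
  exams$jointedness <- dplyr::case_when(
    exams$bit_type %in% unjointed ~ "unjointed",
    exams$bit_type %in% jointed ~ "jointed",
    TRUE ~ as.character(other_jointed)
  )
  exams
}
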