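# Hand-built fixtures and independent brute-force oracles used across tests.

# tiny longitudinal cohort exercising every assembly rule:
#  A noncase throughout; B converts at visit 2; C on diabetes medication;
#  D analyte missing everywhere; E case at visit 1 exactly at threshold;
#  F noncase with no baseline record; G discordant FPG/HbA1c status
tiny_cohort <- function() {
  row <- function(id, v, age, sex, fpg, hba1c, dm = "no", wc = 85, bmi = 26,
                  sbp = 120, dbp = 75, bpmed = "no", htn = "no", fh = "no",
                  pa = 2L, res = "rural") {
    tibble::tibble(
      participant_id = id, visit_index = as.integer(v), age = age, sex = sex,
      waist_circumference = wc, bmi = bmi, systolic_bp = sbp,
      diastolic_bp = dbp, bp_medication = bpmed, hypertension = htn,
      family_history_dm = fh, physical_activity = pa, residency = res,
      diabetes_medication = dm, fpg = fpg, hba1c = hba1c
    )
  }
  dplyr::bind_rows(
    row("A", 1, 45, "female", 5.5, 5.6), row("A", 2, 50, "female", 5.6, 5.7),
    row("A", 3, 55, "female", 5.4, 5.5),
    row("B", 1, 60, "male", 6.5, 6.0), row("B", 2, 65, "male", 7.2, 6.8),
    row("B", 3, 70, "male", 7.5, 7.0),
    row("C", 1, 50, "female", 6.0, 5.9), row("C", 3, 60, "female", 8.0, 7.2,
                                             dm = "yes"),
    row("D", 1, 40, "male", NA, NA), row("D", 2, 45, "male", NA, NA),
    row("E", 1, 55, "female", 7.0, 6.6, wc = 95, htn = "yes"),
    row("F", 2, 48, "female", 5.2, 5.4), row("F", 3, 53, "female", 5.3, 5.5),
    row("G", 1, 52, "female", 6.0, 6.5)
  )
}

# exhaustive pairwise concordance: the oracle for the C-statistic
oracle_c <- function(cases, noncases) {
  cmp <- outer(cases, noncases, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
}

# exhaustive scan over all candidate thresholds (>= rule)
oracle_scan <- function(probs, labels, objective = c("youden", "top_left")) {
  objective <- match.arg(objective)
  y <- as.logical(labels)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(probs[y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(probs[!y] < t), numeric(1))
  score <- if (objective == "youden") {
    sens + spec - 1
  } else {
    -sqrt((1 - sens)^2 + (1 - spec)^2)
  }
  best <- which(score == max(score))
  pick <- best[which.min(thr[best])]
  list(threshold = thr[pick], sensitivity = sens[pick],
       specificity = spec[pick], j = sens[pick] + spec[pick] - 1)
}

# random small instance with ties for oracle comparisons
random_instance <- function(n_max = 50) {
  n <- sample(4:n_max, 1)
  repeat {
    y <- stats::runif(n) < stats::runif(1, 0.2, 0.8)
    if (any(y) && !all(y)) break
  }
  # coarse grid forces ties
  p <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)
  list(probs = p, labels = y)
}

points_spec_3item <- function() {
  score_spec(
    name = "TOY", form = "points",
    probability_link = list(type = "score_logistic", a = -3, b = 0.5),
    items = list(
      list(predictor = "age", kind = "threshold_points", cut_point = 50,
           values = c(0, 2)),
      list(predictor = "waist_circumference", kind = "threshold_points",
           cut_point = 90, values = c(0, 3)),
      list(predictor = "hypertension", kind = "categorical_points",
           levels = list(yes = 1, no = 0))
    )
  )
}
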