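#' Build a 2x2 confusion table
#'
#' @param predictions logical vector (score positive).
#' @param outcomes logical vector (condition present), same length, no `NA`.
#' @return object of class `confusion_2x2` with counts `tp, fp, fn, tn`.
#' @export
confusion <- function(predictions, outcomes) {
  predictions <- as.logical(predictions)
  outcomes <- as.logical(outcomes)
  if (length(predictions) != length(outcomes)) {
    stop("confusion(): predictions and outcomes differ in length")
  }
  if (length(predictions) == 0L) stop("confusion(): empty input")
  if (anyNA(predictions) || anyNA(outcomes)) {
    stop("confusion(): NA in predictions or outcomes")
  }
  structure(list(tp = sum(predictions & outcomes),
                 fp = sum(predictions & !outcomes),
                 fn = sum(!predictions & outcomes),
                 tn = sum(!predictions & !outcomes)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("positive", "negative"),
                              outcome = c("present", "absent")))
  print(m)
  invisible(x)
}

as_confusion <- function(x) {
  if (inherits(x, "confusion_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == 2L)) {
    return(structure(list(tp = x[1, 1], fp = x[1, 2], fn = x[2, 1],
                          tn = x[2, 2]), class = "confusion_2x2"))
  }
  stop("expected a confusion_2x2 or 2x2 matrix")
}

#' Sensitivity and specificity of a 2x2 table
#'
#' @param c a [confusion()] table (or 2x2 matrix, rows = predicted +/-,
#'   columns = outcome +/-).
#' @return named numeric `c(sensitivity, specificity)`.
#' @examples
#' sens_spec(confusion(c(rep(TRUE, 44), FALSE), rep(TRUE, 45)))[["sensitivity"]]
#' @export
sens_spec <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fn == 0L) stop("sens_spec(): no outcome-positive cases")
  if (c$fp + c$tn == 0L) stop("sens_spec(): no outcome-negative cases")
  c(sensitivity = c$tp / (c$tp + c$fn), specificity = c$tn / (c$tn + c$fp))
}

#' AUC of a dichotomous predictor
#'
#' The ROC curve of a binary score has a single interior operating point, so
#' its area is the trapezoid `(sensitivity + specificity) / 2` — identical to
#' the Mann-Whitney statistic of the 0/1 predictions.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return the AUC.
#' @examples
#' binary_auc(1.00, 0.44) # 0.72
#' @export
binary_auc <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 |
            specificity > 1)) {
    stop("binary_auc(): rates must lie in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

#' Confidence interval for a binary-classifier AUC
#'
#' Default is the Hanley-McNeil normal-approximation interval from the
#' asymptotic standard error of the AUC; the alternative is a stratified
#' parametric bootstrap that resamples the positive and negative margins of
#' the 2x2 table binomially. Intervals are clipped to `[0, 1]`.
#'
#' @param c a [confusion()] table.
#' @param level confidence level (default 0.95).
#' @param method `"hanley"` or `"bootstrap"`.
#' @param B bootstrap replicates (default 2000).
#' @return named numeric `c(auc, ci_low, ci_high)`.
#' @export
auc_ci <- function(c, level = 0.95, method = c("hanley", "bootstrap"),
                   B = 2000) {
  c <- as_confusion(c)
  method <- match.arg(method)
  ss <- sens_spec(c)
  a <- binary_auc(ss[["sensitivity"]], ss[["specificity"]])
  m <- c$tp + c$fn  # outcome-positive
  n <- c$fp + c$tn  # outcome-negative
  if (method == "hanley") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
                 (m * n))
    z <- qnorm(1 - (1 - level) / 2)
    lo <- a - z * se; hi <- a + z * se
  } else {
    sens_b <- rbinom(B, m, ss[["sensitivity"]]) / m
    spec_b <- rbinom(B, n, ss[["specificity"]]) / n
    a_b <- (sens_b + spec_b) / 2
    qs <- quantile(a_b, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  c(auc = a, ci_low = max(0, lo), ci_high = min(1, hi))
}

# Placement values for the DeLong machinery (midrank formulation).
.delong_placements <- function(score, outcome) {
  xp <- score[outcome]; xn <- score[!outcome]
  m <- length(xp); n <- length(xn)
  r_all <- rank(c(xp, xn), ties.method = "average")
  r_p <- rank(xp, ties.method = "average")
  r_n <- rank(xn, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_p) / n             # per positive
  v01 <- 1 - (r_all[m + seq_len(n)] - r_n) / m     # per negative
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores evaluated on the same encounters against
#' the same outcome, using DeLong's covariance of the placement values.
#' Identical predictions give `p = 1` by convention.
#'
#' @param pred_a,pred_b predictions (logical or numeric scores) on the same
#'   encounters.
#' @param outcomes logical outcome vector.
#' @return list with `auc_a`, `auc_b`, `statistic` (z), `p_value`.
#' @export
compare_auc <- function(pred_a, pred_b, outcomes) {
  outcomes <- as.logical(outcomes)
  pred_a <- as.numeric(pred_a); pred_b <- as.numeric(pred_b)
  stopifnot(length(pred_a) == length(outcomes),
            length(pred_b) == length(outcomes))
  if (!any(outcomes) || all(outcomes)) {
    stop("compare_auc(): need both outcome classes")
  }
  pa <- .delong_placements(pred_a, outcomes)
  pb <- .delong_placements(pred_b, outcomes)
  m <- sum(outcomes); n <- sum(!outcomes)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- (if (m > 1) var(d10) else 0) / m + (if (n > 1) var(d01) else 0) / n
  delta <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, statistic = NA_real_,
                p_value = p))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, statistic = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Chi-squared or Fisher association test for a 2x2 table
#'
#' Pearson chi-squared without continuity correction when all expected cell
#' counts are at least 5, otherwise Fisher's exact test; two-sided.
#'
#' @param c a [confusion()] table or 2x2 matrix.
#' @return list with `p_value`, `method` (`"chi-squared"`/`"fisher"`), and
#'   `statistic` (chi-squared statistic, `NA` for Fisher).
#' @export
association_test <- function(c) {
  c <- as_confusion(c)
  m <- matrix(c(c$tp, c$fn, c$fp, c$tn), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("association_test(): degenerate margin")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(p_value = ht$p.value, method = "chi-squared",
         statistic = unname(ht$statistic))
  } else {
    ht <- stats::fisher.test(m)
    list(p_value = ht$p.value, method = "fisher", statistic = NA_real_)
  }
}

#' Grade an AUC into the report's discrimination bands
#'
#' Bands: `[0.51, 0.70)` poor, `[0.70, 0.80)` adequate, `[0.80, 0.90)`
#' sufficient, `[0.90, 1]` excellent, below 0.51 not discriminative. The
#' half-open decimal closure makes the bands partition `[0, 1]`.
#'
#' @param auc numeric vector in `[0, 1]`.
#' @return character vector of grades.
#' @examples
#' grade_auc(c(0.82, 0.73, 0.90)) # sufficient, adequate, excellent
#' @export
grade_auc <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) {
    stop("grade_auc(): AUC outside [0, 1]")
  }
  cut(auc, breaks = c(-Inf, 0.51, 0.70, 0.80, 0.90, Inf), right = FALSE,
      labels = c("not discriminative", "poor", "adequate", "sufficient",
                 "excellent")) |> as.character()
}

.fmt_num <- function(x, digits) sprintf(paste0("%.", digits, "f"),
                                        round_half_away(x, digits))

#' Stratified descriptive summary of an encounter table
#'
#' Numeric fields are summarized as mean +/- SD when a Shapiro-Wilk test (on
#' at most 5000 sampled values) does not reject normality at 0.05, otherwise
#' as median \[IQR\] with linear-interpolation quantiles; logical fields as
#' percentages.
#'
#' @param encounters encounter table with a `unit` column.
#' @param variables character vector of columns to summarize (default: all
#'   numeric/logical except identifiers).
#' @param digits decimal places for numeric formatting (default 1).
#' @return data.table with one row per variable and one formatted column per
#'   stratum plus `"all"`.
#' @export
cohort_summary <- function(encounters, variables = NULL, digits = 1) {
  enc <- as.data.table(encounters)
  if (nrow(enc) == 0L) stop("cohort_summary(): empty encounter table")
  if (is.null(variables)) {
    variables <- names(enc)[vapply(enc, function(x)
      is.numeric(x) || is.logical(x), logical(1))]
    variables <- setdiff(variables, c("encounter_id"))
  }
  strata <- c(sort(unique(enc$unit)), "all")
  out <- data.table(variable = variables)
  for (s in strata) {
    sub <- if (s == "all") enc else enc[unit == s]
    if (nrow(sub) == 0L) stop("cohort_summary(): empty stratum ", s)
    col <- vapply(variables, function(v) {
      x <- sub[[v]]
      if (is.logical(x)) return(fmt_percent(sum(x), length(x)))
      x <- x[!is.na(x)]
      if (length(x) < 3L || sd(x) == 0) {
        return(sprintf("%s ± %s", .fmt_num(mean(x), digits),
                       .fmt_num(if (length(x) > 1) sd(x) else 0, digits)))
      }
      sw <- shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)
      if (sw$p.value >= 0.05) {
        sprintf("%s ± %s", .fmt_num(mean(x), digits),
                .fmt_num(sd(x), digits))
      } else {
        q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)  # type 7
        sprintf("%s [%s–%s]", .fmt_num(q[2], digits),
                .fmt_num(q[1], digits), .fmt_num(q[3], digits))
      }
    }, character(1))
    out[, (s) := col]
  }
  out[]
}

#' Evaluate score discrimination per stratum and outcome
#'
#' For every unit stratum (plus `"all"`), score and outcome this computes the
#' 2x2 table, sensitivity/specificity, the two-point ROC AUC with its
#' confidence interval, the discrimination grade, and a chi-squared/Fisher
#' association p-value; pairwise DeLong comparisons between scores are
#' attached. The infection outcome (any suspected-infection episode) is
#' evaluated over all encounters of the stratum; the mortality outcome is by
#' default restricted to encounters with suspected infection.
#'
#' @param determinations table from [score_cohort()].
#' @param episodes table from [detect_episodes()].
#' @param encounters encounter table with `encounter_id`, `unit`, `died`.
#' @param mortality_within_infection restrict mortality rows to encounters
#'   with suspected infection (default `TRUE`).
#' @param ci_method,ci_level,B passed to [auc_ci()].
#' @return object of class `score_evaluation`: a data.table of performance
#'   rows with attribute `"comparisons"` (pairwise DeLong p-values).
#' @export
evaluate_scores <- function(determinations, episodes, encounters,
                            mortality_within_infection = TRUE,
                            ci_method = "hanley", ci_level = 0.95, B = 2000) {
  det <- as.data.table(determinations)
  enc <- as.data.table(encounters)
  eps <- as.data.table(episodes)
  infected_ids <- unique(eps$encounter_id)
  enc[, infected := encounter_id %in% infected_ids]

  # encounter-level positivity: any episode (or full-stay window) positive
  pos <- det[, .(positive = any(positive)), by = .(encounter_id, score)]
  wide <- dcast(pos, encounter_id ~ score, value.var = "positive")
  tab <- merge(enc, wide, by = "encounter_id", all.x = TRUE)
  for (s in SCORES) {
    if (!s %in% names(tab)) tab[, (s) := FALSE]
    tab[is.na(get(s)), (s) := FALSE]
  }

  strata <- c(sort(unique(tab$unit)), "all")
  rows <- list(); comps <- list()
  for (st in strata) {
    sub <- if (st == "all") tab else tab[unit == st]
    for (outc in c("infection", "mortality")) {
      d <- sub
      y <- if (outc == "infection") d$infected else {
        if (mortality_within_infection) d <- d[infected == TRUE]
        d$died
      }
      if (outc == "mortality") y <- d$died
      evaluable <- length(y) > 0 && any(y) && any(!y)
      for (s in SCORES) {
        if (!evaluable) {
          rows[[length(rows) + 1L]] <- data.table(
            stratum = st, score = s, outcome = outc, evaluable = FALSE,
            tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
            tn = NA_integer_, sensitivity = NA_real_, specificity = NA_real_,
            auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            grade = NA_character_, p_association = NA_real_)
          next
        }
        cf <- confusion(d[[s]], y)
        ss <- sens_spec(cf)
        ci <- auc_ci(cf, level = ci_level, method = ci_method, B = B)
        assoc <- tryCatch(association_test(cf)$p_value,
                          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.table(
          stratum = st, score = s, outcome = outc, evaluable = TRUE,
          tp = cf$tp, fp = cf$fp, fn = cf$fn, tn = cf$tn,
          sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
          auc = ci[["auc"]], ci_low = ci[["ci_low"]],
          ci_high = ci[["ci_high"]], grade = grade_auc(ci[["auc"]]),
          p_association = assoc)
      }
      if (evaluable) {
        prs <- combn(SCORES, 2)
        for (j in seq_len(ncol(prs))) {
          cmp <- compare_auc(d[[prs[1, j]]], d[[prs[2, j]]], y)
          comps[[length(comps) + 1L]] <- data.table(
            stratum = st, outcome = outc, score_a = prs[1, j],
            score_b = prs[2, j], auc_a = cmp$auc_a, auc_b = cmp$auc_b,
            p_value = cmp$p_value)
        }
      }
    }
  }
  res <- rbindlist(rows)
  setattr(res, "comparisons", rbindlist(comps))
  setattr(res, "class", c("score_evaluation", class(res)))
  res
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat("Score discrimination (two-point ROC)\n")
  d <- as.data.table(unclass(x))[evaluable == TRUE]
  if (nrow(d)) {
    d <- d[, .(stratum, score, outcome,
               sens = .fmt_num(sensitivity, 2), spec = .fmt_num(specificity, 2),
               auc = sprintf("%s [%s-%s]", .fmt_num(auc, 2),
                             .fmt_num(ci_low, 2), .fmt_num(ci_high, 2)),
               grade)]
    print(as.data.frame(d), row.names = FALSE)
  } else {
    cat("  (no evaluable strata)\n")
  }
  invisible(x)
}
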