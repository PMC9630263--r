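# Laterality classification, pairing designs and the paired statistical
# comparisons behind the three analyses (rule, laterality, rule within
# side).

#' Classify lower-limb dominance from the IPLAG score
#'
#' Scores 1-2 are left-footed, 4-5 right-footed; 3 (ambidextrous / no
#' preference) is unclassifiable for the dominant/non-dominant split.
#'
#' @param iplag_score integer in 1..5.
#' @return `"left"` or `"right"`.
#' @export
classify_laterality <- function(iplag_score) {
  if (length(iplag_score) != 1L || !iplag_score %in% 1:5)
    stop("classify_laterality: IPLAG score must be a single integer in 1..5")
  if (iplag_score == 3L)
    stop("classify_laterality: score 3 (ambidextrous / no preference) is unclassifiable")
  if (iplag_score <= 2L) "left" else "right"
}

#' Dominance-relative dive side
#'
#' DLL when the trial's dive side equals the subject's dominant lower limb,
#' NDLL otherwise.
#'
#' @param trial_side `"left"` or `"right"`.
#' @param dominance `"left"` or `"right"`.
#' @return `"DLL"` or `"NDLL"`.
#' @export
assign_relative_side <- function(trial_side, dominance) {
  stopifnot(trial_side %in% c("left", "right"),
            dominance %in% c("left", "right"))
  if (trial_side == dominance) "DLL" else "NDLL"
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard test with explicit preconditions
#' (3 <= n <= 5000, non-constant input).
#'
#' @param x numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    stop("shapiro_wilk: sample size must be in [3, 5000]")
  if (stats::sd(x) == 0)
    stop("shapiro_wilk: constant sample")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Student's paired t-test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the differences d = a - b, two-sided p
#' from the t distribution with n - 1 degrees of freedom.  Conventions for
#' degenerate differences: all exactly zero gives t = 0, p = 1; constant
#' non-zero differences (sd = 0) give t = +/-Inf, p = 0 with a warning.
#'
#' @param a,b numeric vectors of equal length n >= 2.
#' @return list with `t`, `p`, `df`, `n`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("paired_t_test: need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = n - 1L, n = n, mean_diff = 0))
    warning("paired_t_test: constant non-zero differences; reporting t = +/-Inf, p = 0")
    return(list(t = sign(md) * Inf, p = 0, df = n - 1L, n = n, mean_diff = md))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L, n = n,
       mean_diff = md)
}

#' Cohen's d effect size
#'
#' `"pooled"` (default): absolute mean difference over the pooled SD
#' (conventional 0.2 / 0.5 / 0.8 ladder); `"paired_diff"`: absolute mean of
#' the paired differences over their SD.
#'
#' @param a,b numeric vectors (equal length for `paired_diff`).
#' @param method `"pooled"` or `"paired_diff"`.
#' @return nonnegative effect size.
#' @export
cohens_d <- function(a, b, method = c("pooled", "paired_diff")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    stop("cohens_d: need at least 2 observations per group")
  if (method == "pooled") {
    na <- length(a); nb <- length(b)
    sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                 (na + nb - 2))
    if (sp == 0) return(if (mean(a) == mean(b)) 0 else Inf)
    abs(mean(a) - mean(b)) / sp
  } else {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 0 else Inf)
    abs(mean(d)) / stats::sd(d)
  }
}

# condition labels of one design for each trial row; NA = not in design
design_conditions <- function(results, design) {
  dominance <- vapply(results$iplag_score, classify_laterality, character(1))
  rel <- mapply(assign_relative_side, results$side, dominance)
  switch(design,
    rule = list(a = "OR", b = "NR",
                cond = ifelse(results$rule == "old", "OR", "NR")),
    laterality = list(a = "DLL", b = "NDLL", cond = rel),
    rule_within_dominant = list(
      a = "ORD", b = "NRD",
      cond = ifelse(rel != "DLL", NA_character_,
                    ifelse(results$rule == "old", "ORD", "NRD"))),
    rule_within_nondominant = list(
      a = "ORND", b = "NRND",
      cond = ifelse(rel != "NDLL", NA_character_,
                    ifelse(results$rule == "old", "ORND", "NRND"))),
    stop("unknown design: ", design))
}

#' Build paired samples for one design and variable
#'
#' Pairing unit is the subject.  `"subject_mean"` (default) pairs each
#' subject's condition means; `"trial_matched"` pairs the k-th valid trial
#' of one condition with the k-th of the other within each subject
#' (surplus trials dropped) and pools the pairs across subjects.
#' Subjects lacking trials in either condition are dropped and logged.
#'
#' @param results data.frame from [process_trials()] (already excludes
#'   quality-discarded trials).
#' @param variable one of [dive_variable_names()].
#' @param design `"rule"`, `"laterality"`, `"rule_within_dominant"` or
#'   `"rule_within_nondominant"`.
#' @param pairing_mode `"subject_mean"` or `"trial_matched"`.
#' @return list with vectors `a` and `b` (condition order as in the design
#'   labels), labels `label_a`/`label_b`, and `dropped` (log of dropped
#'   units/trials).
#' @export
build_pairs <- function(results, variable,
                        design = c("rule", "laterality",
                                   "rule_within_dominant",
                                   "rule_within_nondominant"),
                        pairing_mode = c("subject_mean", "trial_matched")) {
  design <- match.arg(design)
  pairing_mode <- match.arg(pairing_mode)
  stopifnot(variable %in% names(results))
  dc <- design_conditions(results, design)
  build_pairs_cond(results[[variable]], results$subject_id, dc, design,
                   pairing_mode)
}

# pairing core operating on precomputed condition labels (run_analysis
# computes each design's labels once and reuses them across variables)
build_pairs_cond <- function(values, subject_id, dc, design, pairing_mode) {
  keep <- !is.na(dc$cond)
  df <- data.frame(subject_id = subject_id[keep],
                   cond = dc$cond[keep],
                   value = values[keep],
                   stringsAsFactors = FALSE)
  a <- numeric(0); b <- numeric(0)
  dropped <- list()
  for (s in unique(df$subject_id)) {
    va <- df$value[df$subject_id == s & df$cond == dc$a]
    vb <- df$value[df$subject_id == s & df$cond == dc$b]
    if (length(va) == 0L || length(vb) == 0L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        subject_id = s, reason = "missing_condition", n_dropped = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    if (pairing_mode == "subject_mean") {
      a <- c(a, mean(va)); b <- c(b, mean(vb))
    } else {
      k <- min(length(va), length(vb))
      surplus <- (length(va) - k) + (length(vb) - k)
      if (surplus > 0)
        dropped[[length(dropped) + 1L]] <- data.frame(
          subject_id = s, reason = "surplus_trials", n_dropped = surplus,
          stringsAsFactors = FALSE)
      a <- c(a, va[seq_len(k)]); b <- c(b, vb[seq_len(k)])
    }
  }
  if (length(a) < 2L)
    stop(sprintf("build_pairs: fewer than 2 pairs for design '%s' (t-test undefined)",
                 design))
  list(a = a, b = b, label_a = dc$a, label_b = dc$b,
       dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Run the full statistical analysis
#'
#' For every outcome variable and requested design: group descriptives,
#' Shapiro-Wilk per group, Student's paired t-test, Cohen's d and the
#' significance flag at p <= 0.05.  The t statistic is computed on
#' differences a - b with group a the old-rule / dominant-side condition,
#' so a significant negative t means the new rule (or NDLL side) has the
#' larger mean.  A Holm-adjusted p column is appended for transparency (no
#' correction enters the significance flag).
#'
#' @param results data.frame from [process_trials()].
#' @param designs subset of the four designs to run.
#' @param pairing_mode,d_method see [build_pairs()] and [cohens_d()].
#' @param variables outcome variables to analyse.
#' @param alpha significance level (default 0.05).
#' @param shapiro_gate logical; when `TRUE`, abort with a message if any
#'   group's Shapiro-Wilk p falls below `alpha` (normality enforced rather
#'   than merely reported; default `FALSE`).
#' @return an `analysis_report` data.frame with one row per variable x
#'   design: labels, n pairs, group means/SDs, Shapiro-Wilk p per group,
#'   t, p, Cohen's d, significance; attribute `pairing_mode` records the
#'   mode used.
#' @export
run_analysis <- function(results,
                         designs = c("rule", "laterality",
                                     "rule_within_dominant",
                                     "rule_within_nondominant"),
                         pairing_mode = c("subject_mean", "trial_matched"),
                         d_method = c("pooled", "paired_diff"),
                         variables = dive_variable_names(),
                         alpha = 0.05, shapiro_gate = FALSE) {
  pairing_mode <- match.arg(pairing_mode)
  d_method <- match.arg(d_method)
  rows <- list()
  for (design in designs) {
    dc <- design_conditions(results, design)
    for (v in variables) {
      pr <- build_pairs_cond(results[[v]], results$subject_id, dc, design,
                             pairing_mode)
      tt <- paired_t_test(pr$a, pr$b)
      d <- cohens_d(pr$a, pr$b, method = d_method)
      swa <- tryCatch(shapiro_wilk(pr$a)$p, error = function(e) NA_real_)
      swb <- tryCatch(shapiro_wilk(pr$b)$p, error = function(e) NA_real_)
      if (shapiro_gate && any(c(swa, swb) < alpha, na.rm = TRUE))
        stop(sprintf("run_analysis: normality gate failed for %s/%s (Shapiro-Wilk p = %.4g, %.4g)",
                     v, design, swa, swb))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, design = design,
        group_a = pr$label_a, group_b = pr$label_b, n_pairs = tt$n,
        mean_a = mean(pr$a), sd_a = stats::sd(pr$a),
        mean_b = mean(pr$b), sd_b = stats::sd(pr$b),
        shapiro_p_a = swa, shapiro_p_b = swb,
        t = tt$t, p = tt$p, cohens_d = d,
        significant = tt$p <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  attr(out, "pairing_mode") <- pairing_mode
  attr(out, "d_method") <- d_method
  class(out) <- c("analysis_report", "data.frame")
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d comparisons (%s pairing, %s d)\n",
              nrow(x), attr(x, "pairing_mode"), attr(x, "d_method")))
  print.data.frame(x, ...)
  invisible(x)
}
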