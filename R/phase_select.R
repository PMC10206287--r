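# Mobile-phase comparison: validated-peak counts, ANOVA on asymmetry of
# commonly validated peaks, and the rank-based Sp + Saf peak quality score.

#' Construct a per-phase result
#'
#' @param phase_id Phase label.
#' @param per_analyte Named list mapping analyte_id to a `peak_metrics`
#'   record (analytes with no detected peak are simply absent).
#' @param validated_ids Character vector of validated analyte ids; computed
#'   with [validate_for_phase()] when omitted.
#' @param intensity_min,mcq_min Validation thresholds used when
#'   `validated_ids` is omitted.
#' @return An object of class `phase_result`.
#' @export
phase_result <- function(phase_id, per_analyte, validated_ids = NULL,
                         intensity_min = 1000, mcq_min = 0.5) {
  if (is.null(validated_ids))
    validated_ids <- validate_for_phase(per_analyte, intensity_min, mcq_min)
  if (!all(validated_ids %in% names(per_analyte)))
    stop_validation("validated_ids must be a subset of per_analyte names")
  structure(list(phase_id = phase_id, per_analyte = per_analyte,
                 validated_ids = validated_ids),
            class = "phase_result")
}

#' Validate analytes within one mobile phase
#'
#' An analyte is validated when its maximum intensity and MCQ are both
#' defined and at or above the user thresholds (inclusive comparisons). An
#' undefined metric fails closed.
#'
#' @param per_analyte Named list of `peak_metrics`.
#' @param intensity_min Minimum maximum-intensity (counts).
#' @param mcq_min Minimum MCQ.
#' @return Character vector of validated analyte ids.
#' @export
validate_for_phase <- function(per_analyte, intensity_min, mcq_min) {
  ok <- vapply(per_analyte, function(m) {
    !is.na(m$max_intensity) && !is.na(m$mcq) &&
      m$max_intensity >= intensity_min && m$mcq >= mcq_min
  }, logical(1))
  names(per_analyte)[ok]
}

#' Commonly validated analytes across phases
#'
#' @param phases List of `phase_result`s (at least 2).
#' @return Character vector: the intersection of the phases' validated sets
#'   (possibly empty).
#' @export
common_validated <- function(phases) {
  if (length(phases) < 2L) stop_config("need at least 2 phases")
  Reduce(intersect, lapply(phases, `[[`, "validated_ids"))
}

#' One-way ANOVA on asymmetry factors across phases
#'
#' Classic equal-variance one-way ANOVA F-test of the asymmetry factors of
#' the commonly validated peaks, grouped by mobile phase. With fewer than
#' two groups, any group smaller than two values, or a degenerate F
#' statistic (all groups constant and equal), the p-value is defined as 1.0
#' so the asymmetry rank never fires on insufficient evidence.
#'
#' @param groups Named list mapping phase_id to numeric asymmetry values.
#' @return The ANOVA p-value.
#' @export
anova_asymmetry <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L)) return(1.0)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  p <- tryCatch(
    stats::oneway.test(values ~ labels, var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.na(p) || !is.finite(p)) 1.0 else p
}

#' Score mobile phases by validated peaks and asymmetry (Sp + Saf)
#'
#' Sp is the ascending rank of the number of validated peaks (1 = fewest,
#' n = most; ties share the minimum rank of the tied block): more resolved
#' peaks score higher. Saf ranks separation performance by asymmetry, but
#' only when the one-way ANOVA across phases is significant at `alpha`;
#' otherwise (or when the common validated set is empty or too small) every
#' phase receives Saf = 1. When significant, separation quality is the mean
#' asymmetry's distance from 1 (an ideal symmetric peak) — closest to 1
#' ranks highest — or, with `saf_criterion = "lowest_mean"`, simply the
#' lowest mean asymmetry. The total score is Sp + Saf and the best phase is
#' the highest total, ties broken by more validated peaks, then by
#' lexicographic phase id.
#'
#' @param phases List of at least two `phase_result`s.
#' @param alpha Significance level for the ANOVA gate (default 0.05).
#' @param saf_criterion `"distance_to_one"` (default) or `"lowest_mean"`.
#' @return An object of class `phase_score_table`: a data frame with columns
#'   `phase_id`, `n_validated`, `mean_asymmetry`, `anova_p`, `sp`, `saf`,
#'   `total`, `best`, sorted by `phase_id`, with attributes `anova_p` and
#'   `best_phase`.
#' @export
score_phases <- function(phases, alpha = 0.05,
                         saf_criterion = c("distance_to_one", "lowest_mean")) {
  saf_criterion <- match.arg(saf_criterion)
  if (length(phases) < 2L) stop_config("need at least 2 phases to score")
  ids <- vapply(phases, `[[`, character(1), "phase_id")
  if (anyDuplicated(ids)) stop_config("duplicate phase_id in input")
  ord <- order(ids)
  phases <- phases[ord]; ids <- ids[ord]

  n_validated <- vapply(phases, function(p) length(p$validated_ids), numeric(1))
  common <- common_validated(phases)
  asym_groups <- lapply(phases, function(p)
    vapply(common, function(a) p$per_analyte[[a]]$asymmetry, numeric(1),
           USE.NAMES = FALSE))
  names(asym_groups) <- ids
  mean_asym <- vapply(asym_groups, function(g)
    if (length(g) == 0L || all(is.na(g))) NA_real_ else mean(g, na.rm = TRUE),
    numeric(1))
  p <- if (length(common) == 0L) 1.0 else anova_asymmetry(asym_groups)

  sp <- rank(n_validated, ties.method = "min")
  if (p < alpha && !any(is.na(mean_asym))) {
    quality <- switch(saf_criterion,
                      distance_to_one = abs(mean_asym - 1),
                      lowest_mean = mean_asym)
    saf <- rank(-quality, ties.method = "min")   # best quality gets rank n
  } else {
    saf <- rep(1, length(phases))
  }
  total <- sp + saf
  best_idx <- order(-total, -n_validated, ids)[1L]

  tab <- data.frame(phase_id = ids, n_validated = as.integer(n_validated),
                    mean_asymmetry = as.numeric(mean_asym), anova_p = p,
                    sp = as.integer(sp), saf = as.integer(saf),
                    total = as.integer(total),
                    best = seq_along(ids) == best_idx,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("phase_score_table", "data.frame"),
            anova_p = p, best_phase = ids[best_idx])
}

#' @export
print.phase_score_table <- function(x, ...) {
  cat("Mobile-phase peak quality scores\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("best phase: %s (ANOVA p = %.4g)\n",
              attr(x, "best_phase"), attr(x, "anova_p")))
  invisible(x)
}

#' Write a phase score table to CSV
#'
#' @param x A `phase_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_scores <- function(x, path) {
  write_table(as.data.frame(x)[, c("phase_id", "n_validated",
                                   "mean_asymmetry", "anova_p",
                                   "sp", "saf", "total", "best")], path)
}
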