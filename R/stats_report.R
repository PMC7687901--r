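# The study's statistical decision tree: Shapiro-Wilk normality gate,
# ANOVA / Wilcoxon signed-rank on the normal branch, Kruskal-Wallis /
# Friedman on the non-normal branch, Fisher's exact test for nominal data,
# and the Sidak multiple-comparison correction applied as an adjusted alpha.

#' Shapiro-Wilk normality gate
#'
#' Each group is tested at `alpha`; the gate passes only when every group
#' passes. Groups with fewer than 3 observations cannot be tested and fail
#' the gate with a warning (routing to the nonparametric branch).
#'
#' @param samples list of numeric vectors (one per group).
#' @param alpha gate level (default 0.05).
#' @return list with `pass` (overall), `per_group` logical vector, and the
#'   per-group p values (`NA` where untestable).
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!length(samples)) stopf("no samples")
  res <- vapply(samples, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L || length(unique(x)) == 1L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  per <- !is.na(res) & res >= alpha
  if (anyNA(res))
    warning("group(s) with n < 3 (or constant values) cannot be tested for normality; gate fails")
  list(pass = all(per), per_group = per, p_values = res)
}

#' Sidak-adjusted significance threshold
#'
#' For a family of `m` comparisons at family-wise level `alpha`, each
#' comparison is tested at `1 - (1 - alpha)^(1/m)`.
#'
#' @param alpha family-wise level.
#' @param m family size (>= 1).
#' @return adjusted per-comparison alpha.
#' @export
sidak_adjust <- function(alpha = 0.05, m = 1L) {
  if (m < 1) stopf("`m` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  if (m == 1) return(alpha)
  1 - (1 - alpha)^(1 / m)
}

#' Two-sided Fisher's exact test for a 2 x k table
#'
#' Two-sided p value obtained by summing hypergeometric probabilities no
#' larger than the observed table's. A table with a zero margin carries no
#' evidence and returns p = 1.
#'
#' @param table matrix of non-negative integer counts.
#' @return list with `p_value` and the input table.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) stopf("counts must be non-negative integers")
  p <- if (any(rowSums(table) == 0) || any(colSums(table) == 0)) 1
       else stats::fisher.test(table)$p.value
  list(p_value = min(p, 1), table = table)
}

#' Compare groups with the study's decision tree
#'
#' Continuous data: if all groups pass the Shapiro-Wilk gate, paired data go
#' to the Wilcoxon signed-rank test and unpaired data to a single-factor
#' ANOVA; if any group fails, paired data go to the Friedman rank-sum test
#' and unpaired data to the Kruskal-Wallis test. Nominal data go to Fisher's
#' exact test regardless of the gate. With family size `m > 1` the decision
#' threshold is Sidak-adjusted.
#'
#' The placement of the (nonparametric, paired) Wilcoxon signed-rank test on
#' the normality-passed branch mirrors the source protocol; set
#' `parametric_paired = TRUE` for a paired t-test instead.
#'
#' @param samples for continuous data, a named list of numeric vectors; for
#'   nominal data, a 2 x k count matrix.
#' @param paired are the groups paired (equal lengths required)?
#' @param kind "continuous" or "nominal".
#' @param m family size for the Sidak correction.
#' @param alpha family-wise significance level.
#' @param parametric_paired use a paired t-test on the normal branch.
#' @return object of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `alpha_adjusted`, `significant`, `gate` (normality gate
#'   result or NULL).
#' @export
compare_groups <- function(samples, paired = FALSE,
                           kind = c("continuous", "nominal"),
                           m = 1L, alpha = 0.05, parametric_paired = FALSE) {
  kind <- match.arg(kind)
  a_adj <- sidak_adjust(alpha, m)
  gate <- NULL
  if (kind == "nominal") {
    fe <- fisher_exact(samples)
    test <- "Fisher's exact"; stat <- NA_real_; p <- fe$p_value
  } else {
    if (!is.list(samples) || length(samples) < 2L) stopf("need >= 2 groups")
    if (any(vapply(samples, length, integer(1)) < 2L)) stopf("group sizes must be >= 2")
    if (paired && length(unique(vapply(samples, length, integer(1)))) != 1L)
      stopf("paired groups must have equal lengths")
    gate <- suppressWarnings(normality_gate(samples, alpha = 0.05))
    if (gate$pass) {
      if (paired) {
        if (parametric_paired) {
          if (length(samples) != 2L) stopf("paired t-test needs exactly 2 groups")
          tt <- stats::t.test(samples[[1L]], samples[[2L]], paired = TRUE)
          test <- "paired t"; stat <- unname(tt$statistic); p <- tt$p.value
        } else {
          if (length(samples) != 2L) stopf("Wilcoxon signed-rank needs exactly 2 groups")
          wt <- suppressWarnings(stats::wilcox.test(samples[[1L]], samples[[2L]], paired = TRUE))
          test <- "Wilcoxon signed-rank"; stat <- unname(wt$statistic); p <- wt$p.value
        }
      } else {
        y <- unlist(samples, use.names = FALSE)
        gfac <- factor(rep(seq_along(samples), vapply(samples, length, integer(1))))
        av <- stats::anova(stats::aov(y ~ gfac))
        test <- "one-way ANOVA"; stat <- av$`F value`[1L]; p <- av$`Pr(>F)`[1L]
      }
    } else {
      if (paired) {
        ymat <- do.call(cbind, samples)
        ft <- stats::friedman.test(ymat)
        test <- "Friedman"; stat <- unname(ft$statistic); p <- ft$p.value
      } else {
        kt <- stats::kruskal.test(samples)
        test <- "Kruskal-Wallis"; stat <- unname(kt$statistic); p <- kt$p.value
      }
    }
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 alpha = alpha, m = m, alpha_adjusted = a_adj,
                 significant = is.finite(p) && p < a_adj,
                 gate = gate, paired = paired, kind = kind),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  gs <- if (is.null(x$gate)) "" else
    sprintf("; normality gate %s", if (x$gate$pass) "passed" else "failed")
  cat(sprintf("<group_comparison> %s: p = %.4g (alpha %.4g%s) -> %s%s\n",
              x$test, x$p_value, x$alpha_adjusted,
              if (x$m > 1) sprintf(", Sidak m = %d", x$m) else "",
              if (x$significant) "significant" else "not significant", gs))
  invisible(x)
}

#' Collate analysis results into a report
#'
#' Gathers CV estimates, P-wave measurements, arrhythmia calls, enrichment
#' summaries, distance profiles and group comparisons into a serializable
#' report mirroring the figure-panel tables, together with configuration and
#' seeds.
#'
#' @param results named list; recognized classes are collated by section,
#'   anything else is stored verbatim under `other`.
#' @param config optional list of configuration values to embed.
#' @param seeds optional named seeds to embed.
#' @return object of class `analysis_report` (a named list).
#' @export
build_report <- function(results = list(), config = list(), seeds = list()) {
  section_of <- function(x) {
    if (inherits(x, "cv_estimate")) "conduction_velocity"
    else if (inherits(x, "p_wave_measurement")) "p_wave"
    else if (inherits(x, "arrhythmia_call")) "arrhythmia"
    else if (inherits(x, "enrichment_summary") || inherits(x, "enrichment_ratio")) "enrichment"
    else if (inherits(x, "mass_enrichment")) "mass_enrichment"
    else if (inherits(x, "distance_profile")) "intermembrane_distance"
    else if (inherits(x, "group_comparison")) "statistics"
    else "other"
  }
  sections <- list()
  for (nm in names(results)) {
    sec <- section_of(results[[nm]])
    entry <- unclass(results[[nm]])
    entry <- entry[!vapply(entry, is.function, logical(1))]
    sections[[sec]][[nm]] <- entry
  }
  structure(list(sections = sections,
                 n_results = length(results),
                 config = config, seeds = seeds,
                 package_version = tryCatch(as.character(utils::packageVersion("idnano")),
                                            error = function(e) "unknown"),
                 created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d results in %d section(s): %s\n",
              x$n_results, length(x$sections),
              paste(names(x$sections), collapse = ", ")))
  invisible(x)
}

#' Write / read a report as JSON
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return `read_report` returns the report list (class restored).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "analysis_report"
  rep
}
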