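#' Pool technical replicates to animal level
#'
#' The animal, not the well, is the statistical unit: left- and right-nerve
#' fragments are pooled per animal by an arithmetic mean over included
#' standard wells for every metric column. Negative-control wells never
#' contribute (the upstream metric tables already omit them). With
#' `by_side = TRUE` the mean is additionally stratified by nerve side, which
#' supports the left-versus-right equivalence check; when both sides
#' contribute equal well counts the pooled mean equals the mean of the side
#' means.
#'
#' @param metrics Per-well mitostress table from [compute_mitostress()].
#' @param tox Optional per-well toxicity table from [compute_mitotox()],
#'   joined by `well_id` before pooling.
#' @param by_side Stratify by the `side` column instead of pooling across it.
#' @return A tibble with one row per animal (or per animal x side):
#'   `animal_id`, `group`, `n_wells`, and the per-animal mean of every
#'   numeric metric. Animals whose wells all failed QC upstream are simply
#'   absent; an animal contributing only `NA` for some metric gets `NA` there
#'   with a warning.
#' @export
aggregate_by_animal <- function(metrics, tox = NULL, by_side = FALSE) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot(all(c("well_id", "animal_id", "group") %in% names(metrics)))
  if (!is.null(tox)) {
    tox <- tibble::as_tibble(tox)
    metrics <- dplyr::left_join(
      metrics, tox[setdiff(names(tox), c("animal_id", "group"))],
      by = "well_id")
  }
  drop <- c("well_id", "note", if (!by_side) "side")
  metrics <- metrics[setdiff(names(metrics), drop)]
  keys <- c("animal_id", "group", if (by_side) "side")
  out <- dplyr::summarise(
    dplyr::group_by(metrics, dplyr::across(dplyr::all_of(keys))),
    n_wells = dplyr::n(),
    dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("^n_wells$"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  out[] <- lapply(out, function(x) replace(x, is.nan(x), NA))
  if (anyNA(out)) {
    warning("some animal-level means are missing (all contributing wells NA).",
            call. = FALSE)
  }
  out
}

# Significance tiers at 0.05 / 0.01 / 0.001.
signif_tier <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Two-group comparison of animal-level metrics
#'
#' Runs an unpaired two-tailed Student's t-test (pooled variance by default,
#' matching the classical "Student's" test; set `var_equal = FALSE` for
#' Welch) on every metric column of an animal-level summary table with
#' exactly two groups. Group means and SDs are across animals.
#'
#' @param summaries Animal-level table from [aggregate_by_animal()] (or any
#'   tibble with `animal_id`, `group` and numeric metric columns).
#' @param metrics Character vector of metric columns to compare (default:
#'   all numeric columns except `n_wells`).
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A tibble with one row per metric: `metric`, `group1`, `group2`,
#'   `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, `statistic`, `df`,
#'   `p_value`, `signif` (`*`/`**`/`***` at 0.05/0.01/0.001, `ns` above).
#' @export
compare_groups <- function(summaries, metrics = NULL, var_equal = TRUE) {
  summaries <- tibble::as_tibble(summaries)
  stopifnot("group" %in% names(summaries))
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2) {
    stop("compare_groups() needs exactly two groups; got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  n_per <- table(summaries$group)
  if (any(n_per < 2)) {
    stop("need >= 2 animals per group; too few in: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), call. = FALSE)
  }
  if (is.null(metrics)) {
    num <- vapply(summaries, is.numeric, logical(1))
    metrics <- setdiff(names(summaries)[num], c("n_wells", "week"))
  }
  purrr::map_dfr(metrics, function(m) {
    x <- summaries[[m]][summaries$group == groups[1]]
    y <- summaries[[m]][summaries$group == groups[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(
        metric = m, group1 = groups[1], group2 = groups[2],
        mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
        mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
        statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        signif = NA_character_))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
    tibble::tibble(
      metric = m, group1 = groups[1], group2 = groups[2],
      mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
      mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, signif = signif_tier(tt$p.value))
  })
}

#' Two-factor comparison with Sidak-adjusted simple effects
#'
#' Fits a two-way ANOVA (`response ~ factor1 * factor2`, e.g. genotype by
#' week for blood glucose or body weight) and reports the Sidak-adjusted
#' simple-effect pairwise comparisons: each level of one factor compared
#' between levels of the other, both ways, adjusted as one family (four
#' comparisons in a 2 x 2 design).
#'
#' @param data A data frame in long form.
#' @param response Name of the numeric response column.
#' @param factor1,factor2 Names of the two factor columns (default `group`
#'   and `week`).
#' @return A tibble: `contrast`, `stratum`, `estimate`, `se`, `df`,
#'   `statistic`, `p_value` (Sidak-adjusted), `signif`, plus the ANOVA table
#'   as `attr(, "anova")`.
#' @export
compare_two_factor <- function(data, response, factor1 = "group",
                               factor2 = "week") {
  data <- tibble::as_tibble(data)
  stopifnot(all(c(response, factor1, factor2) %in% names(data)))
  d <- stats::setNames(
    data.frame(data[[response]], factor(data[[factor1]]),
               factor(data[[factor2]])),
    c(".y", factor1, factor2))
  if (nlevels(d[[factor1]]) < 2 || nlevels(d[[factor2]]) < 2) {
    stop("both factors need >= 2 levels.", call. = FALSE)
  }
  fit <- stats::aov(stats::reformulate(sprintf("%s * %s", factor1, factor2),
                                       response = ".y"), data = d)
  emm <- emmeans::emmeans(fit, stats::reformulate(c(factor1, factor2)))
  cons <- emmeans::contrast(emm, method = "pairwise", simple = "each",
                            combine = TRUE, adjust = "sidak")
  tab <- as.data.frame(cons)
  # `simple = "each"` marks the contrasted factor with "."; the other
  # column holds the stratum level the comparison is conditioned on.
  lev <- cbind(as.character(tab[[factor1]]), as.character(tab[[factor2]]))
  strat <- apply(lev, 1, function(r) paste(r[r != "."], collapse = ":"))
  out <- tibble::tibble(
    contrast = as.character(tab$contrast), stratum = strat,
    estimate = tab$estimate, se = tab$SE, df = tab$df,
    statistic = tab$t.ratio, p_value = tab$p.value,
    signif = signif_tier(tab$p.value))
  attr(out, "anova") <- summary(fit)
  out
}

#' Classify hyperglycemia
#'
#' A random-fed blood glucose concentration strictly exceeding 16.7 mM — the
#' murine renal threshold for glucose reabsorption — is classified
#' hyperglycemic. Values at or above the 33.3 mM glucometer detection
#' ceiling are right-censored; they still classify as hyperglycemic but are
#' flagged via `attr(, "censored")`.
#'
#' @param glucose_mM Numeric vector of blood glucose concentrations (mM,
#'   non-negative).
#' @param threshold_mM Diagnostic threshold (default 16.7).
#' @param ceiling_mM Meter detection limit (default 33.3).
#' @return A logical vector (`TRUE` = hyperglycemic) with a logical
#'   `censored` attribute of the same length.
#' @examples
#' classify_hyperglycemia(c(20.1, 7.5, 16.7)) # TRUE FALSE FALSE
#' @export
classify_hyperglycemia <- function(glucose_mM, threshold_mM = 16.7,
                                   ceiling_mM = 33.3) {
  if (any(glucose_mM < 0, na.rm = TRUE)) {
    stop("glucose concentrations must be >= 0.", call. = FALSE)
  }
  out <- glucose_mM > threshold_mM
  attr(out, "censored") <- !is.na(glucose_mM) & glucose_mM >= ceiling_mM
  out
}
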