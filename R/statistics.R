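#' Kruskal-Wallis omnibus test
#'
#' Rank-based comparison of two or more groups with mid-rank tie
#' correction, p-value from the chi-square approximation with k - 1
#' degrees of freedom (via [stats::kruskal.test()]). The degenerate case
#' of all-identical pooled values is reported as H = 0, p = 1 and
#' flagged, rather than failing.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`,
#'   `degenerate`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("`groups` must be a list of at least two numeric samples.")
  }
  n <- lengths(groups)
  if (any(n < 1L) || sum(n) < 3L) {
    abort("Each group needs n >= 1 and the pooled sample n >= 3.")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  degenerate = TRUE))
  }
  ht <- stats::kruskal.test(groups)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, degenerate = FALSE)
}

#' Pearson chi-square test of independence
#'
#' Pearson's chi-square on a contingency table of counts, without
#' continuity correction, df = (r - 1)(c - 1).
#'
#' @param counts A matrix (or table) of non-negative integer counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))  # 6.667
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Contingency table has an all-zero margin.")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Orders the p-values, rejects all hypotheses up to the largest i with
#' p(i) <= i q / m, and reports monotone adjusted values
#' (via [stats::p.adjust()]). Controls the false discovery rate at q for
#' independent or positively dependent tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level in (0, 1).
#' @return A tibble in input order: `p`, `p_adjusted`, `reject`.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.008, 0.039, 0.041), q = 0.01)  # one rejection
bh_adjust <- function(p, q = 0.01) {
  if (length(p) == 0L) abort("Empty p-value vector.")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  adj <- stats::p.adjust(p, method = "BH")
  tibble(p = p, p_adjusted = adj, reject = adj <= q)
}

contrast_marks <- function() {
  c("healthy-asthma" = "*", "asthma-COPD" = "†", "COPD-healthy" = "‡")
}

# Two-sample rank test (Mann-Whitney / two-group Kruskal-Wallis form),
# normal approximation with tie correction.
pairwise_rank <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    return(c(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  c(statistic = unname(ht$statistic), p_value = p)
}

#' Three-group comparison with FDR control
#'
#' Reproduces the study's comparison design on a long metric table:
#' a Kruskal-Wallis omnibus test for every metric x region, two-sample
#' rank tests for the three pairwise contrasts, chi-square tests for
#' categorical demographics and Kruskal-Wallis for continuous ones, with
#' one Benjamini-Hochberg adjustment at level `q` across the whole
#' comparison family.
#'
#' The default family contains every omnibus test, the whole-lung
#' pairwise contrasts and the demographic tests; with the default cohort
#' layout (3 airway metrics x 10 regions, 6 lobar metrics x 5 lobes, 5
#' whole-lung metrics, 7 demographic variables) it comprises 87 tests.
#' Regional pairwise contrasts are emitted as post-hoc annotations
#' (flagged on raw p < q, the figure-footnote convention) unless
#' `family = "all"` pulls every emitted test into one BH family.
#'
#' @param metrics Long tibble from [generate_cohort_metrics()] (or real
#'   data in the same shape): `subject_id`, `group`, `variable`,
#'   `region`, `value`.
#' @param demographics Optional per-subject covariate tibble (see
#'   [generate_demographics()]); continuous columns are tested with
#'   Kruskal-Wallis and categorical ones with chi-square.
#' @param q FDR level (default 0.01).
#' @param family `"default"` (omnibus + whole-lung pairwise +
#'   demographics) or `"all"` (every emitted test in one family).
#' @return An object of class `qct_comparison` with [tidy()],
#'   [glance()], [autoplot()] and [report_markdown()] methods.
#' @export
compare_groups <- function(metrics, demographics = NULL, q = 0.01,
                           family = c("default", "all")) {
  family <- match.arg(family)
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  metrics <- as_tibble(metrics)
  needed <- c("subject_id", "group", "variable", "region", "value")
  if (!all(needed %in% names(metrics))) {
    abort(paste0("`metrics` needs columns ", paste(needed, collapse = ", "), "."))
  }
  metrics$group <- as.character(metrics$group)

  key <- paste(metrics$variable, metrics$region, sep = "\r")
  by_combo <- split(seq_len(nrow(metrics)), key)
  combo_names <- names(by_combo)
  pairs <- list(c("healthy", "asthma"), c("asthma", "COPD"),
                c("COPD", "healthy"))
  marks <- contrast_marks()

  nmax <- 4L * length(by_combo)
  col_var <- character(nmax); col_reg <- character(nmax)
  col_test <- character(nmax); col_con <- rep(NA_character_, nmax)
  col_stat <- numeric(nmax); col_df <- rep(NA_real_, nmax)
  col_p <- numeric(nmax)
  nrow_out <- 0L
  skipped <- character(0)
  for (ci in seq_along(by_combo)) {
    idx <- by_combo[[ci]]
    vr <- strsplit(combo_names[ci], "\r", fixed = TRUE)[[1]]
    vals <- metrics$value[idx]
    grp <- metrics$group[idx]
    keep <- is.finite(vals)
    vals <- vals[keep]; grp <- grp[keep]
    gsplit <- split(vals, factor(grp, levels = cohort_groups()))
    gsplit <- gsplit[lengths(gsplit) > 0L]
    if (length(gsplit) < 2L) {
      skipped <- c(skipped, paste(vr, collapse = " / "))
      next
    }
    if (length(unique(vals)) == 1L) {
      h <- 0; dfh <- length(gsplit) - 1; ph <- 1
    } else {
      ht <- stats::kruskal.test(gsplit)
      h <- unname(ht$statistic); dfh <- unname(ht$parameter); ph <- ht$p.value
    }
    nrow_out <- nrow_out + 1L
    col_var[nrow_out] <- vr[1]; col_reg[nrow_out] <- vr[2]
    col_test[nrow_out] <- "kruskal_wallis"
    col_stat[nrow_out] <- h; col_df[nrow_out] <- dfh; col_p[nrow_out] <- ph
    for (pr in pairs) {
      if (!all(pr %in% names(gsplit))) next
      r <- pairwise_rank(gsplit[[pr[1]]], gsplit[[pr[2]]])
      nrow_out <- nrow_out + 1L
      col_var[nrow_out] <- vr[1]; col_reg[nrow_out] <- vr[2]
      col_test[nrow_out] <- "pairwise_rank"
      col_con[nrow_out] <- paste(pr, collapse = "-")
      col_stat[nrow_out] <- r[["statistic"]]
      col_p[nrow_out] <- r[["p_value"]]
    }
  }
  if (length(skipped)) {
    message("Skipped (fewer than 2 groups): ", paste(skipped, collapse = "; "))
  }
  sel <- seq_len(nrow_out)
  results <- tibble(variable = col_var[sel], region = col_reg[sel],
                    test = col_test[sel], contrast = col_con[sel],
                    statistic = col_stat[sel], df = col_df[sel],
                    p_value = col_p[sel])

  if (!is.null(demographics)) {
    demographics <- as_tibble(demographics)
    demographics$group <- as.character(demographics$group)
    cont <- intersect(c("age", "bmi", "fev1_pct", "fev1_fvc", "pack_years"),
                      names(demographics))
    cat_ <- intersect(c("sex", "race"), names(demographics))
    demo_rows <- purrr::map_dfr(cont, function(v) {
      g <- split(demographics[[v]], factor(demographics$group,
                                           levels = cohort_groups()))
      g <- g[lengths(g) > 0L]
      if (length(g) < 2L) return(NULL)
      r <- kruskal_wallis(g)
      tibble(variable = v, region = "demographics", test = "kruskal_wallis",
             contrast = NA_character_, statistic = r$statistic,
             df = as.double(r$df), p_value = r$p_value)
    })
    demo_cat <- purrr::map_dfr(cat_, function(v) {
      tab <- table(demographics$group, demographics[[v]])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (any(dim(tab) < 2L)) return(NULL)
      r <- chi_square(tab)
      tibble(variable = v, region = "demographics", test = "chi_square",
             contrast = NA_character_, statistic = r$statistic,
             df = as.double(r$df), p_value = r$p_value)
    })
    results <- dplyr::bind_rows(results, demo_rows, demo_cat)
  }

  in_family <- if (family == "all") {
    rep(TRUE, nrow(results))
  } else {
    results$test != "pairwise_rank" | results$region == "whole"
  }
  results$in_family <- in_family
  results$p_adjusted <- NA_real_
  results$significant <- NA
  if (any(in_family)) {
    adj <- bh_adjust(results$p_value[in_family], q = q)
    results$p_adjusted[in_family] <- adj$p_adjusted
    results$significant[in_family] <- adj$reject
  }
  ann <- !in_family
  results$significant[ann] <- results$p_value[ann] < q
  results$mark <- ifelse(results$test == "pairwise_rank" &
                           !is.na(results$significant) & results$significant,
                         unname(marks[results$contrast]), "")
  results$mark[is.na(results$mark)] <- ""

  summaries <- metrics |>
    dplyr::group_by(.data$variable, .data$region, .data$group) |>
    dplyr::summarise(n = sum(is.finite(.data$value)),
                     mean = mean(.data$value[is.finite(.data$value)]),
                     sd = sd(.data$value[is.finite(.data$value)]),
                     .groups = "drop") |>
    dplyr::mutate(ci_half = qt(0.975, pmax(.data$n - 1, 1)) *
                    .data$sd / sqrt(pmax(.data$n, 1)))

  structure(list(results = results, summaries = summaries, q = q,
                 family = family, family_size = sum(in_family),
                 n_rejected = sum(results$significant[results$in_family],
                                  na.rm = TRUE)),
            class = "qct_comparison")
}

#' @export
print.qct_comparison <- function(x, ...) {
  cat("<qct_comparison> ", nrow(x$results), " tests emitted; BH family of ",
      x$family_size, " at q = ", x$q, "; ", x$n_rejected,
      " family rejection(s)\n", sep = "")
  sig <- x$results[which(x$results$in_family & x$results$significant), ]
  if (nrow(sig)) {
    cat("Significant after FDR control:\n")
    print(as_tibble(sig[, c("variable", "region", "test", "contrast",
                            "p_value", "p_adjusted")]), n = 20)
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x,object A `qct_comparison` object.
#' @param ... Unused.
#' @method tidy qct_comparison
#' @export
tidy.qct_comparison <- function(x, ...) x$results

#' @rdname compare_groups
#' @method glance qct_comparison
#' @export
glance.qct_comparison <- function(x, ...) {
  tibble(n_tests = nrow(x$results), family_size = x$family_size,
         n_rejected = x$n_rejected, q = x$q, family = x$family)
}

#' Markdown report of a group comparison
#'
#' Group means with confidence intervals per metric and region, annotated
#' with the footnote convention of the figures: `*` healthy vs asthma,
#' `†` asthma vs COPD, `‡` COPD vs healthy (p < q for
#' annotations; BH-adjusted within the family).
#'
#' @param comparison A `qct_comparison`.
#' @param path Optional file to write to.
#' @return The report lines, invisibly when `path` is given.
#' @export
report_markdown <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "qct_comparison"))
  res <- comparison$results
  sums <- comparison$summaries
  lines <- c("# Group comparison report", "",
             paste0("Family: ", comparison$family, " (", comparison$family_size,
                    " tests), BH at q = ", comparison$q, "; ",
                    comparison$n_rejected, " rejection(s)."), "",
             paste0("Footnotes: * healthy vs asthma; † asthma vs COPD; ",
                    "‡ COPD vs healthy."), "")
  combos <- unique(res[res$region != "demographics", c("variable", "region")])
  lines <- c(lines, "| variable | region | healthy | asthma | COPD | flags |",
             "|---|---|---|---|---|---|")
  fmt <- function(m, ci) {
    ifelse(is.finite(m), sprintf("%.3g (±%.2g)", m, ci), "-")
  }
  for (i in seq_len(nrow(combos))) {
    v <- combos$variable[i]; r <- combos$region[i]
    s <- sums[sums$variable == v & sums$region == r, ]
    cell <- vapply(cohort_groups(), function(g) {
      row <- s[s$group == g, ]
      if (nrow(row)) fmt(row$mean, row$ci_half) else "-"
    }, character(1))
    fl <- paste(res$mark[res$variable == v & res$region == r &
                           res$test == "pairwise_rank"], collapse = "")
    lines <- c(lines, paste0("| ", v, " | ", r, " | ",
                             paste(cell, collapse = " | "), " | ", fl, " |"))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
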