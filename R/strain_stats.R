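# Comparison machinery: branch-by-branch matching of morphometry tables,
# through-origin least squares with Pearson r, per-generation ANOVA across
# strains, and Bonferroni-corrected paired t tests.

#' Match branches of two morphometry tables by Raabe label
#'
#' Inner join on the binary label; only airways present in both tables are
#' paired. Unmatched labels are reported on both sides.
#'
#' @param table_a,table_b Morphometry tables (data frames with `label` and
#'   measure columns). Duplicate labels are rejected.
#' @return A `matched_pairs` object: `pairs` (data frame with `label` and
#'   `<measure>_a` / `<measure>_b` columns), `only_a`, `only_b`.
#' @export
match_branches <- function(table_a, table_b) {
  if (anyDuplicated(table_a$label) || anyDuplicated(table_b$label)) {
    stop("tables contain duplicate labels")
  }
  shared <- intersect(table_a$label, table_b$label)
  measures <- intersect(
    c("length_mm", "diameter_mm", "branch_angle_deg", "gravity_angle_deg"),
    intersect(names(table_a), names(table_b)))
  ia <- match(shared, table_a$label)
  ib <- match(shared, table_b$label)
  pairs <- data.frame(label = shared, stringsAsFactors = FALSE)
  for (m in measures) {
    pairs[[paste0(m, "_a")]] <- table_a[[m]][ia]
    pairs[[paste0(m, "_b")]] <- table_b[[m]][ib]
  }
  structure(list(
    pairs = pairs,
    only_a = setdiff(table_a$label, shared),
    only_b = setdiff(table_b$label, shared)
  ), class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs> %d paired, %d only in A, %d only in B\n",
              nrow(x$pairs), length(x$only_a), length(x$only_b)))
  invisible(x)
}

#' Least-squares regression through the origin, with Pearson r
#'
#' Slope of the no-intercept fit `y ~ 0 + x`: `sum(x*y) / sum(x^2)`. The
#' correlation reported is the conventional mean-centered Pearson r; the
#' uncentered R-squared of the through-origin fit is also returned to
#' disambiguate the two conventions.
#'
#' @param x,y Numeric vectors, n >= 2, not all `x` zero.
#' @return List: `slope`, `r` (NA, flagged via `r_defined = FALSE`, when
#'   either variable has zero variance), `r_squared_uncentered`, `n`.
#' @export
regression_through_origin <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite pairs")
  if (all(x == 0)) stop("all x are zero; slope undefined")
  slope <- sum(x * y) / sum(x^2)
  r_defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  r <- if (r_defined) stats::cor(x, y) else NA_real_
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  list(slope = slope, r = r, r_defined = r_defined,
       r_squared_uncentered = if (ss_tot > 0) 1 - ss_res / ss_tot else
         NA_real_,
       n = n)
}

#' One-way ANOVA across strains of per-cast generation means
#'
#' For each generation and measure, a one-way fixed-effects ANOVA across
#' strains. The replicates are casts: each cast contributes its
#' generation-mean (airway values within a generation averaged), matching
#' how generation data are summarized before strain comparison. Set
#' `replicates = "branches"` to use individual branches instead.
#'
#' @param tables Named list of morphometry tables, one per cast.
#' @param strains Character vector, same length as `tables`: strain of each
#'   cast.
#' @param measures Measure columns to test.
#' @param replicates `"casts"` (default) or `"branches"`.
#' @return Data frame: generation, measure, F, p, significant at .05/.01,
#'   n_groups; generations with fewer than 2 strains of >= 2 casts are
#'   absent (with a `reason` row).
#' @export
anova_by_strain <- function(tables, strains,
                            measures = c("length_mm", "diameter_mm",
                                         "branch_angle_deg",
                                         "gravity_angle_deg"),
                            replicates = c("casts", "branches")) {
  replicates <- match.arg(replicates)
  stopifnot(length(tables) == length(strains))
  gens <- sort(unique(unlist(lapply(tables, function(t) nchar(t$label)))))
  out <- list()
  for (gg in gens) {
    for (m in measures) {
      vals <- list()
      grp <- character(0)
      for (i in seq_along(tables)) {
        t <- tables[[i]]
        sel <- nchar(t$label) == gg & is.finite(t[[m]])
        if (!any(sel)) next
        if (replicates == "casts") {
          vals[[length(vals) + 1]] <- mean(t[[m]][sel])
          grp <- c(grp, strains[i])
        } else {
          vals[[length(vals) + 1]] <- t[[m]][sel]
          grp <- c(grp, rep(strains[i], sum(sel)))
        }
      }
      y <- unlist(vals)
      gf <- factor(grp)
      counts <- base::table(gf)
      if (length(counts) < 2 || sum(counts >= 2) < 2) {
        out[[length(out) + 1]] <- data.frame(
          generation = gg, measure = m, F = NA_real_, p = NA_real_,
          sig_05 = NA, sig_01 = NA, n_groups = length(counts),
          reason = "insufficient groups", stringsAsFactors = FALSE)
        next
      }
      if (stats::var(y) == 0) {
        out[[length(out) + 1]] <- data.frame(
          generation = gg, measure = m, F = 0, p = 1,
          sig_05 = FALSE, sig_01 = FALSE, n_groups = length(counts),
          reason = "", stringsAsFactors = FALSE)
        next
      }
      fit <- stats::aov(y ~ gf)
      s <- summary(fit)[[1]]
      Fv <- s$`F value`[1]
      pv <- s$`Pr(>F)`[1]
      out[[length(out) + 1]] <- data.frame(
        generation = gg, measure = m, F = Fv, p = pv,
        sig_05 = pv < 0.05, sig_01 = pv < 0.01,
        n_groups = length(counts), reason = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired t tests with Bonferroni correction
#'
#' Standard paired t statistic for each comparison; the Bonferroni family
#' size `m` defaults to the number of comparisons supplied. Each raw p is
#' compared to `alpha / m`, and adjusted p-values `min(1, m * p)` are
#' reported. Zero-variance differences are flagged degenerate (t = 0 when
#' the mean difference is 0; p -> 0 limit otherwise).
#'
#' @param comparisons Named list; each element a list/data frame with
#'   numeric `x` and `y` of equal length (>= 2 pairs).
#' @param m Bonferroni family size (default `length(comparisons)`).
#' @param alpha Family-wise significance level (default 0.01).
#' @return Data frame: comparison, n, t, p, p_adjusted, threshold,
#'   significant, degenerate.
#' @export
paired_t_bonferroni <- function(comparisons, m = length(comparisons),
                                alpha = 0.01) {
  stopifnot(length(comparisons) >= 1, m >= 1)
  rows <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    nm <- names(comparisons)[i] %||% as.character(i)
    d <- cmp$x - cmp$y
    n <- length(d)
    if (n < 2) stop("comparison '", nm, "' has fewer than 2 pairs")
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        return(data.frame(comparison = nm, n = n, t = 0, p = 1,
                          p_adjusted = 1, threshold = alpha / m,
                          significant = FALSE, degenerate = TRUE,
                          stringsAsFactors = FALSE))
      }
      # all differences identical and nonzero: t -> infinity, p -> 0
      return(data.frame(comparison = nm, n = n, t = Inf, p = 0,
                        p_adjusted = 0, threshold = alpha / m,
                        significant = TRUE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(cmp$x, cmp$y, paired = TRUE)
    p <- tt$p.value
    data.frame(comparison = nm, n = n, t = unname(tt$statistic), p = p,
               p_adjusted = min(1, m * p), threshold = alpha / m,
               significant = p < alpha / m, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two morphometry tables measure by measure
#'
#' Matches branches by label and reports the through-origin slope, Pearson
#' r and n for each shared measure — the shape of a method-comparison
#' summary row.
#'
#' @param table_a,table_b Morphometry tables.
#' @param measures Measure columns to compare.
#' @return Data frame: measure, slope, r, r_squared_uncentered, n.
#' @export
compare_tables <- function(table_a, table_b,
                           measures = c("length_mm", "diameter_mm",
                                        "branch_angle_deg")) {
  mp <- match_branches(table_a, table_b)
  rows <- lapply(measures, function(m) {
    xa <- mp$pairs[[paste0(m, "_a")]]
    xb <- mp$pairs[[paste0(m, "_b")]]
    if (is.null(xa) || is.null(xb)) return(NULL)
    ok <- is.finite(xa) & is.finite(xb)
    if (sum(ok) < 2) return(NULL)
    fit <- regression_through_origin(xa[ok], xb[ok])
    data.frame(measure = m, slope = fit$slope, r = fit$r,
               r_squared_uncentered = fit$r_squared_uncentered, n = fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
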