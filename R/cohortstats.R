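#' Construct a clinical expression cohort
#'
#' A cohort holds one expression value per sample-gene pair on the 2log
#' (log base-2) scale, plus per-sample categorical clinical
#' annotations. Annotation levels outside the declared vocabulary are
#' mapped to `"unknown"`; unknowns are excluded from tests listwise,
#' never imputed.
#'
#' @param expression Numeric matrix, samples in rows (rownames are
#'   sample ids), genes in columns, values on the 2log scale.
#' @param annotations Data frame with one row per sample (`sample`
#'   column or rownames) and categorical columns such as `age_group`
#'   (`<18mo` / `>=18mo`), `mycn` (`amplified` / `not amplified`),
#'   `inss_stage` (`1`,`2`,`3`,`4`,`4S`).
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(expression, annotations) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    rownames(expression) <- sprintf("S%04d", seq_len(nrow(expression)))
  if (is.null(annotations$sample)) annotations$sample <- rownames(expression)
  if (nrow(annotations) != nrow(expression))
    stop("annotations must have one row per sample", call. = FALSE)
  if (anyDuplicated(annotations$sample))
    stop("duplicate sample identifiers", call. = FALSE)
  ann <- annotations[match(rownames(expression), annotations$sample), , drop = FALSE]
  for (cl in setdiff(names(ann), "sample")) {
    v <- as.character(ann[[cl]])
    v[is.na(v) | v == "" | v == "n.d."] <- "unknown"
    ann[[cl]] <- v
  }
  rownames(ann) <- NULL
  structure(list(expression = expression, annotations = ann),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("Expression cohort: %d samples x %d genes (2log scale); annotations: %s\n",
              nrow(x$expression), ncol(x$expression),
              paste(setdiff(names(x$annotations), "sample"), collapse = ", ")))
  invisible(x)
}

#' Genes present in a cohort
#' @param cohort A `cohort_matrix`.
#' @return Character vector of gene identifiers.
#' @export
cohort_genes <- function(cohort) colnames(cohort$expression)

# Kruskal-Wallis H with tie correction, from first principles; used both
# as the permutation-test statistic and cross-checked against
# stats::kruskal.test in the test suite.
.kw_statistic <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) h / tie_corr else 0
}

#' Kruskal-Wallis association of expression with clinical groups
#'
#' Rank-based test for a location difference of a gene's expression
#' across two or more clinical groups. The H statistic carries the tie
#' correction and the p-value comes from the chi-square approximation
#' with k-1 degrees of freedom. For small cohorts (total n at most
#' `exact_max_n`) an exact permutation p-value is also computed by full
#' enumeration of group-label assignments.
#'
#' Unknown annotations (`NA` or `"unknown"`) are dropped before
#' testing. Two-group comparisons use the same test (with 1 df it is
#' equivalent to a rank-sum test).
#'
#' @param values Numeric expression vector.
#' @param groups Group labels, same length.
#' @param exact_max_n Largest total n for which the exact permutation
#'   p-value is enumerated (default 8).
#' @return An `association_result` list: `statistic` (H), `df`,
#'   `p_value`, `p_exact` (or `NA`), `groups` (per-group n),
#'   `direction` (group with the highest median), `method`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups, exact_max_n = 8) {
  keep <- !is.na(values) & !is.na(groups) & groups != "unknown"
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2)
    stop("need at least two non-empty groups after dropping unknowns", call. = FALSE)
  n <- length(values)
  k <- nlevels(groups)
  if (stats::sd(values) == 0) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  p_exact <- NA_real_
  if (n <= exact_max_n && stats::sd(values) > 0) {
    h_obs <- .kw_statistic(values, groups)
    perms <- .all_label_permutations(as.integer(groups))
    h_all <- apply(perms, 2, function(g) .kw_statistic(values, g))
    p_exact <- mean(h_all >= h_obs - 1e-12)
  }
  med <- tapply(values, groups, stats::median)
  structure(list(statistic = h, df = k - 1, p_value = p, p_exact = p_exact,
                 groups = table(groups), direction = names(which.max(med)),
                 method = "Kruskal-Wallis"),
            class = "association_result")
}

# All distinct assignments of the multiset of group labels to positions,
# as an integer matrix (one column per assignment). Exponential; callers
# gate on small n.
.all_label_permutations <- function(g) {
  n <- length(g)
  slots <- list(seq_len(n))
  labs <- sort(unique(g))
  counts <- tabulate(g)
  assign_rec <- function(remaining, lab_idx) {
    if (lab_idx > length(labs)) return(matrix(integer(0), nrow = 0, ncol = 1))
    lab <- labs[lab_idx]
    m <- counts[lab]
    picks <- utils::combn(remaining, m, simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- setdiff(remaining, p)
      if (lab_idx == length(labs)) {
        v <- integer(n); v[p] <- lab
        out[[length(out) + 1L]] <- matrix(v, ncol = 1)
      } else {
        sub <- assign_rec(rest, lab_idx + 1L)
        sub[p, ] <- lab
        out[[length(out) + 1L]] <- sub
      }
    }
    do.call(cbind, out)
  }
  assign_rec(seq_len(n), 1L)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g", x$method,
              x$statistic, if (is.null(x$df)) "-" else x$df, x$p_value))
  if (!is.null(x$p_exact) && !is.na(x$p_exact))
    cat(sprintf(" (exact permutation p = %.3g)", x$p_exact))
  if (!is.null(x$direction)) cat(sprintf("; highest median: %s", x$direction))
  cat("\n")
  invisible(x)
}

#' Significance of a Pearson correlation via the t transform
#'
#' Converts a correlation to `t = r / sqrt((1 - r^2) / (n - 2))`,
#' distributed approximately as Student's t with n-2 degrees of
#' freedom, and returns the two-sided p-value.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n Sample count, >= 3.
#' @return List with `t`, `p_value`, `df` and `limit` (`TRUE` when
#'   |r| = 1 and the p-value is the degenerate limit 0).
#' @examples
#' correlation_significance(0.289, 88)   # p ~ 6.3e-3
#' correlation_significance(0.225, 649)  # p ~ 6.8e-9
#' @export
correlation_significance <- function(r, n) {
  if (n < 3) stop("`n` must be at least 3", call. = FALSE)
  if (!is.finite(r) || abs(r) > 1) stop("`r` must be in [-1, 1]", call. = FALSE)
  df <- n - 2
  if (abs(r) == 1)
    return(list(t = sign(r) * Inf, p_value = 0, df = df, limit = TRUE))
  t <- r / sqrt((1 - r^2) / df)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p_value = p, df = df, limit = FALSE)
}

#' Pearson correlation of two 2log expression vectors
#'
#' Standard product-moment correlation of values already on the 2log
#' scale (no re-transform), with significance via
#' [correlation_significance()].
#'
#' @param x,y Numeric vectors of equal length >= 3, 2log scale.
#' @return A `correlation_result` list: `r`, `n`, `t`, `p_value`, `df`.
#' @export
pearson_log2 <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in an input vector", call. = FALSE)
  r <- stats::cor(x, y)
  sig <- correlation_significance(r, length(x))
  structure(list(r = r, n = length(x), t = sig$t, p_value = sig$p_value,
                 df = sig$df, method = "2log Pearson"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.3f (n = %d), t = %.3f (df = %d), two-sided p = %.3g\n",
              x$method, x$r, x$n, x$t, x$df, x$p_value))
  invisible(x)
}

#' Dual-gene table ranked by one gene's expression
#'
#' Produces the plotting data for a ranked dual-gene panel: one row per
#' sample, ordered by ascending expression of the ranking gene (ties
#' broken by sample id), carrying both genes' 2log values and all
#' clinical annotations.
#'
#' @param cohort A [cohort_matrix()].
#' @param gene_rank Gene whose expression defines the row order.
#' @param gene_other The second gene carried along.
#' @return Data frame with columns `rank`, `sample`, the two gene
#'   columns, and the annotation columns.
#' @export
ranked_dual_gene_export <- function(cohort, gene_rank, gene_other) {
  gn <- cohort_genes(cohort)
  for (g in c(gene_rank, gene_other))
    if (!g %in% gn) stop(sprintf("gene '%s' not in cohort", g), call. = FALSE)
  ids <- rownames(cohort$expression)
  o <- order(cohort$expression[, gene_rank], ids)
  out <- data.frame(rank = seq_along(o), sample = ids[o],
                    stringsAsFactors = FALSE)
  out[[gene_rank]] <- cohort$expression[o, gene_rank]
  out[[gene_other]] <- cohort$expression[o, gene_other]
  ann <- cohort$annotations[o, setdiff(names(cohort$annotations), "sample"),
                            drop = FALSE]
  rownames(ann) <- NULL
  cbind(out, ann)
}

#' One-tailed paired t-test for viability reduction
#'
#' Paired t-test on per-experiment mean viabilities, one-tailed in the
#' direction control > treated (a viability reduction under
#' treatment). Pairs with identical values throughout (all differences
#' zero) give t = 0, p = 0.5; non-zero constant differences have no
#' estimable variance and are an error.
#'
#' @param treated,control Equal-length paired numeric vectors (n >= 2).
#' @return An `association_result` with `statistic` (t), `df`,
#'   `p_value` (one-tailed).
#' @export
paired_onetailed_t <- function(treated, control) {
  if (length(treated) != length(control))
    stop("`treated` and `control` must be paired (equal length)", call. = FALSE)
  n <- length(treated)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- control - treated
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(statistic = 0, df = n - 1, p_value = 0.5,
                            p_exact = NA_real_, groups = NULL,
                            direction = "none",
                            method = "paired t (one-tailed)"),
                       class = "association_result"))
    }
    stop("differences are constant and non-zero: variance is not estimable",
         call. = FALSE)
  }
  tt <- stats::t.test(control, treated, paired = TRUE, alternative = "greater")
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, p_exact = NA_real_, groups = NULL,
                 direction = if (mean(d) > 0) "control > treated" else "treated >= control",
                 method = "paired t (one-tailed)"),
            class = "association_result")
}
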