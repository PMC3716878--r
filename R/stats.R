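#' One-sample t-test against a reference value
#'
#' Thin tidy wrapper around [stats::t.test()] used for testing individual
#' bias and offset parameters against zero.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param mu0 Reference value; default 0.
#' @return A one-row tibble: `estimate` (mean), `statistic` (t), `df`,
#'   `p_value` (two-sided).
#' @examples
#' one_sample_t(c(1, 2, 3))
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("one_sample_t(): need at least 2 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("one_sample_t(): zero variance, test undefined", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Pearson correlation with its t-based test
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, both non-constant.
#' @return A one-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p_value` (two-sided).
#' @examples
#' pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("pearson_corr(): need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_corr(): zero variance in a vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Mixed-design (split-plot) ANOVA
#'
#' Univariate mixed-model ANOVA with one between-participant factor
#' (optional) and any number of within-participant factors, the workhorse
#' inferential design of the analysis (e.g. 2 group x 2 judgment type on
#' bias parameters; 2 x 3 x 12 on intra-individual SDs; 2 x 2 x 2 x 2 on
#' sequential subset biases). Fitting goes through [stats::aov()] with the
#' standard `Error(participant / (within factors))` strata; F ratios are
#' the uncorrected univariate ones by default. Setting `gg = TRUE` applies
#' the Greenhouse-Geisser sphericity correction to the degrees of freedom
#' of within-participant effects.
#'
#' The design must be complete and balanced: exactly one value per
#' participant and within-cell, and each participant in a single group.
#'
#' @param data A data frame in long format.
#' @param dv Name of the numeric response column.
#' @param participant Name of the participant identifier column.
#' @param between Name of the between-participant factor column, or `NULL`.
#' @param within Character vector of within-participant factor columns.
#' @param gg Apply the Greenhouse-Geisser correction? Default `FALSE`.
#' @return An object of class `vp_anova`; its `tidy()` method returns the
#'   effect table (`effect`, `df_num`, `df_den`, `statistic`, `p_value`,
#'   and `epsilon` when `gg = TRUE`).
#' @examples
#' d <- tidyr::expand_grid(participant = paste0("p", 1:8), kind = c("a", "b"))
#' d$group <- rep(c("g1", "g2"), each = 4)[match(d$participant, unique(d$participant))]
#' d$value <- rnorm(nrow(d))
#' tidy(mixed_anova(d, "value", "participant", "group", "kind"))
#' @export
mixed_anova <- function(data, dv, participant, between = NULL, within,
                        gg = FALSE) {
  stopifnot(is.data.frame(data), length(within) >= 1L)
  d <- as.data.frame(data[, c(dv, participant, between, within)])
  for (v in c(participant, between, within)) d[[v]] <- factor(d[[v]])

  cells <- interaction(d[within], drop = FALSE)
  counts <- table(d[[participant]], cells)
  if (any(counts != 1L)) {
    stop("mixed_anova(): design not balanced; need exactly one value per ",
         "participant and within-cell", call. = FALSE)
  }
  if (!is.null(between)) {
    gpp <- tapply(d[[between]], d[[participant]],
                  function(g) length(unique(g)))
    if (any(gpp != 1L)) {
      stop("mixed_anova(): a participant appears in more than one group",
           call. = FALSE)
    }
  }

  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", participant, "/(",
                paste(within, collapse = " * "), "))")
  f <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(f, data = d)

  tab <- purrr::list_rbind(purrr::imap(summary(fit), function(s, stratum) {
    tt <- as.data.frame(s[[1]])
    terms <- trimws(rownames(tt))
    resid_row <- terms == "Residuals"
    if (!any(resid_row)) return(NULL)
    df_den <- tt$Df[resid_row]
    keep <- !resid_row
    if (!any(keep)) return(NULL)
    tibble::tibble(
      stratum = sub("^Error: ", "", stratum),
      effect = terms[keep],
      df_num = tt$Df[keep],
      df_den = df_den,
      sumsq = tt[["Sum Sq"]][keep],
      statistic = tt[["F value"]][keep],
      p_value = tt[["Pr(>F)"]][keep]
    )
  }))

  if (gg) {
    eps <- gg_epsilons(d, dv, participant, between, within)
    tab$epsilon <- unname(eps[tab$stratum])
    tab$epsilon[is.na(tab$epsilon)] <- 1
    tab$p_value <- stats::pf(tab$statistic, tab$df_num * tab$epsilon,
                             tab$df_den * tab$epsilon, lower.tail = FALSE)
  }

  structure(list(table = tab, dv = dv, between = between, within = within,
                 n_participants = nlevels(d[[participant]]), gg = gg),
            class = "vp_anova")
}

# Greenhouse-Geisser epsilon per within-effect stratum. For each nonempty
# subset W of within factors (a stratum participant:W), the participant x
# cell matrix of means over the other within factors is reduced to its
# group-centered covariance; epsilon = tr(M)^2 / ((k-1) * tr(M^2)) with
# M = C S C' for orthonormal contrasts C.
gg_epsilons <- function(d, dv, participant, between, within) {
  subsets <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)
  eps <- c()
  for (W in subsets) {
    cell <- interaction(d[W], drop = FALSE)
    agg <- stats::aggregate(d[[dv]], list(p = d[[participant]], cell = cell),
                            mean)
    wide <- tapply(agg$x, list(agg$p, agg$cell), mean)
    k <- ncol(wide)
    if (k < 2L) next
    if (!is.null(between)) {
      grp <- tapply(as.character(d[[between]]), d[[participant]],
                    function(g) g[1])[rownames(wide)]
      centered <- do.call(rbind, lapply(split(as.data.frame(wide), grp),
                                        function(m) scale(m, scale = FALSE)))
    } else {
      centered <- scale(wide, scale = FALSE)
    }
    S <- crossprod(as.matrix(centered)) / (nrow(centered) - 1)
    C <- stats::contr.helmert(k)
    C <- t(qr.Q(qr(C)))
    M <- C %*% S %*% t(C)
    e <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
    nm <- paste0(participant, ":", paste(W, collapse = ":"))
    eps[nm] <- e
  }
  eps
}

#' @export
print.vp_anova <- function(x, ...) {
  cat("<vp_anova>", x$dv, "~",
      paste(c(x$between, x$within), collapse = " * "),
      sprintf("(n = %d%s)\n", x$n_participants,
              if (x$gg) ", Greenhouse-Geisser" else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.vp_anova <- function(x, ...) x$table

#' @export
glance.vp_anova <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    n_effects = nrow(x$table),
    gg_corrected = x$gg
  )
}

#' Bonferroni-corrected pairwise t-tests
#'
#' Post-hoc comparisons between design cells: every pair of cells is
#' compared with a t-test (paired within participants when a participant
#' column is supplied, two-sample otherwise) and the raw p-values are
#' multiplied by the number of comparisons, capped at 1.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param cell Name of the cell (condition) column.
#' @param participant Optional participant column for paired comparisons.
#' @param alpha Significance level after correction; default 0.05.
#' @return A tibble with one row per pair: `cell_a`, `cell_b`, `statistic`,
#'   `df`, `p_value` (raw), `p_adjusted`, `significant`.
#' @export
bonferroni_pairwise <- function(data, dv, cell, participant = NULL,
                                alpha = 0.05) {
  cells <- unique(as.character(data[[cell]]))
  if (length(cells) < 2L) {
    stop("bonferroni_pairwise(): need at least 2 cells", call. = FALSE)
  }
  prs <- utils::combn(cells, 2, simplify = FALSE)
  res <- purrr::list_rbind(purrr::map(prs, function(pr) {
    a <- data[data[[cell]] == pr[1], ]
    b <- data[data[[cell]] == pr[2], ]
    if (!is.null(participant)) {
      ids <- intersect(a[[participant]], b[[participant]])
      x <- a[[dv]][match(ids, a[[participant]])]
      y <- b[[dv]][match(ids, b[[participant]])]
      if (stats::sd(x - y) == 0) {
        stop("bonferroni_pairwise(): zero variance of paired differences",
             call. = FALSE)
      }
      tt <- stats::t.test(x, y, paired = TRUE)
    } else {
      tt <- stats::t.test(a[[dv]], b[[dv]])
    }
    tibble::tibble(cell_a = pr[1], cell_b = pr[2],
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res$significant <- res$p_adjusted < alpha
  res
}
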