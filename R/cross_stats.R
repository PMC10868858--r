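# Hatch-rate statistics: binomial GLM likelihood-ratio tests, Spearman
# association, Levene (Brown-Forsythe) variance comparison.

#' Construct a statistic result
#'
#' @param name statistic name.
#' @param value statistic value.
#' @param df degrees of freedom (may be `NA` or length 2).
#' @param p p-value in `[0, 1]`.
#' @param n number of observations used.
#' @param flags character vector of caveats (e.g. `"separation"`).
#' @return An object of class `cid_stat`.
#' @export
cid_stat <- function(name, value, df = NA_real_, p = NA_real_, n = NA_integer_,
                     flags = character(0)) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p-value outside [0, 1]")
  structure(list(name = name, value = value, df = df, p = p, n = n,
                 flags = flags),
            class = "cid_stat")
}

#' @export
print.cid_stat <- function(x, ...) {
  cat(sprintf("<cid_stat> %s = %.4g%s, p = %.4g, n = %d%s\n", x$name, x$value,
              if (all(is.na(x$df))) "" else
                sprintf(" (df %s)", paste(x$df, collapse = ", ")),
              x$p, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Hatching rate of an egg raft
#'
#' @param eggs eggs laid (vectorized).
#' @param larvae larvae hatched, `0 <= larvae <= eggs`.
#' @return `larvae / eggs`; `NA` where `eggs == 0` (unfertilized
#'   sentinel, excluded from downstream analyses).
#' @export
hatching_rate <- function(eggs, larvae) {
  if (any(larvae < 0 | larvae > eggs)) stop("need 0 <= larvae <= eggs")
  ifelse(eggs > 0, larvae / eggs, NA_real_)
}

#' Likelihood-ratio test for a presence effect on hatch rates
#'
#' Fits a binomial GLM of per-raft success counts (`larvae` of `eggs`)
#' on a presence indicator and compares with the null model by a
#' likelihood-ratio test (chi-square, 1 df).  Raft sizes enter through
#' the binomial denominator, so rafts are weighted by their egg counts.
#' Overdispersion is deliberately not modelled here (plain binomial GLM).
#'
#' @param records data.frame with `eggs` and `larvae` columns;
#'   unfertilized rows (`fertilized == FALSE` or `NA` hatch data) are
#'   excluded.
#' @param indicator logical/factor vector, or the name of a column of
#'   `records`.
#' @param covariates optional character vector of additional model terms
#'   (column names) present in both the null and the full model, e.g. a
#'   replicate factor.
#' @return A `cid_stat` (`"LRT chi-square"`), flagged `"separation"`
#'   when one indicator group has zero hatching overall.
#' @export
lrt_presence_effect <- function(records, indicator, covariates = NULL) {
  if (is.character(indicator) && length(indicator) == 1)
    indicator <- records[[indicator]]
  keep <- !is.na(records$eggs) & !is.na(records$larvae) & records$eggs > 0
  if ("fertilized" %in% names(records)) keep <- keep & records$fertilized
  d <- data.frame(eggs = records$eggs, larvae = records$larvae)
  if (!is.null(covariates)) d[covariates] <- records[covariates]
  d$ind <- if (is.factor(indicator)) indicator else factor(indicator)
  d <- d[keep, , drop = FALSE]
  if (nlevels(droplevels(d$ind)) < 2) stop("need at least 2 indicator groups")
  base_terms <- if (is.null(covariates)) "1" else paste(covariates, collapse = " + ")
  f0 <- as.formula(paste("cbind(larvae, eggs - larvae) ~", base_terms))
  f1 <- as.formula(paste("cbind(larvae, eggs - larvae) ~ ind +", base_terms))
  m0 <- glm(f0, family = binomial(), data = d)
  m1 <- suppressWarnings(glm(f1, family = binomial(), data = d))
  chi <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  df <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
  grp_hatch <- tapply(d$larvae, droplevels(d$ind), sum)
  flags <- if (any(grp_hatch == 0)) "separation" else character(0)
  cid_stat("LRT chi-square", chi, df = df,
           p = pchisq(chi, df, lower.tail = FALSE), n = nrow(d), flags = flags)
}

#' Spearman rank association of hatch rates with a covariate
#'
#' Mid-rank tie handling, two-sided p (normal approximation, as required
#' with ties).
#'
#' @param hr hatch rates.
#' @param covariate paired covariate (n >= 5 complete pairs).
#' @return A `cid_stat` (`"Spearman rho"`).
#' @export
spearman_assoc <- function(hr, covariate) {
  keep <- !is.na(hr) & !is.na(covariate)
  hr <- hr[keep]; covariate <- covariate[keep]
  if (length(hr) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  ct <- suppressWarnings(cor.test(hr, covariate, method = "spearman",
                                  exact = FALSE))
  cid_stat("Spearman rho", unname(ct$estimate), p = ct$p.value, n = length(hr))
}

#' Levene test for equality of hatch-rate spread across groups
#'
#' Absolute deviations from the group centre (median by default, the
#' robust Brown-Forsythe variant) compared by one-way ANOVA.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 3), or a
#'   numeric vector when `g` is given.
#' @param g optional grouping factor paired with a numeric `groups`
#'   vector.
#' @param center `"median"` (default) or `"mean"`.
#' @return A `cid_stat` (`"Levene F"`, df = c(k-1, n-k)).
#' @export
levene_compare <- function(groups, g = NULL, center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.list(groups)) {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
  } else {
    y <- groups
    g <- factor(g)
  }
  keep <- !is.na(y)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 3)) stop("each group needs at least 3 values")
  lt <- car::leveneTest(y, g, center = if (center == "median") median else mean)
  cid_stat("Levene F", lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
           p = lt[1, "Pr(>F)"], n = length(y))
}
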