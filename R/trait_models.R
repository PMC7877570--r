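#' Covariate retention heuristic with categorical collapsing
#'
#' Screens candidate covariates one at a time against the trait (linear
#' regression for quantitative traits, logistic for binary) and retains
#' `age` and `sex` unconditionally plus every candidate whose univariate
#' association is nominally significant (`P < alpha`; overall LRT for
#' categoricals, Wald for continuous covariates). For a retained categorical,
#' levels whose level-vs-reference contrast has `P >= alpha` are merged into
#' the reference group, reducing the variable to a ternary or binary coding
#' (e.g. education grouped to levels {1,2,3} = 0 vs level 4 = 1 when only the
#' top level differs).
#'
#' @param cohort a [cohort_table()].
#' @param trait trait column name.
#' @param candidates character vector of candidate covariate columns
#'   (default: education, smoking and, when present, bmi).
#' @param alpha retention significance level (default 0.05).
#' @param categorical which candidates are treated as categorical (levels
#'   collapsible); default education and smoking.
#' @return object of class `covariate_spec`: list with the trait, its type,
#'   the always-kept set, and per-covariate coding (`"continuous"` or a
#'   level-to-group mapping).
#' @export
select_covariates <- function(cohort, trait,
                              candidates = intersect(
                                c("education", "smoking", "bmi"), names(cohort)
                              ),
                              alpha = 0.05,
                              categorical = c("education", "smoking")) {
  type <- trait_types(cohort)[[trait]]
  if (is.null(type)) stop("unknown trait: ", trait, call. = FALSE)
  y <- cohort[[trait]]
  if (stats::var(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop("trait ", trait, " is constant", call. = FALSE)
  }
  fam <- if (type == "binary") stats::binomial() else stats::gaussian()
  retained <- list()
  for (cv in setdiff(candidates, c("age", "sex", trait))) {
    x <- cohort[[cv]]
    is_cat <- cv %in% categorical
    if (is_cat && length(unique(stats::na.omit(x))) < 2) {
      warning("covariate ", cv, " has a single observed level; dropped",
              call. = FALSE)
      next
    }
    d <- data.frame(y = y, x = if (is_cat) factor(x) else x)
    d <- d[stats::complete.cases(d), ]
    fit <- stats::glm(y ~ x, data = d, family = fam)
    if (is_cat) {
      fit0 <- stats::glm(y ~ 1, data = d, family = fam)
      p_overall <- if (type == "binary") {
        stats::pchisq(fit0$deviance - fit$deviance,
                      df = fit0$df.residual - fit$df.residual, lower.tail = FALSE)
      } else {
        a <- stats::anova(fit0, fit, test = "F")
        a$`Pr(>F)`[2]
      }
      if (is.na(p_overall) || p_overall >= alpha) next
      cf <- summary(fit)$coefficients
      lev <- levels(d$x)
      groups <- stats::setNames(rep(0L, length(lev)), lev)
      gi <- 0L
      for (l in lev[-1]) {
        pl <- cf[paste0("x", l), 4]
        if (!is.na(pl) && pl < alpha) {
          gi <- gi + 1L
          groups[l] <- gi
        }
      }
      if (all(groups == 0L)) next # overall signal but no single level stands out
      retained[[cv]] <- list(coding = "collapsed", groups = groups)
    } else {
      p <- summary(fit)$coefficients[2, 4]
      if (!is.na(p) && p < alpha) retained[[cv]] <- list(coding = "continuous")
    }
  }
  structure(
    list(trait = trait, type = type, alpha = alpha,
         always = c("age", "sex"), retained = retained),
    class = "covariate_spec"
  )
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("<covariate_spec> trait ", x$trait, " (", x$type, "); always: ",
      paste(x$always, collapse = ", "), "\n", sep = "")
  for (nm in names(x$retained)) {
    r <- x$retained[[nm]]
    if (r$coding == "continuous") {
      cat("  ", nm, ": continuous\n", sep = "")
    } else {
      cat("  ", nm, ": collapsed (",
          paste(sprintf("%s->%d", names(r$groups), r$groups), collapse = ", "),
          ")\n", sep = "")
    }
  }
  invisible(x)
}

# model-frame of the retained covariates, coded per the spec
covariate_frame <- function(cohort, spec) {
  d <- data.frame(age = cohort$age, sex = factor(cohort$sex))
  for (nm in names(spec$retained)) {
    r <- spec$retained[[nm]]
    if (r$coding == "continuous") {
      d[[nm]] <- cohort[[nm]]
    } else {
      g <- r$groups[as.character(cohort[[nm]])]
      d[[nm]] <- factor(g, levels = sort(unique(r$groups)))
    }
  }
  rownames(d) <- cohort$id
  d
}

#' Residualize and inverse-normal transform a quantitative trait
#'
#' Fits the trait on the retained covariates jointly, takes residuals, and
#' applies the rank-based inverse-normal transform with the Blom offset
#' (`qnorm((rank - 3/8) / (n + 1/4))`). The output preserves the residual
#' ordering and has mean 0 and s.d. close to 1. Individuals missing the trait
#' or any retained covariate get `NA` (complete-case analysis).
#'
#' @param cohort a [cohort_table()].
#' @param spec a `covariate_spec` from [select_covariates()].
#' @return numeric vector aligned with `cohort$id`, attribute `n_used`.
#' @export
transform_quantitative <- function(cohort, spec) {
  y <- cohort[[spec$trait]]
  d <- covariate_frame(cohort, spec)
  d$y <- y
  cc <- stats::complete.cases(d)
  X <- stats::model.matrix(~., data = d[cc, setdiff(names(d), "y"), drop = FALSE])
  if (sum(cc) <= ncol(X)) {
    stop("fewer observations than model parameters", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y[cc])
  r <- fit$residuals
  z <- stats::qnorm((rank(r, ties.method = "average") - 3 / 8) /
                      (length(r) + 1 / 4))
  out <- rep(NA_real_, nrow(cohort))
  out[cc] <- z
  attr(out, "n_used") <- sum(cc)
  out
}

#' Joint global-ancestry association with a baseline ancestry
#'
#' Regresses the (transformed) trait on the global proportions of all
#' ancestries except the baseline (default EUR), so coefficients are
#' interpreted per unit ancestry relative to the baseline. Quantitative
#' traits use linear regression on the residual-transformed trait (covariates
#' already removed); binary traits keep the retained covariates in a joint
#' logistic model, optionally adding BMI. P-values are Wald tests.
#'
#' @param y outcome: transformed trait vector (quantitative) or 0/1 vector
#'   (binary), aligned with `ga$id`.
#' @param ga tibble of global proportions (`id` + one column per ancestry).
#' @param spec a `covariate_spec` (used for binary traits; may be `NULL` for
#'   quantitative).
#' @param cohort the [cohort_table()] (needed for binary-trait covariates and
#'   BMI adjustment).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param baseline ancestry omitted from the regressors; `NULL` raises a
#'   collinearity error (the K proportions sum to 1).
#' @param adjust_bmi add BMI as a covariate (binary traits; per the usual
#'   adiposity-adjusted disease models).
#' @return tibble of class `ancestry_effects`: one row per non-baseline
#'   ancestry with `beta`, `se`, `p`; attributes `model`, `baseline`, `n`.
#' @export
fit_global_ancestry_model <- function(y, ga, spec = NULL, cohort = NULL,
                                      trait_type = c("quantitative", "binary"),
                                      baseline = "EUR", adjust_bmi = FALSE) {
  trait_type <- match.arg(trait_type)
  anc_cols <- setdiff(names(ga), "id")
  if (is.null(baseline)) {
    stop("ancestry proportions sum to 1: drop one ancestry as baseline ",
         "(set `baseline`)", call. = FALSE)
  }
  use <- setdiff(anc_cols, baseline)
  d <- as.data.frame(ga[, use])
  d$.y <- y
  if (trait_type == "binary") {
    if (!is.null(spec) && !is.null(cohort)) {
      d <- cbind(d, covariate_frame(cohort, spec))
    }
    if (adjust_bmi) {
      if (is.null(cohort) || !"bmi" %in% names(cohort)) {
        stop("adjust_bmi requires a cohort with a bmi column", call. = FALSE)
      }
      d$bmi <- cohort$bmi
    }
  }
  cc <- stats::complete.cases(d)
  d <- d[cc, ]
  if (trait_type == "quantitative") {
    fit <- stats::lm(.y ~ ., data = d)
    cf <- summary(fit)$coefficients
  } else {
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = d, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          stop("separation in logistic fit", call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }
    )
    cf <- summary(fit)$coefficients
  }
  if (any(is.na(stats::coef(fit)[use]))) {
    stop("collinear ancestry regressors: use K-1 proportions with a baseline",
         call. = FALSE)
  }
  out <- tibble::tibble(
    ancestry = use,
    beta = unname(cf[use, 1]), se = unname(cf[use, 2]), p = unname(cf[use, 4])
  )
  structure(out,
    model = paste0(
      if (trait_type == "quantitative") "linear" else "logistic",
      if (adjust_bmi) "+bmi" else ""
    ),
    baseline = baseline, n = nrow(d), fit = fit,
    class = c("ancestry_effects", class(out))
  )
}

#' Effect per 10% increase in ancestry
#'
#' Rescales a per-unit-ancestry coefficient to the conventional
#' per-10%-ancestry report: `0.1 * beta` (trait s.d.) for quantitative
#' traits; for binary traits the odds ratio `exp(0.1 * beta)` and the percent
#' change in odds `100 * (exp(0.1 * beta) - 1)`.
#'
#' @param beta coefficient per unit ancestry (trait-s.d. units or log-odds).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return one-row tibble: `per10_sd` for quantitative; `or_per10` and
#'   `pct_odds_per10` for binary.
#' @export
per_10pct_effect <- function(beta, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.finite(beta))
  if (trait_type == "quantitative") {
    tibble::tibble(per10_sd = 0.1 * beta)
  } else {
    or <- exp(0.1 * beta)
    tibble::tibble(or_per10 = or, pct_odds_per10 = 100 * (or - 1))
  }
}

#' Global-ancestry model with neighborhood-SES and census-tract clustering
#'
#' Adds the nSES quintile as a fixed effect and the census tract as a random
#' intercept, since all individuals of a tract share the same nSES value
#' (spatial clustering). Quantitative traits use `lme4::lmer` on the
#' transformed trait; binary traits use `lme4::glmer` with the retained
#' covariates. With a single cluster the model falls back to fixed effects
#' with a warning. Wald (normal-approximation) P-values are reported.
#'
#' @inheritParams fit_global_ancestry_model
#' @param nses nSES quintile vector aligned with `ga$id` (default taken from
#'   `cohort`).
#' @param cluster census-tract labels (default from `cohort`).
#' @return `ancestry_effects` tibble; attribute `ranef_sd` holds the
#'   estimated random-intercept s.d. (`NA` under the fixed-effects fallback).
#' @export
fit_nses_mixed_model <- function(y, ga, spec = NULL, cohort,
                                 trait_type = c("quantitative", "binary"),
                                 nses = cohort$nses,
                                 cluster = cohort$census_tract,
                                 baseline = "EUR", adjust_bmi = FALSE) {
  trait_type <- match.arg(trait_type)
  use <- setdiff(setdiff(names(ga), "id"), baseline)
  d <- as.data.frame(ga[, use])
  d$.y <- y
  d$nses <- nses
  d$.cluster <- cluster
  if (trait_type == "binary" && !is.null(spec)) {
    d <- cbind(d, covariate_frame(cohort, spec))
  }
  if (adjust_bmi) d$bmi <- cohort$bmi
  d <- d[stats::complete.cases(d), ]
  fixed <- paste(setdiff(names(d), c(".y", ".cluster")), collapse = " + ")
  if (length(unique(d$.cluster)) < 2) {
    warning("single cluster: falling back to fixed-effects model", call. = FALSE)
    eff <- fit_global_ancestry_model(
      d$.y, dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(d))), d[, use]),
      trait_type = trait_type, baseline = baseline
    )
    attr(eff, "ranef_sd") <- NA_real_
    return(eff)
  }
  f <- stats::as.formula(paste0(".y ~ ", fixed, " + (1 | .cluster)"))
  if (trait_type == "quantitative") {
    fit <- lme4::lmer(f, data = d, REML = TRUE)
  } else {
    fit <- lme4::glmer(f, data = d, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
  }
  cf <- as.data.frame(summary(fit)$coefficients)
  z <- cf[use, "Estimate"] / cf[use, "Std. Error"]
  out <- tibble::tibble(
    ancestry = use, beta = unname(cf[use, "Estimate"]),
    se = unname(cf[use, "Std. Error"]),
    p = unname(2 * stats::pnorm(-abs(z)))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(out,
    model = paste0(trait_type, "+nses_mixed"),
    baseline = baseline, n = nrow(d), fit = fit,
    ranef_sd = vc$sdcor[vc$grp == ".cluster"][1],
    class = c("ancestry_effects", class(out))
  )
}

#' Stratified and interaction analysis of ancestry effects
#'
#' Fits the global-ancestry model separately within the two levels of a
#' binary stratifier (e.g. disease status), and a pooled model with
#' ancestry-by-stratifier product terms, reporting the interaction
#' coefficients and Wald P-values. A stratum with fewer observations than
#' model parameters yields `NA` effects.
#'
#' @inheritParams fit_global_ancestry_model
#' @param stratifier 0/1 vector aligned with `ga$id`.
#' @return list with `strata` (named list of `ancestry_effects`, names
#'   `"0"`/`"1"`) and `interaction` (tibble of ancestry-x-stratifier terms).
#' @export
stratified_and_interaction <- function(y, ga, stratifier,
                                       trait_type = c("quantitative", "binary"),
                                       baseline = "EUR") {
  trait_type <- match.arg(trait_type)
  if (length(unique(stats::na.omit(stratifier))) != 2) {
    stop("stratifier must have two non-empty levels", call. = FALSE)
  }
  use <- setdiff(setdiff(names(ga), "id"), baseline)
  strata <- list()
  for (s in c(0, 1)) {
    i <- which(stratifier == s)
    d <- as.data.frame(ga[i, use])
    d$.y <- y[i]
    d <- d[stats::complete.cases(d), ]
    if (nrow(d) <= length(use) + 1) {
      strata[[as.character(s)]] <- structure(
        tibble::tibble(ancestry = use, beta = NA_real_, se = NA_real_,
                       p = NA_real_),
        class = c("ancestry_effects", "tbl_df", "tbl", "data.frame")
      )
    } else {
      strata[[as.character(s)]] <- fit_global_ancestry_model(
        d$.y, dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(d))), d[, use]),
        trait_type = trait_type, baseline = baseline
      )
    }
  }
  d <- as.data.frame(ga[, use])
  d$.y <- y
  d$.s <- stratifier
  d <- d[stats::complete.cases(d), ]
  f <- stats::as.formula(paste0(
    ".y ~ .s + ", paste(use, collapse = " + "), " + ",
    paste(paste0(use, ":.s"), collapse = " + ")
  ))
  fit <- if (trait_type == "quantitative") {
    stats::lm(f, data = d)
  } else {
    stats::glm(f, data = d, family = stats::binomial())
  }
  cf <- summary(fit)$coefficients
  iterm <- ifelse(paste0(use, ":.s") %in% rownames(cf),
                  paste0(use, ":.s"), paste0(".s:", use))
  found <- iterm %in% rownames(cf)
  interaction <- tibble::tibble(
    term = use[found],
    beta = unname(cf[iterm[found], 1]),
    se = unname(cf[iterm[found], 2]),
    p = unname(cf[iterm[found], 4])
  )
  list(strata = strata, interaction = interaction, fit = fit)
}

#' Obesity labels from BMI
#'
#' Polynesian-ancestry cohorts use a BMI cutoff of 32 kg/m^2 to define
#' obesity (higher lean-to-fat mass at a given BMI than in European-ancestry
#' populations).
#'
#' @param bmi numeric BMI in kg/m^2.
#' @param cutoff kg/m^2 threshold, default 32.
#' @return integer 0/1 vector (1 = obese); `NA` preserved.
#' @export
label_obesity <- function(bmi, cutoff = 32) {
  as.integer(bmi >= cutoff)
}

#' Flag significance under the 14-trait Bonferroni budget
#'
#' Reporting helper for trait-panel summaries where 14 traits are tested.
#'
#' @param p P-value(s).
#' @param n_traits number of traits in the panel (default 14).
#' @return logical vector, `TRUE` when `p < 0.05 / n_traits`.
#' @export
significant_14traits <- function(p, n_traits = 14) {
  p < 0.05 / n_traits
}
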