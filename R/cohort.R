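# Cohort-level statistics of mutation incidence: group means, pooled
# t-tests, age-adjusted logistic and multinomial models, and Poisson age
# trends.

#' Per-group mean and range of a mutation category
#'
#' @param table Cohort table with `group` and the category column.
#' @param category Column name (e.g. `"dloop"`, `"pathogenic_nonsyn"`).
#' @return Data frame (`group`, `n`, `mean`, `min`, `max`).
#' @export
group_means <- function(table, category) {
  if (!category %in% names(table))
    stop(sprintf("no category '%s' in table", category), call. = FALSE)
  groups <- unique(table$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[category]][table$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-group homoscedastic t-test on a mutation category
#'
#' Pooled-variance (Student) two-tailed t-test comparing a category count
#' between two sets of groups (each may pool several group labels).
#'
#' @param table Cohort table.
#' @param category Category column name.
#' @param groups_a,groups_b Character vectors of group labels to pool.
#' @return List `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_group_ttest <- function(table, category, groups_a, groups_b) {
  xa <- table[[category]][table$group %in% groups_a]
  xb <- table[[category]][table$group %in% groups_b]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("both groups need n >= 2", call. = FALSE)
  pooled_var <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
    (length(xa) + length(xb) - 2L)
  if (pooled_var == 0) {
    if (mean(xa) == mean(xb))
      return(list(t = 0, df = length(xa) + length(xb) - 2L, p = 1,
                  mean_a = mean(xa), mean_b = mean(xb)))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(xa, xb, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(xa), mean_b = mean(xb))
}

#' Age-adjusted logistic regression of case status on mutation burden
#'
#' Fits `case ~ count + age` by maximum likelihood and reports the Wald
#' odds ratio per unit count with its two-tailed p-value.
#'
#' @param table Cohort table.
#' @param category Category column name.
#' @param case_groups,control_groups Group labels defining the outcome.
#' @return List `or`, `beta`, `se`, `p`, `separation`.
#' @export
logistic_age_adjusted <- function(table, category, case_groups,
                                  control_groups) {
  d <- table[table$group %in% c(case_groups, control_groups), , drop = FALSE]
  d$case <- as.integer(d$group %in% case_groups)
  if (all(d$case == 1L) || all(d$case == 0L))
    stop("both outcomes must be present", call. = FALSE)
  d$count <- d[[category]]
  fit <- suppressWarnings(stats::glm(case ~ count + age, data = d,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  sep <- !fit$converged || co["count", "Std. Error"] > 50
  if (sep)
    return(list(or = NA_real_, beta = NA_real_, se = NA_real_,
                p = NA_real_, separation = TRUE))
  list(or = exp(co["count", "Estimate"]), beta = co["count", "Estimate"],
       se = co["count", "Std. Error"], p = co["count", "Pr(>|z|)"],
       separation = FALSE)
}

#' Age-adjusted multinomial logistic regression across disease stages
#'
#' Fits a multinomial logit of stage (reference = pooled controls) on
#' mutation burden and age, returning one Wald odds ratio and p-value per
#' stage.
#'
#' @param table Cohort table.
#' @param category Category column name.
#' @param stage_groups Character vector of stage labels (each its own
#'   outcome level).
#' @param control_groups Labels pooled into the reference level.
#' @return Data frame (`stage`, `or`, `beta`, `se`, `p`).
#' @export
multinomial_age_adjusted <- function(table, category, stage_groups,
                                     control_groups) {
  d <- table[table$group %in% c(stage_groups, control_groups), , drop = FALSE]
  d$outcome <- ifelse(d$group %in% stage_groups, d$group, "control_ref")
  d$outcome <- stats::relevel(factor(d$outcome), ref = "control_ref")
  d$count <- d[[category]]
  fit <- nnet::multinom(outcome ~ count + age, data = d, trace = FALSE)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(stage_groups[1],
                                                     names(cf)))
  vc <- stats::vcov(fit)
  out <- do.call(rbind, lapply(rownames(cf), function(st) {
    beta <- cf[st, "count"]
    se <- sqrt(vc[paste0(st, ":count"), paste0(st, ":count")])
    z <- beta / se
    data.frame(stage = st, or = exp(beta), beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Poisson age trend of mutation incidence
#'
#' Log-linear Poisson regression of a category count on age
#' (`count ~ age`), returning the slope per year of age with its standard
#' error and two-tailed Wald p-value.
#'
#' @param table Cohort table.
#' @param category Category column name.
#' @param groups Optional group labels to restrict to.
#' @return List `beta`, `se`, `p`, `n`, `degenerate`.
#' @export
poisson_age_trend <- function(table, category, groups = NULL) {
  d <- if (is.null(groups)) table else
    table[table$group %in% groups, , drop = FALSE]
  if (nrow(d) < 3L) stop("need n >= 3", call. = FALSE)
  d$count <- d[[category]]
  if (all(d$count == 0))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n = nrow(d), degenerate = TRUE))
  fit <- stats::glm(count ~ age, data = d, family = stats::poisson())
  co <- summary(fit)$coefficients
  list(beta = co["age", "Estimate"], se = co["age", "Std. Error"],
       p = co["age", "Pr(>|z|)"], n = nrow(d), degenerate = FALSE)
}

#' Incidence report across categories and groups
#'
#' Produces the two standard cohort reports: per-group mean (range) of each
#' category with a pooled t-test comparing case and control group sets, and
#' per-group-set Poisson age trends.
#'
#' @param table Cohort table.
#' @param categories Category columns to report.
#' @param control_groups,case_groups Group label sets for the t-test
#'   contrast.
#' @param trend_groups Named list of group-label sets for the age-trend
#'   report.
#' @return List of data frames `means` and `age_trends`.
#' @export
cohort_report <- function(table,
                          categories = c("all", "dloop", "coding",
                                         "pathogenic_nonsyn"),
                          control_groups = "control",
                          case_groups = c("premanifest", "early_stage"),
                          trend_groups = list(
                            controls = "control",
                            cases = c("premanifest", "early_stage"))) {
  means <- do.call(rbind, lapply(categories, function(cat) {
    gm <- group_means(table, cat)
    gm$category <- cat
    p <- tryCatch(two_group_ttest(table, cat, case_groups,
                                  control_groups)$p, error = function(e) NA)
    gm$t_test_p <- p
    gm
  }))
  trends <- do.call(rbind, lapply(categories, function(cat) {
    do.call(rbind, lapply(names(trend_groups), function(gn) {
      tr <- tryCatch(poisson_age_trend(table, cat, trend_groups[[gn]]),
                     error = function(e) list(beta = NA, se = NA, p = NA,
                                              n = NA, degenerate = TRUE))
      data.frame(category = cat, groups = gn, beta = tr$beta, se = tr$se,
                 p = tr$p, n = tr$n, stringsAsFactors = FALSE)
    }))
  }))
  list(means = means, age_trends = trends)
}
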