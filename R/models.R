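# -- Satterthwaite machinery for lme4 LMMs ----------------------------------
#
# Degrees of freedom for a 1-df fixed-effect test: df = 2 f^2 / (g' A g),
# where f = Var(beta_j) as a function of the variance parameters
# (theta, sigma), g its gradient there, and A = 2 H^{-1} the asymptotic
# covariance of the variance-parameter estimates (H = Hessian of the REML
# deviance). The REML deviance as a function of (theta, sigma) is rebuilt
# from lme4's profiled deviance function.

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- x; e[i] <- x[i] + h; fp <- f(e)
    e[i] <- x[i] - h; fm <- f(e)
    (fp - fm) / (2 * h)
  }, 0.0)
}

satterthwaite_table <- function(fit, devfun) {
  ee <- environment(devfun)
  vp_hat <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  k <- length(vp_hat)
  devfun_vp <- function(vp) {
    s2 <- vp[k]^2
    devfun(vp[-k])
    n <- nrow(ee$pp$V); p <- ncol(ee$pp$X)
    pwrss <- ee$resp$wrss() + ee$pp$sqrL(1)
    ee$pp$ldL2() + pwrss / s2 + (n - p) * log(2 * pi * s2) + ee$pp$ldRX2()
  }
  vcov_vp <- function(vp) {
    devfun(vp[-k])
    vp[k]^2 * as.matrix(ee$pp$unsc())
  }
  beta <- lme4::fixef(fit)
  n <- nrow(ee$pp$V); p <- length(beta)
  df <- se <- rep(NA_real_, p)
  fallback <- FALSE
  A <- tryCatch(2 * solve(stats::optimHess(vp_hat, devfun_vp)),
                error = function(e) NULL)
  V <- vcov_vp(vp_hat)
  for (j in seq_len(p)) {
    se[j] <- sqrt(V[j, j])
    if (!is.null(A)) {
      g <- num_grad(function(vp) vcov_vp(vp)[j, j], vp_hat)
      denom <- drop(t(g) %*% A %*% g)
      df[j] <- if (denom > 0) 2 * V[j, j]^2 / denom else NA_real_
    }
    if (is.na(df[j]) || df[j] <= 0) { df[j] <- n - p; fallback <- TRUE }
  }
  tval <- beta / se
  list(table = data.frame(term = names(beta), estimate = unname(beta),
                          se = se, statistic = tval, df = df,
                          p = 2 * stats::pt(-abs(tval), df),
                          stringsAsFactors = FALSE),
       fallback = fallback)
}

# -- ModelFit container ------------------------------------------------------

herd_fit <- function(name, fit, coefficients, random, n, family, link,
                     messages = character()) {
  structure(list(name = name, fit = fit, coefficients = coefficients,
                 random = random, n = n, family = family, link = link,
                 messages = messages), class = "herd_fit")
}

#' @export
print.herd_fit <- function(x, ...) {
  cat("<herd_fit> ", x$name, " (", x$family, ", ", x$link, " link), n = ",
      x$n, "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.null(x$random) && nrow(x$random)) {
    cat("random effects:\n")
    print(x$random, row.names = FALSE, digits = 4)
  }
  if (length(x$messages)) cat("notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

collect_messages <- function(expr) {
  msgs <- character()
  res <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(result = res, messages = msgs)
}

ranef_variances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2), c("grp", "vcov", "sdcor")]
  names(vc) <- c("group", "variance", "sd")
  rownames(vc) <- NULL
  vc
}

# -- (i) beta GLM: foraging ~ sex + rank ------------------------------------

#' Beta regression of foraging proportion on sex and dominance rank
#'
#' Tests whether sex and ordinal dominance rank predict the proportion of
#' scans an individual spends foraging, using a beta-family GLM with logit
#' link. Rank enters as a numeric covariate (1 = most dominant), so a
#' positive coefficient means subordinate animals forage more.
#' Single-term-deletion p-values come from likelihood-ratio tests.
#'
#' @param budget per-individual activity budget from [behavior_budget()].
#' @param ranks named integer vector of ordinal dominance ranks.
#' @param compress when the response contains exact 0s or 1s the beta
#'   likelihood is undefined; with `compress = TRUE` the standard compression
#'   `(y (n - 1) + 0.5) / n` is applied, otherwise (default) a boundary value
#'   is an error instructing the flag.
#' @return A `herd_fit` with terms `sexmale` and `rank`.
#' @export
fit_foraging_model <- function(budget, ranks, compress = FALSE) {
  dat <- data.frame(y = budget$foraging,
                    sex = factor(budget$sex, levels = c("female", "male")),
                    rank = as.numeric(ranks[budget$id]))
  if (anyNA(dat$rank)) stop("missing rank for some individuals")
  if (any(dat$y <= 0 | dat$y >= 1)) {
    if (!compress)
      stop("foraging proportions on the boundary of (0,1); rerun with ",
           "compress = TRUE to apply the (y*(n-1) + 0.5)/n transform")
    n <- nrow(dat)
    dat$y <- (dat$y * (n - 1) + 0.5) / n
  }
  cm <- collect_messages({
    full <- mgcv::gam(y ~ sex + rank, family = mgcv::betar(link = "logit"),
                      data = dat, method = "ML")
    no_sex <- mgcv::gam(y ~ rank, family = mgcv::betar(link = "logit"),
                        data = dat, method = "ML")
    no_rank <- mgcv::gam(y ~ sex, family = mgcv::betar(link = "logit"),
                         data = dat, method = "ML")
    list(full = full, no_sex = no_sex, no_rank = no_rank)
  })
  m <- cm$result
  pt <- summary(m$full)$p.table
  lrt <- function(red) {
    stat <- 2 * (as.numeric(stats::logLik(m$full)) - as.numeric(stats::logLik(red)))
    stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  coefs <- data.frame(
    term = rownames(pt), estimate = pt[, 1], se = pt[, 2],
    statistic = pt[, 3], p_wald = pt[, 4],
    p_drop1 = c(NA, lrt(m$no_sex), lrt(m$no_rank)),
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  herd_fit("foraging_beta_glm", m$full, coefs, random = NULL, n = nrow(dat),
           family = "beta", link = "logit", messages = cm$messages)
}

# -- (ii) binomial GLMM: session-level neighbour synchrony -------------------

#' Binomial GLMM of session synchrony by neighbour type
#'
#' Models the number of scans (out of the session's valid scans) in which
#' each neighbour type (NN1, NN2, NN3) matched the focal's behavior, against
#' the random-conspecific reference, with logit link and random intercepts
#' for hour of observation and focal identity. Fit as successes out of
#' trials, i.e. binomial weights equal to the valid-scan count.
#'
#' @param tab session-level table from [session_neighbor_synchrony()].
#' @return A `herd_fit`; the `p_drop1` for the `type` contrasts is the
#'   3-df likelihood-ratio p for deleting the neighbour-type term.
#' @export
fit_neighbor_model <- function(tab) {
  if (length(unique(tab$n_sync / tab$n_valid)) < 2L)
    stop("degenerate response: all proportions identical")
  tab$hour_f <- factor(tab$hour)
  cm <- collect_messages({
    full <- lme4::glmer(cbind(n_sync, n_valid - n_sync) ~ type +
                          (1 | hour_f) + (1 | focal_id),
                        data = tab, family = stats::binomial())
    red <- lme4::glmer(cbind(n_sync, n_valid - n_sync) ~ 1 +
                         (1 | hour_f) + (1 | focal_id),
                       data = tab, family = stats::binomial())
    list(full = full, red = red)
  })
  full <- cm$result$full
  cm2 <- collect_messages(list(
    sm = summary(full)$coefficients,
    p = stats::anova(cm$result$red, full)[2, "Pr(>Chisq)"]))
  msgs <- c(cm$messages, cm2$messages)
  if (lme4::isSingular(full)) msgs <- c(msgs, "singular random-effect fit")
  sm <- cm2$result$sm
  p_lrt <- cm2$result$p
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2], statistic = sm[, 3],
    p_wald = sm[, 4],
    p_drop1 = c(NA, rep(p_lrt, nrow(sm) - 1L)), stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  herd_fit("neighbor_binomial_glmm", full, coefs, ranef_variances(full),
           n = nrow(tab), family = "binomial", link = "logit", messages = msgs)
}

# -- (iii a) binomial GLMM: scan-level focal/NN1 synchrony -------------------

#' Binomial GLMM of scan-level focal-NN1 synchrony
#'
#' Binary response: were the focal and its nearest neighbour synchronized in
#' a scan? Fixed effects are the dyad's sex combination, binary affiliation
#' and absolute rank difference; random intercepts for the neighbour's
#' distance category, both identities, and hour.
#'
#' @param tab scan-level table from [nn_scan_table()].
#' @param terms fixed terms for which single-term-deletion p-values are
#'   computed (default all three); restricting this skips the corresponding
#'   reduced refits, useful in large calibration loops.
#' @return A `herd_fit` with per-term likelihood-ratio deletion p-values
#'   (`NA` for deletions not requested).
#' @export
fit_nn_scan_model <- function(tab, terms = c("sex_combo", "affiliation",
                                             "rank_diff")) {
  terms <- match.arg(terms, several.ok = TRUE)
  if (length(unique(tab$synchronized)) < 2L)
    stop("response has fewer than 2 distinct values")
  tab$sex_combo <- factor(tab$sex_combo, levels = c("different", "same"))
  tab$hour_f <- factor(tab$hour)
  forms <- list(
    full = synchronized ~ sex_combo + affiliation + rank_diff +
      (1 | distance) + (1 | focal_id) + (1 | nn1_id) + (1 | hour_f),
    no_sex = synchronized ~ affiliation + rank_diff +
      (1 | distance) + (1 | focal_id) + (1 | nn1_id) + (1 | hour_f),
    no_aff = synchronized ~ sex_combo + rank_diff +
      (1 | distance) + (1 | focal_id) + (1 | nn1_id) + (1 | hour_f),
    no_rank = synchronized ~ sex_combo + affiliation +
      (1 | distance) + (1 | focal_id) + (1 | nn1_id) + (1 | hour_f))
  wanted <- c("full", c(sex_combo = "no_sex", affiliation = "no_aff",
                        rank_diff = "no_rank")[terms])
  cm <- collect_messages(
    lapply(forms[wanted], function(f)
      lme4::glmer(f, data = tab, family = stats::binomial())))
  fits <- cm$result
  lrt <- function(red) if (is.null(red)) NA_real_ else
    stats::anova(red, fits$full)[2, "Pr(>Chisq)"]
  cm2 <- collect_messages(list(
    sm = summary(fits$full)$coefficients,
    p = c(NA, lrt(fits$no_sex), lrt(fits$no_aff), lrt(fits$no_rank))))
  msgs <- c(cm$messages, cm2$messages)
  if (lme4::isSingular(fits$full)) msgs <- c(msgs, "singular random-effect fit")
  sm <- cm2$result$sm
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2], statistic = sm[, 3],
    p_wald = sm[, 4], p_drop1 = cm2$result$p,
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  herd_fit("nn_scan_binomial_glmm", fits$full, coefs,
           ranef_variances(fits$full), n = nrow(tab),
           family = "binomial", link = "logit", messages = msgs)
}

# -- (iii b) Gaussian LMM on dyads with crossed random effects ---------------

#' Dyadic LMM with crossed member-identity random effects
#'
#' Gaussian mixed model of a symmetric dyadic response (observed synchrony
#' or proximity likelihood) on sex combination, affiliation and rank
#' difference, with crossed random intercepts for both members' identities
#' (member 1 = lexicographically smaller id). Fixed-effect tests use
#' Satterthwaite-approximated degrees of freedom; every fixed term has 1 df,
#' so the t-test is the single-term deletion.
#'
#' @param tab dyad table carrying `id_a`, `id_b`, the covariates from
#'   [dyad_covariates()], and the response column.
#' @param response name of the response column (e.g. `"observed"` or
#'   `"proximity"`).
#' @return A `herd_fit`; `p_drop1` holds the Satterthwaite p, and the
#'   coefficient table a `df` column.
#' @export
fit_dyadic_lmm <- function(tab, response = "observed") {
  if (!response %in% names(tab)) stop("no column '", response, "' in table")
  y <- tab[[response]]
  if (stats::sd(y) == 0) stop("constant response; model undefined")
  dat <- data.frame(y = y,
                    sex_combo = factor(tab$sex_combo, levels = c("different", "same")),
                    affiliation = tab$affiliation, rank_diff = tab$rank_diff,
                    id_a = tab$id_a, id_b = tab$id_b,
                    stringsAsFactors = FALSE)
  cm <- collect_messages({
    parsed <- lme4::lFormula(y ~ sex_combo + affiliation + rank_diff +
                               (1 | id_a) + (1 | id_b),
                             data = dat, REML = TRUE)
    devfun <- do.call(lme4::mkLmerDevfun, parsed)
    opt <- lme4::optimizeLmer(devfun)
    fit <- lme4::mkMerMod(environment(devfun), opt, parsed$reTrms,
                          fr = parsed$fr)
    list(fit = fit, devfun = devfun)
  })
  fit <- cm$result$fit
  msgs <- cm$messages
  if (lme4::isSingular(fit))
    msgs <- c(msgs, "singular random-effect fit; fixed effects still reported")
  st <- satterthwaite_table(fit, cm$result$devfun)
  if (st$fallback)
    msgs <- c(msgs, "Satterthwaite df unavailable for some terms; residual df used")
  coefs <- st$table
  names(coefs)[names(coefs) == "p"] <- "p_drop1"
  coefs$p_wald <- 2 * stats::pnorm(-abs(coefs$statistic))
  herd_fit(paste0("dyadic_lmm_", response), fit, coefs, ranef_variances(fit),
           n = nrow(dat), family = "gaussian", link = "identity",
           messages = msgs)
}
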