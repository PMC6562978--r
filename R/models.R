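# Inferential layer: ANOVA/Tukey on log density, random-intercept LMMs
# with least-squares-means (Tukey-adjusted) contrasts, negative binomial
# mixed regression of group size on log distance-to-cover (Laplace
# approximation via glmmTMB), binomial GAMs for vulnerable-individual
# positioning, and the greenness models. All logs are natural.

new_mob_fit <- function(family, formula, coef = NULL, contrasts = NULL,
                        lrt_p = NA_real_, sigma_session = NA_real_,
                        nobs = NA_integer_, anova = NULL, extra = list(),
                        method = character()) {
  structure(list(family = family, formula = formula, coef = coef,
                 contrasts = contrasts, lrt_p = lrt_p,
                 sigma_session = sigma_session, nobs = nobs,
                 anova = anova, method = method, extra = extra),
            class = "mob_fit")
}

#' @export
print.mob_fit <- function(x, ...) {
  cat(x$family, "fit:", x$formula, sprintf("(n = %s)", x$nobs), "\n")
  if (!is.null(x$anova))
    cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$anova$df1, x$anova$df2,
                x$anova$F, x$anova$p))
  if (!is.na(x$lrt_p)) cat(sprintf("  zone LRT p = %.4g\n", x$lrt_p))
  if (!is.na(x$sigma_session))
    cat(sprintf("  session sigma = %.3g\n", x$sigma_session))
  if (!is.null(x$coef)) { cat("  fixed effects:\n"); print(x$coef, digits = 3) }
  if (!is.null(x$contrasts)) {
    cat("  pairwise contrasts (adjusted):\n")
    print(utils::head(x$contrasts, 10), digits = 3)
    if (nrow(x$contrasts) > 10) cat("  ...\n")
  }
  invisible(x)
}

.zone_factor <- function(z) factor(z, levels = intersect(.ZONES, unique(z)))

.quiet_lmer <- function(formula, data, REML = TRUE) {
  withCallingHandlers(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = REML)),
    warning = function(w) {
      if (grepl("singular|converge|scaled gradient", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

.lmm_lrt_zone <- function(formula, data) {
  # Likelihood-ratio p for dropping every zone term (ML fits). A
  # single-zone input makes the full and null models identical: p = 1.
  if (length(unique(data$zone)) < 2 ||
      !any(grepl("zone", deparse(stats::as.formula(formula))))) return(1)
  f <- stats::as.formula(formula)
  fixed <- attr(stats::terms(lme4::nobars(f)), "term.labels")
  keep <- fixed[!grepl("zone", fixed)]
  re <- paste0("(", vapply(lme4::findbars(f), deparse, character(1)), ")")
  f0 <- stats::reformulate(c(if (length(keep)) keep else "1", re),
                           response = deparse(f[[2]]))
  m1 <- .quiet_lmer(f, data, REML = FALSE)
  m0 <- .quiet_lmer(f0, data, REML = FALSE)
  stats::anova(m0, m1)[2, "Pr(>Chisq)"]
}

.tukey_zone_contrasts <- function(fit, by = NULL) {
  spec <- if (is.null(by)) "zone" else stats::as.formula(paste("~ zone |", by))
  emm <- emmeans::emmeans(fit, spec, lmer.df = "satterthwaite")
  out <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  names(out)[names(out) == "p.value"] <- "p_adj"
  out
}

#' One-way ANOVA with Tukey HSD on log grazing density
#'
#' @param density_table Output of [grazing_density()] (zone, session,
#'   density_km2).
#' @return A `"mob_fit"` with the F test (`anova`) and the Tukey HSD
#'   pairwise table (`contrasts`).
#' @export
density_anova <- function(density_table) {
  d <- as.data.frame(density_table)
  if (length(unique(d$zone)) < 2 || length(unique(d$session)) < 2)
    stop("density ANOVA needs >= 2 zones and >= 2 sessions")
  if (all(d$density_km2 <= 0))
    stop("all densities are zero: log transform undefined")
  if (any(d$density_km2 <= 0)) {
    # a zone empty in one session is treated as not surveyed that session
    warning(sum(d$density_km2 <= 0),
            " empty zone-session cell(s) dropped before the log ANOVA")
    d <- d[d$density_km2 > 0, , drop = FALSE]
    if (length(unique(d$zone)) < 2 || min(table(d$zone)) < 2)
      stop("too few positive density cells after dropping empty ones")
  }
  d$zone <- .zone_factor(d$zone)
  if (stats::var(log(d$density_km2)) == 0) {
    # no variation anywhere: F = 0 by convention, nothing distinguishable
    zl <- levels(d$zone)
    prs <- utils::combn(zl, 2)
    contrasts <- data.frame(contrast = paste(prs[2, ], "-", prs[1, ]),
                            estimate = 0, lower = 0, upper = 0, p_adj = 1)
    return(new_mob_fit("gaussian ANOVA", "log(density_km2) ~ zone",
                       contrasts = contrasts,
                       anova = list(F = 0, df1 = length(zl) - 1,
                                    df2 = nrow(d) - length(zl), p = 1),
                       nobs = nrow(d), method = c("aov", "TukeyHSD")))
  }
  fit <- stats::aov(log(density_km2) ~ zone, data = d)
  s <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$zone
  contrasts <- data.frame(contrast = sub("-", " - ", rownames(tuk)),
                          estimate = tuk[, "diff"],
                          lower = tuk[, "lwr"], upper = tuk[, "upr"],
                          p_adj = tuk[, "p adj"], row.names = NULL)
  new_mob_fit("gaussian ANOVA", "log(density_km2) ~ zone",
              contrasts = contrasts,
              anova = list(F = s[1, "F value"], df1 = s[1, "Df"],
                           df2 = s[2, "Df"], p = s[1, "Pr(>F)"]),
              nobs = nrow(d), method = c("aov", "TukeyHSD"),
              extra = list(model = fit))
}

#' LMM of log group size on disturbance and chain rule
#'
#' Gaussian mixed model of log group size with zone, chain rule and their
#' interaction as fixed effects and a session random intercept; pairwise
#' least-squares-means contrasts between zones within each chain rule and
#' between chain rules within each zone, Tukey-adjusted.
#'
#' @param groups Per-group table (columns size, zone, session, chain_m; a
#'   single-chain table drops the chain terms).
#' @return A `"mob_fit"`.
#' @export
groupsize_lmm <- function(groups) {
  g <- as.data.frame(groups)
  if (length(unique(g$zone)) < 2 || length(unique(g$session)) < 2)
    stop("needs >= 2 zones and >= 2 sessions")
  g$zone <- .zone_factor(g$zone)
  g$session <- factor(g$session)
  g$logsize <- log(g$size)
  multi <- length(unique(g$chain_m)) > 1
  if (multi) {
    g$chain <- factor(g$chain_m)
    f <- logsize ~ zone * chain + (1 | session)
  } else f <- logsize ~ zone + (1 | session)
  fit <- .quiet_lmer(f, g)
  ctr <- .tukey_zone_contrasts(fit, by = if (multi) "chain" else NULL)
  chain_ctr <- NULL
  if (multi) {
    emm <- emmeans::emmeans(fit, ~ chain | zone, lmer.df = "satterthwaite")
    chain_ctr <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                                 adjust = "tukey"))
    names(chain_ctr)[names(chain_ctr) == "p.value"] <- "p_adj"
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  lrt <- .lmm_lrt_zone(f, g)
  new_mob_fit("gaussian LMM", deparse(f), contrasts = ctr, lrt_p = lrt,
              sigma_session = vc$sdcor[vc$grp == "session"][1],
              nobs = nrow(g), method = c("lmer", "lsmeans Tukey"),
              extra = list(model = fit, chain_contrasts = chain_ctr))
}

#' LMM of log clusteredness on disturbance
#'
#' Log mean nearest-neighbour distance (groups of size > 1 only) with zone
#' as the fixed factor and session and group size as random intercepts;
#' inference by likelihood-ratio test plus Tukey contrasts.
#'
#' @param groups Per-group table at a single chain rule with columns
#'   mean_nn_m, size, zone, session.
#' @return A `"mob_fit"`.
#' @export
clusteredness_lmm <- function(groups) {
  g <- as.data.frame(groups)
  g <- g[!is.na(g$mean_nn_m) & g$size > 1, , drop = FALSE]
  if (!nrow(g)) stop("no groups of size > 1")
  g$zone <- .zone_factor(g$zone)
  g$session <- factor(g$session)
  g$size_f <- factor(g$size)
  g$lognn <- log(g$mean_nn_m)
  f <- if (nlevels(g$zone) > 1) lognn ~ zone + (1 | session) + (1 | size_f)
       else lognn ~ (1 | session) + (1 | size_f)
  fit <- .quiet_lmer(f, g)
  lrt <- .lmm_lrt_zone(f, g)
  ctr <- if (nlevels(g$zone) > 1) .tukey_zone_contrasts(fit) else NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_mob_fit("gaussian LMM", deparse(f), contrasts = ctr, lrt_p = lrt,
              sigma_session = vc$sdcor[vc$grp == "session"][1],
              nobs = nrow(g), method = c("lmer", "LRT", "Tukey"),
              extra = list(model = fit))
}

#' LMM of one demographic proportion on disturbance
#'
#' Per-group class proportion with zone fixed and session and group size as
#' random intercepts; likelihood-ratio test plus Tukey contrasts.
#'
#' @param compositions Output of [survey_compositions()], one chain rule.
#' @param demo_class One of [DEMO_CLASSES].
#' @return A `"mob_fit"`.
#' @export
demography_lmm <- function(compositions, demo_class) {
  stopifnot(demo_class %in% DEMO_CLASSES)
  g <- as.data.frame(compositions)
  if (length(unique(g$chain_m)) > 1)
    stop("fit one chain rule at a time")
  g$zone <- .zone_factor(g$zone)
  g$session <- factor(g$session)
  g$size_f <- factor(g$n_total)
  g$prop <- g[[demo_class]]
  f <- if (nlevels(g$zone) > 1) prop ~ zone + (1 | session) + (1 | size_f)
       else prop ~ (1 | session) + (1 | size_f)
  fit <- .quiet_lmer(f, g)
  lrt <- .lmm_lrt_zone(f, g)
  ctr <- if (nlevels(g$zone) > 1) .tukey_zone_contrasts(fit) else NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_mob_fit("gaussian LMM", paste0(demo_class, " ", deparse(f)),
              contrasts = ctr, lrt_p = lrt,
              sigma_session = vc$sdcor[vc$grp == "session"][1],
              nobs = nrow(g), method = c("lmer", "LRT", "Tukey"),
              extra = list(model = fit))
}

#' Negative binomial mixed regression of group size on distance to cover
#'
#' Group size (counts, log link) regressed on log distance-to-cover nested
#' within disturbance type: one intercept deviation and one slope per zone
#' (reference level HB), with a Gaussian session random intercept
#' integrated by Laplace approximation. 95% Wald confidence intervals; a
#' slope is flagged `detected` when its CI excludes zero. Distances are
#' floored at 1 m before logging.
#'
#' @param groups Per-group table (size, zone, session, gdc) at one chain
#'   rule.
#' @param random_effect Include the session random intercept? Setting
#'   `FALSE` reduces the model to a plain NB GLM.
#' @return A `"mob_fit"` with the coefficient table and session sigma.
#' @export
groupsize_cover_glmm <- function(groups, random_effect = TRUE) {
  g <- as.data.frame(groups)
  if (any(g$size < 1)) stop("group sizes must be >= 1")
  g$zone <- .zone_factor(g$zone)
  g$session <- factor(g$session)
  g$logd <- log(pmax(g$gdc, 1))
  f <- if (nlevels(g$zone) > 1) {
    if (random_effect) size ~ zone + zone:logd + (1 | session)
    else size ~ zone + zone:logd
  } else {
    if (random_effect) size ~ logd + (1 | session) else size ~ logd
  }
  fit <- suppressWarnings(glmmTMB::glmmTMB(f, data = g,
                                           family = glmmTMB::nbinom2()))
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    warning("NB mixed model did not converge cleanly: ",
            fit$fit$message, " (max |grad| = ",
            signif(max(abs(fit$fit$gradient)), 3), ")")
  ci <- stats::confint(fit, method = "wald")
  fe <- ci[!grepl("Std\\.Dev\\.|\\|", rownames(ci)), , drop = FALSE]
  coef_tab <- data.frame(term = rownames(fe),
                         estimate = fe[, "Estimate"],
                         lower = fe[, 1], upper = fe[, 2],
                         detected = fe[, 1] > 0 | fe[, 2] < 0,
                         row.names = NULL)
  sig <- if (random_effect) {
    vc <- glmmTMB::VarCorr(fit)$cond
    sqrt(as.numeric(vc$session[1]))
  } else NA_real_
  new_mob_fit("negative binomial GLMM", deparse(f), coef = coef_tab,
              sigma_session = sig, nobs = nrow(g),
              method = c("glmmTMB", "Laplace", "Wald CI"),
              extra = list(model = fit,
                           theta = stats::sigma(fit)))
}

#' Binomial GAMs for vulnerable-individual positioning
#'
#' Front/behind (1/0) response per vulnerable individual with disturbance
#' type as a fixed factor and a spline smooth of the group's distance to
#' cover; the model is refit cycling the reference level so every pairwise
#' zone contrast is read off a parametric coefficient.
#'
#' @param records Positioning records from [classify_positioning()].
#' @param k Spline basis dimension (reduced automatically when there are
#'   few unique distances).
#' @return A `"mob_fit"`; `contrasts` holds all zone pairs (estimate on the
#'   logit scale, unadjusted p), `extra$edf` the smooth's effective df.
#' @export
positioning_gam <- function(records, k = 10) {
  r <- as.data.frame(records)
  r$front <- as.integer(r$side == "front")
  r$zone <- .zone_factor(r$zone)
  nuniq <- length(unique(r$gdc))
  if (nuniq < k + 1) {
    k <- max(3, nuniq - 1)
    message("few unique distances; spline basis reduced to k = ", k)
  }
  zones <- levels(r$zone)
  if (length(zones) < 2) {
    fit <- mgcv::gam(front ~ s(gdc, k = k), family = stats::binomial(),
                     data = r, method = "REML", select = TRUE)
    return(new_mob_fit("binomial GAM", "front ~ s(gdc)", nobs = nrow(r),
                       method = "mgcv",
                       extra = list(model = fit, edf = summary(fit)$edf)))
  }
  pairs <- list(); fit1 <- NULL
  for (ref in zones) {
    r$zone <- stats::relevel(r$zone, ref = ref)
    fit <- mgcv::gam(front ~ zone + s(gdc, k = k), family = stats::binomial(),
                     data = r, method = "REML", select = TRUE)
    if (is.null(fit1)) fit1 <- fit
    pt <- summary(fit)$p.table
    for (z in setdiff(zones, ref)) {
      rn <- paste0("zone", z)
      if (!rn %in% rownames(pt)) next
      key <- paste(sort(c(ref, z)), collapse = " - ")
      if (!key %in% names(pairs))
        pairs[[key]] <- data.frame(contrast = paste(ref, "-", z),
                                   estimate = -pt[rn, "Estimate"],
                                   p = pt[rn, "Pr(>|z|)"], row.names = NULL)
    }
  }
  r$zone <- .zone_factor(as.character(r$zone))
  edf <- summary(fit1)$edf
  new_mob_fit("binomial GAM", "front ~ zone + s(gdc)",
              contrasts = do.call(rbind, unname(pairs)), nobs = nrow(r),
              method = c("mgcv", "cycled reference levels"),
              extra = list(model = fit1, edf = edf))
}

#' Greenness models
#'
#' Model A: forage greenness against disturbance type with a session random
#' intercept (likelihood-ratio test and Tukey contrasts). Model B: log
#' group size against greenness nested within disturbance type with a
#' session random intercept (Wald CIs; a slope is `detected` when its CI
#' excludes zero).
#'
#' @param group_green Per-group table (greenness, size, zone, session) at
#'   one chain rule.
#' @return List with elements `greenness` and `size_vs_greenness`, both
#'   `"mob_fit"`.
#' @export
greenness_models <- function(group_green) {
  g <- as.data.frame(group_green)
  g$zone <- .zone_factor(g$zone)
  g$session <- factor(g$session)
  fa <- if (nlevels(g$zone) > 1) greenness ~ zone + (1 | session)
        else greenness ~ (1 | session)
  fit_a <- .quiet_lmer(fa, g)
  lrt_a <- .lmm_lrt_zone(fa, g)
  ctr_a <- if (nlevels(g$zone) > 1) .tukey_zone_contrasts(fit_a) else NULL
  vc_a <- as.data.frame(lme4::VarCorr(fit_a))
  a <- new_mob_fit("gaussian LMM", deparse(fa), contrasts = ctr_a,
                   lrt_p = lrt_a,
                   sigma_session = vc_a$sdcor[vc_a$grp == "session"][1],
                   nobs = nrow(g), method = c("lmer", "LRT", "Tukey"),
                   extra = list(model = fit_a))
  g$logsize <- log(g$size)
  fb <- logsize ~ zone + zone:greenness + (1 | session)
  fit_b <- .quiet_lmer(fb, g)
  ci <- suppressWarnings(stats::confint(fit_b, method = "Wald"))
  fe <- lme4::fixef(fit_b)
  ci <- ci[names(fe), , drop = FALSE]
  coef_tab <- data.frame(term = names(fe), estimate = unname(fe),
                         lower = ci[, 1], upper = ci[, 2],
                         detected = ci[, 1] > 0 | ci[, 2] < 0,
                         row.names = NULL)
  vc_b <- as.data.frame(lme4::VarCorr(fit_b))
  b <- new_mob_fit("gaussian LMM", deparse(fb), coef = coef_tab,
                   sigma_session = vc_b$sdcor[vc_b$grp == "session"][1],
                   nobs = nrow(g), method = c("lmer", "Wald CI"),
                   extra = list(model = fit_b))
  list(greenness = a, size_vs_greenness = b)
}
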