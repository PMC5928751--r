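#' Linear mixed-effects model of the factorial response table
#'
#' Fits `response ~ location * auditory * visual + (1 | participant)` with
#' treatment coding whose reference cell is anterior STG, auditory-clear,
#' visual-clear -- so the intercept ("Baseline") is the response to clear
#' audiovisual speech in anterior STG, and the remaining seven fixed effects
#' are the auditory-noise (An), visual-blur (Vb) and posterior-location main
#' effects and all their interactions. Degrees of freedom are
#' Satterthwaite-approximate (hence fractional), via lmerTest.
#'
#' @param table data.frame with columns `unit` (electrode or hemisphere id),
#'   `participant`, `location` ("anterior"/"posterior"), `auditory`
#'   ("clear"/"noisy"), `visual` ("clear"/"blur"), `response` (percent
#'   signal change from baseline).
#' @return Object of class `lme_result`: `effects` (data.frame `term`,
#'   `estimate`, `se`, `df`, `t`, `p`), `singular` flag, and the fitted
#'   `model`.
#' @export
fit_lme <- function(table) {
  need <- c("unit", "participant", "location", "auditory", "visual", "response")
  if (!all(need %in% names(table)))
    stopf("table must have columns: %s", paste(need, collapse = ", "))
  if (length(unique(table$participant)) < 2) stopf("need >= 2 participants")
  if (any(!is.finite(table$response))) stopf("non-finite responses")
  d <- table
  d$location <- factor(d$location, levels = c("anterior", "posterior"))
  d$auditory <- factor(d$auditory, levels = c("clear", "noisy"))
  d$visual <- factor(d$visual, levels = c("clear", "blur"))
  if (anyNA(d$location) || anyNA(d$auditory) || anyNA(d$visual))
    stopf("unrecognized factor level(s) in the response table")
  if (any(table(d$location, d$auditory, d$visual) == 0))
    stopf("missing factorial cell(s)")
  fit <- lmerTest::lmer(response ~ location * auditory * visual +
                          (1 | participant), data = d)
  cf <- stats::coef(summary(fit))
  term_map <- c(
    "(Intercept)" = "Baseline",
    "locationposterior" = "Posterior location",
    "auditorynoisy" = "Auditory noise (An)",
    "visualblur" = "Visual blur (Vb)",
    "locationposterior:auditorynoisy" = "Posterior location x An",
    "locationposterior:visualblur" = "Posterior location x Vb",
    "auditorynoisy:visualblur" = "An x Vb",
    "locationposterior:auditorynoisy:visualblur" = "Posterior location x An x Vb"
  )
  eff <- data.frame(
    term = unname(term_map[rownames(cf)]),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    df = cf[, "df"],
    t = cf[, "t value"],
    p = cf[, "Pr(>|t|)"],
    row.names = NULL
  )
  structure(list(effects = eff, singular = lme4::isSingular(fit), model = fit),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result>", if (x$singular) "(singular fit)" else "", "\n")
  print(within(x$effects, {
    estimate <- round(estimate, 2); se <- round(se, 2)
    df <- round(df, 1); t <- round(t, 2); p <- signif(p, 2)
  }), row.names = FALSE)
  invisible(x)
}

#' Behavioral accuracy summary and matched-auditory comparison
#'
#' Per-condition proportion correct, plus a paired t-test across
#' participants between the two auditory-noisy conditions (noisy + visual
#' clear vs noisy + visual blur): identical auditory input, different
#' performance -- the comparison that dissociates stimulus-driven from
#' performance-driven response differences.
#'
#' @param trials data.frame with `participant`, `condition`, `correct`.
#' @return list: `accuracy` (data.frame `condition`, `n`, `accuracy`),
#'   `comparison` ([paired_t()] result across participants), `by_participant`.
#' @export
behavioral_accuracy <- function(trials) {
  need <- c("participant", "condition", "correct")
  if (!all(need %in% names(trials)))
    stopf("trials must have columns: %s", paste(need, collapse = ", "))
  if (length(unique(trials$participant)) < 2) stopf("need >= 2 participants")
  agg <- stats::aggregate(correct ~ condition, data = trials,
                          FUN = function(x) c(n = length(x), acc = mean(x)))
  accuracy <- data.frame(condition = agg$condition,
                         n = agg$correct[, "n"],
                         accuracy = agg$correct[, "acc"])
  byp <- stats::aggregate(correct ~ participant + condition, data = trials, mean)
  vc <- byp[byp$condition == "AnoisyVclear", ]
  vb <- byp[byp$condition == "AnoisyVblur", ]
  m <- merge(vc, vb, by = "participant", suffixes = c("_Vclear", "_Vblur"))
  comparison <- if (nrow(m) >= 2)
    paired_t(m$correct_Vclear, m$correct_Vblur)
  else list(status = "descriptive-only", n = nrow(m))
  list(accuracy = accuracy, comparison = comparison, by_participant = byp)
}

#' Paired t-test with a degenerate-difference guard
#'
#' Standard paired t on the element-wise differences (df = n - 1). When the
#' differences have zero variance the statistic is undefined; the result is
#' flagged degenerate and, when the common difference is zero, reported as
#' "no difference".
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2).
#' @return list `t`, `df`, `p`, `mean_diff`, `degenerate`, `status`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stopf("length mismatch")
  n <- length(values_a)
  if (n < 2) stopf("need >= 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = n - 1, p = NA_real_, mean_diff = mean(d),
                degenerate = TRUE,
                status = if (mean(d) == 0) "no difference" else "constant difference"))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), degenerate = FALSE, status = "ok")
}

#' Simulate a factorial response table from generating effect sizes
#'
#' Draws a balanced unit x condition table from the treatment-coded fixed
#' effects (reference cell anterior / auditory-clear / visual-clear), a
#' participant-level random intercept and unit-level noise -- the generator
#' behind the mixed-model recovery and calibration checks.
#'
#' @param effects named numeric vector with elements `baseline`, `posterior`,
#'   `an`, `vb`, `post_an`, `post_vb`, `an_vb`, `post_an_vb` (missing terms
#'   default to 0).
#' @param n_participants number of participants.
#' @param units_per_participant units (e.g. electrodes) per participant;
#'   units are split between anterior and posterior locations.
#' @param sd_participant random-intercept SD (default 60, giving a baseline
#'   standard error near the reported electrode-level scale).
#' @param sd_resid residual SD (default 32, giving within-unit contrast
#'   standard errors near the reported scale).
#' @param seed RNG seed.
#' @return data.frame in the [fit_lme()] layout.
#' @export
simulate_response_table <- function(effects, n_participants = 7,
                                    units_per_participant = 4,
                                    sd_participant = 60, sd_resid = 32,
                                    seed = 1L) {
  full <- c(baseline = 0, posterior = 0, an = 0, vb = 0,
            post_an = 0, post_vb = 0, an_vb = 0, post_an_vb = 0)
  full[names(effects)] <- effects
  with_seed(seed, {
    rows <- list()
    uid <- 0L
    for (p in seq_len(n_participants)) {
      u_p <- stats::rnorm(1, 0, sd_participant)
      for (u in seq_len(units_per_participant)) {
        uid <- uid + 1L
        loc <- if (u %% 2 == 0) "posterior" else "anterior"
        for (aud in c("clear", "noisy")) for (vis in c("clear", "blur")) {
          post <- as.numeric(loc == "posterior")
          an <- as.numeric(aud == "noisy")
          vb <- as.numeric(vis == "blur")
          mu <- full["baseline"] + full["posterior"] * post + full["an"] * an +
            full["vb"] * vb + full["post_an"] * post * an +
            full["post_vb"] * post * vb + full["an_vb"] * an * vb +
            full["post_an_vb"] * post * an * vb
          rows[[length(rows) + 1L]] <- data.frame(
            unit = sprintf("u%03d", uid), participant = sprintf("p%02d", p),
            location = loc, auditory = aud, visual = vis,
            response = mu + u_p + stats::rnorm(1, 0, sd_resid))
        }
      }
    }
    do.call(rbind, rows)
  })
}
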