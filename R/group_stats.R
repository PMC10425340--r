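#' Fit the nested mixed-effects group model
#'
#' Fits `value_um ~ group + batch` with random intercepts for mouse and — for
#' paranode-level measures, where the two paranodes of a node are dependent —
#' for node nested in mouse, by restricted maximum likelihood. Boundary
#' (zero) variance components are allowed. The batch term is dropped with a
#' message when only one staining batch is present; a batch factor aliased
#' with group is a fit error naming the aliased columns. Group means are
#' batch-adjusted estimated marginal means.
#'
#' @param records a morphometry record `data.frame` (see
#'   [write_morphometry()] for the schema).
#' @param measure which measure to model: `"paranode_length"`,
#'   `"node_width"` or `"total_region"`.
#' @param fixed optional right-hand-side formula for the fixed effects
#'   (default `~ group + batch`).
#' @return an object of class `ranvier_fit`: the `lmerTest` model, the
#'   estimated marginal means over groups, fixed-effect table, variance
#'   components, and the modeled data.
#' @export
fit_mixed <- function(records,
                      measure = c("paranode_length", "node_width",
                                  "total_region"),
                      fixed = NULL) {
  measure <- match.arg(measure)
  d <- records[records$measure == measure, , drop = FALSE]
  if (!nrow(d)) stop("no records for measure '", measure, "'")
  d$group <- factor(d$group)
  d$batch <- factor(d$batch)
  d$mouse_id <- factor(d$mouse_id)
  d$node_id <- factor(d$node_id)
  if (nlevels(d$group) < 2)
    stop("fit requires at least 2 groups")
  mice_per_group <- tapply(d$mouse_id, d$group, function(m) length(unique(m)))
  if (any(mice_per_group < 2))
    stop("fit requires at least 2 mice per group")

  has_batch <- nlevels(d$batch) > 1
  if (has_batch) {
    singletons <- names(which(table(unique(d[c("mouse_id", "batch")])$batch) == 1))
    if (length(singletons))
      warning("singleton staining batch(es): ", paste(singletons, collapse = ", "))
    mm <- model.matrix(~ group + batch, d)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("fit error: aliased fixed-effect columns: ",
           paste(aliased, collapse = ", "))
    }
  }

  rhs <- if (!is.null(fixed)) paste(deparse(fixed[[length(fixed)]]), collapse = " ")
         else if (has_batch) "group + batch" else "group"
  re <- if (measure == "paranode_length")
    "(1 | mouse_id) + (1 | mouse_id:node_id)" else "(1 | mouse_id)"
  form <- as.formula(paste("value_um ~", rhs, "+", re))

  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite")
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit,
                 emmeans = emm,
                 fixed_effects = coef(summary(fit)),
                 variance_components = setNames(vc$sdcor, vc$grp),
                 measure = measure,
                 data = d),
            class = "ranvier_fit")
}

#' @export
print.ranvier_fit <- function(x, ...) {
  cat(sprintf("<ranvier_fit> measure = %s, n = %d\n", x$measure, nrow(x$data)))
  print(summary(x$emmeans))
  cat("random-effect SDs:\n")
  print(round(x$variance_components, 4))
  invisible(x)
}

#' Pairwise group contrasts with Satterthwaite degrees of freedom
#'
#' Pairwise differences of the batch-adjusted group means; `t = estimate/SE`,
#' degrees of freedom by the Satterthwaite approximation (generally
#' fractional), two-sided p-values. No multiplicity adjustment by default,
#' matching raw pairwise reporting; Holm is available.
#'
#' @param fit a `ranvier_fit` (or the emmeans-bearing result of
#'   [fit_interaction()]).
#' @param pairs optional character vector selecting contrasts by their
#'   `"A - B"` (or `"A vs. B"`) name.
#' @param adjust `"none"` (default) or any adjustment emmeans supports
#'   (e.g. `"holm"`).
#' @return a `data.frame` with contrast, estimate, SE, df, t, p and a
#'   formatted `report` string like `"Con vs. Res, t(13.5) = -2.356, p = 0.034"`.
#' @export
pairwise_contrasts <- function(fit, pairs = NULL, adjust = "none") {
  emm <- if (inherits(fit, "ranvier_fit")) fit$emmeans else fit
  ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust),
                infer = c(FALSE, TRUE))
  out <- data.frame(contrast = as.character(ct$contrast),
                    estimate = ct$estimate, SE = ct$SE, df = ct$df,
                    t = ct$t.ratio, p = ct$p.value,
                    stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    want <- gsub(" vs\\. ", " - ", pairs)
    # a level contrasted with itself is identically zero
    lev <- unique(unlist(strsplit(out$contrast, " - ", fixed = TRUE)))
    selfs <- want[sub("^(.*) - (.*)$", "\\1", want) ==
                    sub("^(.*) - (.*)$", "\\2", want) &
                    sub("^(.*) - (.*)$", "\\1", want) %in% lev]
    if (length(selfs))
      out <- rbind(out, data.frame(contrast = selfs, estimate = 0, SE = NA,
                                   df = NA, t = 0, p = 1))
    missing_pairs <- setdiff(want, c(out$contrast,
                                     sub("^(.*) - (.*)$", "\\2 - \\1", out$contrast)))
    if (length(missing_pairs))
      stop("key error: unknown contrast(s): ", paste(missing_pairs, collapse = ", "))
    flip <- match(sub("^(.*) - (.*)$", "\\2 - \\1", want), out$contrast)
    keep <- match(want, out$contrast)
    sel <- ifelse(is.na(keep), flip, keep)
    out <- out[sel, , drop = FALSE]
    sw <- which(is.na(keep))
    out$estimate[sw] <- -out$estimate[sw]
    out$t[sw] <- -out$t[sw]
    out$contrast[sw] <- want[sw]
  }
  out$report <- vapply(seq_len(nrow(out)), function(i)
    format_contrast(out$contrast[i], out$t[i], out$df[i], out$p[i]), "")
  rownames(out) <- NULL
  out
}

#' Format / parse contrast report strings
#'
#' `format_contrast` renders a contrast in the conventional legend style,
#' e.g. `"Con vs. Res, t(13.5) = -2.356, p = 0.034"`; `parse_contrast`
#' inverts it.
#'
#' @param contrast contrast name (`"A - B"` or `"A vs. B"`).
#' @param t,df,p test statistic, degrees of freedom, p-value.
#' @param text a formatted contrast string.
#' @return a string; for `parse_contrast`, a list with `contrast`, `t`,
#'   `df`, `p`.
#' @export
format_contrast <- function(contrast, t, df, p) {
  sprintf("%s, t(%.1f) = %.3f, p = %s",
          gsub(" - ", " vs. ", contrast), df, t,
          ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' @rdname format_contrast
#' @export
parse_contrast <- function(text) {
  m <- regmatches(text, regexec(
    "^(.*), t\\(([-0-9.]+)\\) = ([-0-9.]+), p = ([<0-9.]+)$", text))[[1]]
  if (length(m) != 5) stop("cannot parse contrast string: ", text)
  list(contrast = m[2], df = as.numeric(m[3]), t = as.numeric(m[4]),
       p = if (startsWith(m[5], "<")) as.numeric(sub("<", "", m[5])) else
         as.numeric(m[5]))
}

#' Fit the virus-group x axon-type interaction model
#'
#' For axon-specific designs: fits `value_um ~ group * axon_type (+ batch)`
#' with mouse (and node nested in mouse, for paranode-level measures) random
#' intercepts, and reports the interaction coefficient plus within-axon-type
#' pairwise group contrasts — the labeled-vs-labeled contrast carries the
#' manipulation-specific effect, the non-labeled contrast is its negative
#' control.
#'
#' @param records morphometry records with an `axon_type` column
#'   (`"labeled"` / `"non-labeled"`).
#' @param measure modeled measure (paranode-level by default).
#' @return an object of class `ranvier_interaction_fit`: the model, the
#'   interaction row of the coefficient table, per-axon-type emmeans, and
#'   within-axon-type contrasts.
#' @export
fit_interaction <- function(records, measure = "paranode_length") {
  d <- records[records$measure == measure, , drop = FALSE]
  if (!nrow(d)) stop("no records for measure '", measure, "'")
  if (!"axon_type" %in% names(d) || anyNA(d$axon_type) ||
      length(unique(d$axon_type)) < 2)
    stop("contract error: fit_interaction requires axon_type with both levels")
  d$group <- factor(d$group)
  d$axon_type <- factor(d$axon_type)
  d$batch <- factor(d$batch)
  d$mouse_id <- factor(d$mouse_id)
  d$node_id <- factor(d$node_id)
  has_batch <- nlevels(d$batch) > 1
  rhs <- if (has_batch) "group * axon_type + batch" else "group * axon_type"
  re <- if (measure == "paranode_length")
    "(1 | mouse_id) + (1 | mouse_id:node_id)" else "(1 | mouse_id)"
  fit <- suppressMessages(lmerTest::lmer(
    as.formula(paste("value_um ~", rhs, "+", re)), data = d, REML = TRUE))
  ctab <- coef(summary(fit))
  inter <- ctab[grepl(":", rownames(ctab)), , drop = FALSE]
  emm <- emmeans::emmeans(fit, "group", by = "axon_type",
                          lmer.df = "satterthwaite")
  within <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  structure(list(model = fit,
                 interaction = inter,
                 emmeans = emm,
                 within_axon_contrasts = within,
                 measure = measure,
                 data = d),
            class = "ranvier_interaction_fit")
}

#' @export
print.ranvier_interaction_fit <- function(x, ...) {
  cat(sprintf("<ranvier_interaction_fit> measure = %s, n = %d\n",
              x$measure, nrow(x$data)))
  cat("interaction:\n"); print(round(x$interaction, 4))
  cat("within-axon-type contrasts:\n"); print(x$within_axon_contrasts)
  invisible(x)
}

#' Percent difference between group means
#'
#' `100 * (mean_comparison - mean_reference) / mean_reference`, using
#' batch-adjusted estimated marginal means by default (raw group means
#' optionally). For interaction fits, the comparison is made within one
#' axon type.
#'
#' @param fit a `ranvier_fit` or `ranvier_interaction_fit`.
#' @param reference,comparison group level names.
#' @param axon_type for interaction fits, the axon type within which to
#'   compare.
#' @param type `"adjusted"` (estimated marginal means) or `"raw"`.
#' @return percent difference (positive = comparison larger).
#' @export
percent_difference <- function(fit, reference, comparison, axon_type = NULL,
                               type = c("adjusted", "raw")) {
  type <- match.arg(type)
  if (type == "raw") {
    d <- fit$data
    if (!is.null(axon_type)) d <- d[d$axon_type == axon_type, , drop = FALSE]
    mr <- mean(d$value_um[d$group == reference])
    mc <- mean(d$value_um[d$group == comparison])
  } else {
    es <- summary(fit$emmeans)
    if (!is.null(axon_type)) es <- es[es$axon_type == axon_type, , drop = FALSE]
    if (!all(c(reference, comparison) %in% es$group))
      stop("key error: unknown group level")
    mr <- es$emmean[es$group == reference]
    mc <- es$emmean[es$group == comparison]
  }
  if (!is.finite(mr) || mr <= 0)
    stop("contract error: reference mean must be positive")
  100 * (mc - mr) / mr
}
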