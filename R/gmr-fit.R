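#' @title Geometric-mean-ratio regression of ln-transformed outcomes
#' @description
#' Total ED resource consumption is heavily right-skewed, so models are fit
#' by ordinary least squares on the natural-log outcome. The exponentiated
#' coefficient of a binary predictor is the geometric mean ratio (GMR): the
#' multiplicative change of the outcome's geometric mean in the presence vs.
#' the absence of the predictor. Confidence intervals are normal-theory Wald
#' intervals on the ln scale, exponentiated.
#' @name gmr_table
NULL

# Assemble the design columns for a set of predictor blocks.
.block_columns <- function(features, predictors) {
  blocks <- feature_blocks()
  unknown <- setdiff(predictors, names(blocks))
  if (length(unknown)) {
    stop("unknown predictor block: ", paste(unknown, collapse = ", "))
  }
  cols <- unlist(blocks[predictors], use.names = FALSE)
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop("feature frame lacks columns: ", paste(missing, collapse = ", "))
  }
  cols
}

.block_of <- function(columns) {
  blocks <- feature_blocks()
  lut <- stats::setNames(rep(names(blocks), lengths(blocks)),
                         unlist(blocks, use.names = FALSE))
  unname(lut[columns])
}

.fit_gmr <- function(features, outcome, predictors, outcome_label) {
  cols <- .block_columns(features, predictors)
  dat <- features[, cols, drop = FALSE]
  const <- vapply(dat, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("degenerate fit: constant predictor(s): ",
         paste(cols[const], collapse = ", "))
  }
  dat$.y <- outcome
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  p <- 2 * stats::pnorm(-abs(cf / se))
  z <- stats::qnorm(0.975)
  keep <- names(cf) != "(Intercept)"
  nm <- names(cf)[keep]
  # lm mangles names like `age_18_24` only if non-syntactic; ours are clean
  tab <- data.frame(
    name = nm,
    block = .block_of(nm),
    coef_ln = unname(cf[keep]),
    coef_x10 = round(unname(cf[keep]) * 10, 1),
    gmr = exp(unname(cf[keep])),
    ci_low = exp(unname(cf[keep] - z * se[keep])),
    ci_high = exp(unname(cf[keep] + z * se[keep])),
    p = unname(p[keep]),
    baseline_flag = FALSE,
    stringsAsFactors = FALSE)
  structure(tab, class = c("gmr_table", "data.frame"),
            intercept = unname(cf[["(Intercept)"]]),
            n = length(outcome),
            aic = stats::AIC(fit), bic = stats::BIC(fit),
            sigma = stats::sigma(fit),
            predictors = predictors,
            outcome = outcome_label)
}

#' Univariable GMR regression
#'
#' Ordinary least squares of the ln-transformed outcome on a single
#' predictor block, reporting the geometric mean ratio of each level against
#' the block baseline with a normal-theory 95% CI.
#'
#' @param features Feature data frame from [derive_features()].
#' @param outcome Numeric ln-scale outcome vector (e.g. `log(total_tp)`).
#' @param predictor A single block name from [feature_blocks()].
#' @param outcome_label Descriptive label stored with the fit.
#' @return A `gmr_table` data frame with columns `name`, `block`, `coef_ln`,
#'   `coef_x10`, `gmr`, `ci_low`, `ci_high`, `p`, `baseline_flag`, and
#'   attributes `intercept`, `n`, `aic`, `bic`, `sigma`.
#' @export
fit_univariable <- function(features, outcome, predictor,
                            outcome_label = "ln total ED resources (TP)") {
  stopifnot(length(predictor) == 1L)
  .fit_gmr(features, outcome, predictor, outcome_label)
}

#' Multivariable GMR regression
#'
#' Joint ordinary-least-squares fit of the ln-transformed outcome on a set
#' of predictor blocks.
#'
#' @inheritParams fit_univariable
#' @param predictors Character vector of block names (default: the full
#'   candidate set, see [candidate_predictors()]).
#' @return A `gmr_table`; see [fit_univariable()].
#' @export
fit_multivariable <- function(features, outcome,
                              predictors = candidate_predictors(),
                              outcome_label =
                                "ln total ED resources (TP)") {
  .fit_gmr(features, outcome, predictors, outcome_label)
}

#' @export
print.gmr_table <- function(x, ...) {
  cat(sprintf("GMR regression of %s (n = %s)\n", attr(x, "outcome"),
              format(attr(x, "n"), big.mark = ",")))
  cat(sprintf("  intercept %.3f ln(TP); AIC %.1f, BIC %.1f\n",
              attr(x, "intercept"), attr(x, "aic"), attr(x, "bic")))
  df <- as.data.frame(x)
  df$gmr <- round(df$gmr, 2)
  df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2)
  df$p <- signif(df$p, 2)
  print(df[, c("name", "gmr", "ci_low", "ci_high", "p", "coef_x10")],
        row.names = FALSE)
  invisible(x)
}

# Blocks whose every level has a GMR strictly inside the band.
.removable_blocks <- function(tab, band, protected) {
  inside <- tab$gmr > band[1] & tab$gmr < band[2]
  by_block <- split(inside, tab$block)
  cand <- names(by_block)[vapply(by_block, all, logical(1))]
  setdiff(cand, protected)
}

# Distance of a block from the null effect: worst level by |ln GMR|.
.block_distance <- function(tab, blocks) {
  vapply(blocks, function(b) {
    max(abs(log(tab$gmr[tab$block == b])))
  }, numeric(1))
}

#' Prune predictors by the GMR band rule
#'
#' Starting from a multivariable fit, predictors whose GMR changes the
#' geometric mean of the outcome by less than 10% (0.9 < GMR < 1.1 by
#' default) are removed stepwise and the model refit after each removal,
#' until no removable predictor remains. A multi-level categorical block is
#' removable only when *all* its non-baseline levels lie strictly inside the
#' band, and is removed whole. At each step the qualifying block closest to
#' the null (smallest worst-level `|ln GMR|`) is removed; ties break
#' alphabetically by block name. With `refit_each_step = FALSE`, all blocks
#' qualifying in a round are removed at once before refitting.
#'
#' @inheritParams fit_multivariable
#' @param band Length-2 numeric: the open GMR interval treated as negligible.
#' @param protected Block names never removed.
#' @param refit_each_step Remove one block per refit (default) or per round.
#' @return A list of class `gmr_prune`: `fit` (final `gmr_table`),
#'   `predictors` (retained block names), and `trace` (data frame of
#'   removals: `step`, `block`, `max_abs_ln_gmr`).
#' @export
prune_by_gmr_band <- function(features, outcome,
                              predictors = candidate_predictors(),
                              band = c(0.9, 1.1), protected = character(),
                              refit_each_step = TRUE,
                              outcome_label =
                                "ln total ED resources (TP)") {
  stopifnot(length(band) == 2L, band[1] < 1, band[2] > 1)
  preds <- predictors
  trace <- data.frame(step = integer(), block = character(),
                      max_abs_ln_gmr = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- .fit_gmr(features, outcome, preds, outcome_label)
    cand <- .removable_blocks(fit, band, protected)
    if (!length(cand) || length(preds) == 1L) break
    dist <- .block_distance(fit, cand)
    if (refit_each_step) {
      drop <- cand[order(dist, cand)][1L]
    } else {
      drop <- cand[order(dist, cand)]
      drop <- drop[seq_len(min(length(drop), length(preds) - 1L))]
    }
    for (b in drop) {
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, block = b,
        max_abs_ln_gmr = unname(dist[b]), stringsAsFactors = FALSE))
    }
    preds <- setdiff(preds, drop)
  }
  structure(list(fit = fit, predictors = preds, trace = trace),
            class = "gmr_prune")
}

#' @export
print.gmr_prune <- function(x, ...) {
  cat(sprintf("GMR-band pruning: %d block(s) removed, %d retained\n",
              nrow(x$trace), length(x$predictors)))
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  print(x$fit)
  invisible(x)
}
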