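# Comparative-CT (delta-delta-CT) quantification, primer efficiency from
# standard curves, and the normality/variance-gated test cascade that
# produces discrete expression calls.

#' Primer efficiency from a standard curve
#'
#' Fits CT on log10 template amount by least squares; efficiency is
#' `E = 10^(-1/slope) - 1`, so the canonical slope of -3.3219 gives
#' E = 1 (100 \% doubling per cycle).
#'
#' @param log10_amount Numeric vector of log10 template amounts (>= 3
#'   distinct values).
#' @param ct CT values, same length.
#' @return List with `efficiency`, `slope`, `intercept`, `r_squared`.
#' @export
primer_efficiency <- function(log10_amount, ct) {
  ok <- !is.na(log10_amount) & !is.na(ct)
  log10_amount <- log10_amount[ok]; ct <- ct[ok]
  if (length(unique(log10_amount)) < 3L)
    stop("standard curve needs at least 3 distinct template amounts")
  fit <- stats::lm(ct ~ log10_amount)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8)
    stop("degenerate standard curve: slope ~ 0")
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(efficiency = 10^(-1 / slope) - 1,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Relative quantification by the comparative-CT method
#'
#' Per individual and tissue, `dCT = ct_target - ct_control`; individuals
#' missing any needed CT are dropped listwise for this gene. Then
#' `ddCT = mean(dCT focal) - mean(dCT reference)` and `RQ = 2^-ddCT`
#' (or `(1 + efficiency)^-ddCT` when an efficiency is supplied).
#'
#' @param measurements Data frame for one gene/species with columns
#'   `individual`, `tissue` (`"focal"`/`"reference"`), `ct_target`,
#'   `ct_control`.
#' @param efficiency Optional amplification efficiency used in place of
#'   the assumed perfect doubling (base `2` becomes `1 + efficiency`).
#' @return List with `ddct`, `rq`, `n_pairs`, `n_dropped`, and the paired
#'   per-individual `dct_focal` and `dct_reference` vectors.
#' @export
relative_quantification <- function(measurements, efficiency = NULL) {
  m <- measurements
  dct <- m$ct_target - m$ct_control
  foc <- m$tissue == "focal"
  f <- stats::setNames(dct[foc], m$individual[foc])
  r <- stats::setNames(dct[!foc], m$individual[!foc])
  inds <- intersect(names(f), names(r))
  ok <- inds[!is.na(f[inds]) & !is.na(r[inds])]
  n_total <- length(unique(m$individual))
  if (length(ok) == 0L)
    stop("insufficient data: no individual has complete CT measurements")
  ddct <- mean(f[ok]) - mean(r[ok])
  base <- if (is.null(efficiency)) 2 else 1 + efficiency
  list(ddct = ddct, rq = base^(-ddct),
       n_pairs = length(ok), n_dropped = n_total - length(ok),
       dct_focal = unname(f[ok]), dct_reference = unname(r[ok]))
}

#' Choose and run the expression test for one gene
#'
#' Reproduces the study's cascade on the paired per-individual dCT samples:
#' \enumerate{
#'   \item sample size below five: Mann-Whitney (unpaired rank sum);
#'   \item Shapiro-Wilk non-normality (p < 0.05) in either sample:
#'     Wilcoxon signed rank on the paired differences;
#'   \item F-test inequality of variances (p < 0.05): unpaired t-test with
#'     Welch's correction;
#'   \item otherwise: paired t-test.
#' }
#' All p-values are two-sided. Degenerate samples (e.g. all values
#' identical) return an `NA` p-value with `degenerate = TRUE`.
#'
#' @param dct_focal,dct_reference Paired numeric vectors of equal length.
#' @param alpha_gate Gate level for the Shapiro-Wilk and F-test checks.
#' @return List with `test_used`, `p_value`, `n`, `shapiro_p_focal`,
#'   `shapiro_p_reference`, `f_test_p`, `degenerate`.
#' @export
choose_test <- function(dct_focal, dct_reference, alpha_gate = 0.05) {
  x <- dct_focal[!is.na(dct_focal)]
  y <- dct_reference[!is.na(dct_reference)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n <- min(length(x), length(y))
  res <- list(test_used = NA_character_, p_value = NA_real_, n = n,
              shapiro_p_focal = NA_real_, shapiro_p_reference = NA_real_,
              f_test_p = NA_real_, degenerate = FALSE)
  safe_p <- function(expr) {
    tryCatch(suppressWarnings(expr$p.value), error = function(e) NA_real_)
  }
  if (n < 5L) {
    res$test_used <- "mann_whitney"
    res$p_value <- safe_p(stats::wilcox.test(x, y, exact = FALSE))
  } else {
    sw_x <- tryCatch(stats::shapiro.test(x)$p.value,
                     error = function(e) NA_real_)
    sw_y <- tryCatch(stats::shapiro.test(y)$p.value,
                     error = function(e) NA_real_)
    res$shapiro_p_focal <- sw_x
    res$shapiro_p_reference <- sw_y
    if (is.na(sw_x) || is.na(sw_y)) {
      res$degenerate <- TRUE
      res$test_used <- "paired_t"
      return(res)
    }
    if (sw_x < alpha_gate || sw_y < alpha_gate) {
      res$test_used <- "wilcoxon_signed_rank"
      res$p_value <- safe_p(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = FALSE))
    } else {
      fp <- tryCatch(stats::var.test(x, y)$p.value,
                     error = function(e) NA_real_)
      res$f_test_p <- fp
      if (!is.na(fp) && fp < alpha_gate) {
        res$test_used <- "welch_t"
        res$p_value <- safe_p(stats::t.test(x, y))
      } else {
        res$test_used <- "paired_t"
        res$p_value <- safe_p(stats::t.test(x, y, paired = TRUE))
      }
    }
  }
  if (is.na(res$p_value)) res$degenerate <- TRUE
  res
}

#' Discrete expression call from RQ and test p-value
#'
#' States follow the study's coding: 0 = under-expression, 1 = no
#' difference, 2 = over-expression, `NA` = unmeasurable. Only `p < alpha`
#' gives a directional call; `alpha <= p < trend_alpha` stays at state 1
#' with `trend = TRUE` (the dotted p < 0.1 band).
#'
#' @param rq Relative quantification (> 0), or `NA`.
#' @param p_value Two-sided test p-value, or `NA`.
#' @param alpha Directional-call level (default 0.05).
#' @param trend_alpha Trend band upper limit (default 0.1).
#' @return List with `state` (integer or `NA`), `trend`, `p_value`,
#'   `direction` (+1/-1/0).
#' @export
call_expression <- function(rq, p_value, alpha = 0.05, trend_alpha = 0.1) {
  if (is.na(rq) || is.na(p_value))
    return(list(state = NA_integer_, trend = FALSE, p_value = p_value,
                direction = NA_integer_))
  if (p_value < alpha && rq == 1)
    stop("contradictory input: rq exactly 1 with significant p-value")
  direction <- sign(log(rq))
  if (p_value < alpha) {
    state <- if (rq > 1) 2L else 0L
    trend <- FALSE
  } else {
    state <- 1L
    trend <- p_value < trend_alpha
  }
  list(state = state, trend = trend, p_value = p_value,
       direction = as.integer(direction))
}

#' Full qPCR analysis for one species
#'
#' Runs relative quantification, the test cascade and expression calling
#' for every gene in a CT table.
#'
#' @param ct_table Data frame with columns `individual`, `tissue`, `gene`,
#'   `ct_target`, `ct_control` (as written by [simulate_ct_table()]).
#' @param species Species label carried into the result.
#' @param alpha,trend_alpha Call levels, see [call_expression()].
#' @param efficiency Optional efficiency correction, see
#'   [relative_quantification()].
#' @return Data frame with one row per gene: `gene`, `species`, `n`,
#'   `ddct`, `rq`, `test_used`, `p_value`, `state`, `trend`.
#' @export
qpcr_analyze <- function(ct_table, species = "species_1", alpha = 0.05,
                         trend_alpha = 0.1, efficiency = NULL) {
  genes <- unique(ct_table$gene)
  rows <- lapply(genes, function(g) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    rq <- tryCatch(relative_quantification(sub, efficiency = efficiency),
                   error = function(e) NULL)
    if (is.null(rq))
      return(data.frame(gene = g, species = species, n = 0L,
                        ddct = NA_real_, rq = NA_real_,
                        test_used = NA_character_, p_value = NA_real_,
                        state = NA_integer_, trend = FALSE,
                        stringsAsFactors = FALSE))
    dec <- choose_test(rq$dct_focal, rq$dct_reference)
    cl <- call_expression(rq$rq, dec$p_value, alpha = alpha,
                          trend_alpha = trend_alpha)
    data.frame(gene = g, species = species, n = rq$n_pairs,
               ddct = rq$ddct, rq = rq$rq, test_used = dec$test_used,
               p_value = dec$p_value, state = cl$state, trend = cl$trend,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
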