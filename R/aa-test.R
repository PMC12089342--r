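## Amino-acid-level inference on replicate codon shifts: linear mixed model
## with amino-acid fixed effects and codon random effects, Wald t statistics
## for each amino acid against the grand mean, BH-adjusted p-values.

#' Test amino-acid-level shifts across replicates
#'
#' Stacks per-replicate codon shifts and fits, by restricted maximum
#' likelihood, `shift ~ 0 + amino_acid + (1 | codon)`: amino acids as fixed
#' effects, codons as random intercepts (codons of one amino acid share its
#' fixed effect; codon-specific deviations are absorbed by the random term).
#' Each amino acid is then tested against the grand mean of the amino-acid
#' effects with a Wald t statistic (Satterthwaite degrees of freedom), and
#' p-values are adjusted across amino acids by Benjamini-Hochberg.
#'
#' If the random-effect fit is singular (codon variance estimated at zero)
#' the model falls back to an ordinary fixed-effects linear model with the
#' same contrasts, with a warning. If all shifts are identical (e.g.
#' condition equals control) every t is 0 and every p is 1.
#'
#' @param replicate_shifts A list of per-replicate shift tables from
#'   [compute_shifts()] (at least 2 replicates).
#' @return `data.table` with one row per amino acid: `amino_acid`,
#'   `estimate` (deviation from the grand mean), `t_value`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
test_amino_acids <- function(replicate_shifts) {
  if (!is.list(replicate_shifts) || length(replicate_shifts) < 2L)
    stop("need at least 2 replicate shift tables")
  d <- rbindlist(lapply(seq_along(replicate_shifts), function(i) {
    s <- as.data.table(replicate_shifts[[i]])[
      !is.na(shift) & amino_acid %chin% amino_acids()]
    s[, replicate := i]
    s[, .(replicate, codon, amino_acid, shift)]
  }))
  if (nrow(d) == 0L) stop("no defined codon shifts to test")
  d[, amino_acid := factor(amino_acid)]
  aas <- levels(d$amino_acid)
  k <- length(aas)
  blank <- data.table(amino_acid = aas, estimate = 0, t_value = 0,
                      df = NA_real_, p_value = 1, p_adjusted = 1)
  if (var(d$shift) == 0) return(blank)
  ## contrast of amino acid a against the grand mean of all k effects
  contrast_rows <- lapply(seq_len(k), function(a) {
    L <- rep(-1 / k, k)
    L[a] <- 1 - 1 / k
    L
  })
  fit <- tryCatch(
    lmerTest::lmer(shift ~ 0 + amino_acid + (1 | codon), data = d,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  use_lmm <- !is.null(fit) && !lme4::isSingular(fit)
  if (use_lmm) {
    res <- rbindlist(lapply(contrast_rows, function(L) {
      ct <- lmerTest::contest1D(fit, L, confint = FALSE)
      data.table(estimate = ct[["Estimate"]], t_value = ct[["t value"]],
                 df = ct[["df"]], p_value = ct[["Pr(>|t|)"]])
    }))
  } else {
    if (is.null(fit))
      warning("mixed-model fit failed; using fixed-effects-only model")
    else
      warning("singular codon random-effect fit; ",
              "using fixed-effects-only model")
    lfit <- lm(shift ~ 0 + amino_acid, data = d)
    b <- coef(lfit)
    V <- vcov(lfit)
    dfr <- df.residual(lfit)
    res <- rbindlist(lapply(contrast_rows, function(L) {
      est <- sum(L * b)
      se <- sqrt(drop(t(L) %*% V %*% L))
      tv <- if (se == 0) 0 else est / se
      data.table(estimate = est, t_value = tv, df = dfr,
                 p_value = if (se == 0) 1 else 2 * pt(-abs(tv), dfr))
    }))
  }
  res[, amino_acid := aas]
  res[, p_adjusted := p.adjust(p_value, method = "BH")]
  setcolorder(res, c("amino_acid", "estimate", "t_value", "df", "p_value",
                     "p_adjusted"))
  res[]
}
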