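# Statistical layer: aligned-rank-transform (ART) factorial ANOVA with
# post-hoc contrasts, and the Wilcoxon rank-sum test, as thin wrappers in
# the reporting style of the chronobiology literature.  The alignment
# step is implemented here; the per-effect ANOVA on ranks delegates to a
# standard type-III linear-model ANOVA with sum-to-zero contrasts.

#' Aligned-rank-transform two-way ANOVA
#'
#' For each effect (A, B, A:B), responses are aligned by removing the
#' cell mean and adding back that effect's own estimate (computed from
#' unweighted cell means), ranked (average ranks for ties), and a
#' standard factorial ANOVA is run on the ranks; only the aligned
#' effect's row is retained.  Handles unbalanced layouts.
#'
#' @param data Data frame with the response and two factors.
#' @param response,factor_a,factor_b Column names.
#' @return Object of class `art_anova`: list with `table`
#'   (`data.table`: effect, F, df1, df2, p), `aligned_ranks` (per-effect
#'   ranked aligned responses), and the model frame.
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
#' d$y <- rnorm(nrow(d))
#' art_anova(d, "y", "a", "b")$table
#' @export
art_anova <- function(data, response, factor_a, factor_b) {
  df <- as.data.frame(data)
  y <- df[[response]]
  A <- factor(df[[factor_a]])
  B <- factor(df[[factor_b]])
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("each factor needs at least 2 levels")
  if (anyNA(y)) stop("missing responses are not allowed")

  cellm <- tapply(y, list(A, B), mean)          # unweighted cell means
  g <- mean(cellm)
  am <- rowMeans(cellm) - g
  bm <- colMeans(cellm) - g
  abm <- sweep(sweep(cellm - g, 1, am), 2, bm)  # interaction estimates
  m_cell <- cellm[cbind(A, B)]

  aligned <- list(
    A = y - m_cell + am[A],
    B = y - m_cell + bm[B],
    `A:B` = y - m_cell + abm[cbind(A, B)])
  labels <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  rows <- lapply(seq_along(aligned), function(k) {
    r <- rank(aligned[[k]])
    if (sd(r) == 0)          # fully tied: no effect variance anywhere
      return(data.table(effect = labels[k], F = 0,
                        df1 = NA_real_, df2 = NA_real_, p = 1))
    fit <- lm(r ~ A * B)
    tab <- car::Anova(fit, type = 3)
    term <- c("A", "B", "A:B")[k]
    i <- match(term, rownames(tab))
    data.table(effect = labels[k],
               F = tab$`F value`[i],
               df1 = tab$Df[i],
               df2 = tab$Df[nrow(tab)],
               p = tab$`Pr(>F)`[i])
  })
  res <- list(table = rbindlist(rows),
              aligned_ranks = lapply(aligned, rank),
              A = A, B = B,
              factor_names = c(factor_a, factor_b))
  class(res) <- "art_anova"
  res
}

#' @export
print.art_anova <- function(x, ...) {
  cat("Aligned-rank-transform two-way ANOVA\n")
  print(x$table)
  invisible(x)
}

#' Post-hoc contrasts on an ART fit
#'
#' Pairwise comparisons between levels of one effect (or between cells of
#' the interaction), computed on the aligned ranks for that effect.
#' Raw p-values come from pooled-variance t statistics; `"bonferroni"`
#' multiplies by the number of comparisons (capped at 1), `"tukey"`
#' applies the Tukey-Kramer studentized-range adjustment.
#'
#' @param fit An [art_anova()] object.
#' @param effect `"A"`, `"B"` or `"A:B"` (also accepted: the original
#'   factor names).
#' @param pairs Optional list of level pairs to test; defaults to all
#'   pairwise.
#' @param adjust `"bonferroni"`, `"tukey"` or `"none"`.
#' @return `data.table` with `pair`, `estimate` (aligned-rank mean
#'   difference), `p_raw`, `p_adj`.
#' @export
art_contrasts <- function(fit, effect = "A", pairs = NULL,
                          adjust = c("bonferroni", "tukey", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "art_anova"))
  key <- effect
  if (effect %in% fit$factor_names)
    key <- c("A", "B")[match(effect, fit$factor_names)]
  if (!key %in% names(fit$aligned_ranks))
    stop("unknown effect: ", effect)
  grp <- switch(key, A = fit$A, B = fit$B,
                `A:B` = interaction(fit$A, fit$B, sep = ":"))
  r <- fit$aligned_ranks[[key]]
  lev <- levels(grp)
  if (is.null(pairs)) {
    pairs <- combn(lev, 2, simplify = FALSE)
  } else {
    bad <- setdiff(unlist(pairs), lev)
    if (length(bad)) stop("unknown level(s): ", paste(bad, collapse = ", "))
  }
  means <- tapply(r, grp, mean)
  ns <- tapply(r, grp, length)
  k <- nlevels(grp)
  df_err <- length(r) - k
  mse <- sum(tapply(r, grp, function(v) sum((v - mean(v))^2))) / df_err
  out <- rbindlist(lapply(pairs, function(p) {
    d <- means[p[1]] - means[p[2]]
    se <- sqrt(mse * (1 / ns[p[1]] + 1 / ns[p[2]]))
    tstat <- d / se
    p_raw <- 2 * pt(abs(tstat), df_err, lower.tail = FALSE)
    p_tuk <- ptukey(abs(d) / sqrt(mse / 2 * (1 / ns[p[1]] + 1 / ns[p[2]])),
                    k, df_err, lower.tail = FALSE)
    data.table(pair = paste(p[1], "-", p[2]), estimate = unname(d),
               p_raw = unname(p_raw), p_tukey = unname(p_tuk))
  }))
  out[, p_adj := switch(adjust,
                        none = p_raw,
                        bonferroni = p.adjust(p_raw, "bonferroni"),
                        tukey = p_tukey)]
  out[, p_tukey := NULL]
  out[]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location shift.  For pooled sample sizes up to
#' `exact_max` the permutation distribution of the rank sum is
#' enumerated exactly (average ranks make this correct under ties);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Largest pooled n for exact enumeration.
#' @return List with `W` (rank sum of `x` minus its minimum, i.e. the
#'   Mann-Whitney U), `rank_sum_x`, `p`, `method`.
#' @examples
#' rank_sum(c(1, 2), c(3, 4))$p  # exact 1/3
#' @export
rank_sum <- function(x, y, exact_max = 20) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  U <- w - m * (m + 1) / 2
  if (N <= exact_max) {
    sel <- combn(N, m)
    ws <- colSums(matrix(r[sel], nrow = m))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation with tie correction"
  }
  list(W = U, rank_sum_x = w, p = p, method = method)
}
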