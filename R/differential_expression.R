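#' Split an expression matrix into host and virus panels
#'
#' Virus genes have a markedly different rank distribution between infected
#' and uninfected samples, so they are separated from host genes before
#' normalization and analysed as their own panel.
#'
#' @param mat Numeric gene x sample matrix (any scale).
#' @param panel Named character vector, gene id -> "host"/"virus".
#' @return list with matrices \code{host} and \code{virus} (either may have
#'   zero rows).
#' @export
splitPanels <- function(mat, panel) {
    genes <- rownames(mat)
    if (is.null(genes)) stop("matrix must have gene row names")
    missing <- setdiff(genes, names(panel))
    if (length(missing))
        stop("unlabeled gene(s): ", paste(head(missing, 3), collapse = ", "))
    lab <- panel[genes]
    if (!all(lab %in% c("host", "virus")))
        stop("panel labels must be 'host' or 'virus'")
    list(host = mat[lab == "host", , drop = FALSE],
        virus = mat[lab == "virus", , drop = FALSE])
}

#' Quantile normalization
#'
#' Forces every sample's intensity distribution onto the common distribution
#' of across-sample mean order statistics (the Bolstad procedure); ties
#' within a column receive the mean of the values their tied ranks map to.
#' Thin wrapper over \code{\link[limma]{normalizeQuantiles}} preserving
#' dimnames.
#'
#' @param mat Numeric gene x sample matrix (log2 scale by convention).
#' @return Matrix of the same shape; all columns share one sorted value
#'   vector.
#' @export
quantileNormalize <- function(mat) {
    if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
    out <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(out) <- dimnames(mat)
    out
}

#' Pearson correlation between replicate samples
#'
#' @param mat Numeric gene x sample matrix (log2 scale).
#' @param pairs list of length-2 character vectors of sample names.
#' @return Named numeric vector of correlations, rounded to 3 decimals;
#'   pairs with a zero-variance member are NA.
#' @export
replicateCorrelation <- function(mat,
        pairs = list(colnames(mat)[1:2])) {
    vapply(pairs, function(p) {
        x <- mat[, p[1]]; y <- mat[, p[2]]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        round(cor(x, y), 3)
    }, numeric(1), USE.NAMES = FALSE) |>
        setNames(vapply(pairs, paste, character(1), collapse = "-"))
}

#' Two-group per-gene fit
#'
#' Ordinary least squares for the 2-vs-2 design: per-gene log fold change
#' (infected minus uninfected mean) and pooled residual variance with
#' \code{n1 + n2 - 2} degrees of freedom.
#'
#' @param mat Numeric gene x sample matrix, log2 scale.
#' @param condition Character per sample: "infected"/"uninfected".
#' @return data.frame (gene_id, logFC, s2, df_resid) with attributes
#'   \code{n1}, \code{n2}.
#' @export
fitTwoGroup <- function(mat, condition) {
    stopifnot(ncol(mat) == length(condition))
    inf <- condition == "infected"
    uninf <- condition == "uninfected"
    n1 <- sum(inf); n2 <- sum(uninf)
    if (n1 < 2L || n2 < 2L)
        stop("need >= 2 replicates per condition for inference")
    m1 <- rowMeans(mat[, inf, drop = FALSE])
    m2 <- rowMeans(mat[, uninf, drop = FALSE])
    ss <- rowSums((mat[, inf, drop = FALSE] - m1)^2) +
        rowSums((mat[, uninf, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    out <- data.frame(gene_id = rownames(mat), logFC = unname(m1 - m2),
        s2 = unname(ss / df), df_resid = df)
    attr(out, "n1") <- n1
    attr(out, "n2") <- n2
    out
}

# Newton inversion of the trigamma function (for the prior df estimate)
trigammaInverse <- function(x) {
    y <- 0.5 + 1 / x
    for (i in 1:75) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (max(abs(dif / y)) < 1e-10) break
    }
    y
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Estimates the prior degrees of freedom \code{d0} and prior variance
#' \code{s0_sq} by moment-matching \code{log(s2)} against its theoretical
#' scaled log-F distribution (digamma/trigamma inversion), shrinks each
#' gene's variance to the posterior
#' \code{(d0 s0_sq + df s2) / (d0 + df)}, and computes moderated t
#' statistics with \code{d0 + df} degrees of freedom, two-sided p-values
#' and the log-odds (B) ranking statistic (natural log of the posterior
#' odds of differential expression, with a fixed prior proportion and fold
#' change prior variance).
#'
#' When the observed variances are consistent with a single value,
#' \code{d0} is infinite and the posterior variance equals \code{s0_sq} for
#' every gene.
#'
#' @param fit Output of \code{\link{fitTwoGroup}} (>= 10 genes).
#' @param priorProp Prior probability a gene is differentially expressed
#'   (used only by the log-odds; default 0.01).
#' @param priorV0 Prior variance of true log fold changes, in units of the
#'   unscaled variance \code{1/n1 + 1/n2} (default 4).
#' @return list with \code{params} (d0, s0_sq) and \code{table}
#'   (gene_id, logFC, s2, s2_post, df_total, t_mod, p, log_odds).
#' @export
moderateFit <- function(fit, priorProp = 0.01, priorV0 = 4) {
    if (nrow(fit) < 10L)
        stop("hyperparameter estimation needs an ensemble of >= 10 genes")
    df <- fit$df_resid[1L]
    n1 <- attr(fit, "n1"); n2 <- attr(fit, "n2")
    s2 <- fit$s2
    pos <- s2 > 0
    if (!any(pos)) stop("all residual variances are zero")
    z <- log(s2[pos])
    emean <- mean(z)
    evar <- var(z) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s0sq <- exp(emean - digamma(df / 2) + log(df / 2) +
            digamma(d0 / 2) - log(d0 / 2))
    } else {
        # variances consistent with one value: infinite prior df, the
        # plain moment estimator for the common variance
        d0 <- Inf
        s0sq <- mean(s2)
    }
    s2post <- if (is.finite(d0))
        (d0 * s0sq + df * s2) / (d0 + df) else rep(s0sq, length(s2))
    u2 <- 1 / n1 + 1 / n2
    tmod <- fit$logFC / sqrt(s2post * u2)
    # total df capped at the pooled residual df of the ensemble
    dfTotal <- min(d0 + df, nrow(fit) * df)
    p <- 2 * pt(-abs(tmod), df = dfTotal)
    r <- (u2 + priorV0 * u2) / u2   # 1 + v0, v0 in unscaled-variance units
    t2 <- tmod^2
    kernel <- if (is.finite(dfTotal))
        (1 + dfTotal) / 2 * log((t2 + dfTotal) / (t2 / r + dfTotal))
    else t2 * (1 - 1 / r) / 2
    lods <- log(priorProp / (1 - priorProp)) - log(r) / 2 + kernel
    list(params = list(d0 = d0, s0_sq = s0sq),
        table = data.frame(gene_id = fit$gene_id, logFC = fit$logFC,
            s2 = s2, s2_post = s2post, df_total = dfTotal, t_mod = tmod,
            p = p, log_odds = lods))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (\code{stats::p.adjust(method = "BH")}):
#' \code{p_adj(i) = min over j >= rank(i) of min(1, n p(j) / j)}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    p.adjust(p, method = "BH")
}

#' Classify differential-expression results
#'
#' A gene is called up when \code{p_adj < alpha} and \code{logFC > 0}, down
#' when \code{p_adj < alpha} and \code{logFC < 0}, else unchanged. The
#' summary also counts the calls whose fold change exceeds \code{fcFold}
#' (|logFC| > log2(fcFold)). Percentages are over the panel's gene total,
#' half-up to 2 decimals.
#'
#' @param tab data.frame with columns \code{gene_id}, \code{logFC},
#'   \code{p_adj} (e.g. a moderated table plus \code{\link{bhAdjust}}).
#' @param alpha Adjusted-p threshold.
#' @param fcFold Fold-change threshold on the linear scale.
#' @return list with \code{calls} (named vector up/down/unchanged) and
#'   \code{summary} (counts and percentages).
#' @examples
#' deSummaryPercent(5709, 27400)  # 20.84
#' @export
classifyDE <- function(tab, alpha = 0.05, fcFold = 2) {
    stopifnot(all(c("gene_id", "logFC", "p_adj") %in% names(tab)))
    sig <- tab$p_adj < alpha
    call <- ifelse(sig & tab$logFC > 0, "up",
        ifelse(sig & tab$logFC < 0, "down", "unchanged"))
    n <- nrow(tab)
    bigFC <- abs(tab$logFC) > log2(fcFold)
    summ <- list(
        n_genes = n,
        n_up = sum(call == "up"),
        pct_up = deSummaryPercent(sum(call == "up"), n),
        n_down = sum(call == "down"),
        pct_down = deSummaryPercent(sum(call == "down"), n),
        n_up_fc = sum(call == "up" & bigFC),
        pct_up_fc = deSummaryPercent(sum(call == "up" & bigFC), n),
        n_down_fc = sum(call == "down" & bigFC),
        pct_down_fc = deSummaryPercent(sum(call == "down" & bigFC), n))
    list(calls = setNames(call, tab$gene_id), summary = summ)
}

#' @rdname classifyDE
#' @param count,total Counts for the printed-report percentage
#'   (half-up, 2 decimals): 5,709 of 27,400 gives 20.84.
#' @export
deSummaryPercent <- function(count, total) {
    if (total == 0) return(NA_real_)
    roundHalfUp(100 * count / total, 2)
}

#' Gene-level signal matrix from orientation calls
#'
#' The platform's design is one best probe per gene: the gene-level signal
#' is the selected probe's intensity row, for every transcript with a
#' determined orientation.
#'
#' @param signal A \linkS4class{SignalMatrix}.
#' @param calls Output of \code{\link{inferOrientation}}.
#' @return Numeric gene x sample matrix of linear-scale intensities.
#' @export
geneSignalMatrix <- function(signal, calls) {
    det <- calls[calls$chosen_strand != "undetermined", , drop = FALSE]
    v <- intensities(signal)[det$best_probe_id, , drop = FALSE]
    rownames(v) <- det$transcript_id
    v
}

#' Full differential-expression stage for one panel
#'
#' log2(x + 1) transform, quantile normalization, two-group fit,
#' empirical-Bayes moderation, BH adjustment and up/down classification.
#'
#' @param mat Linear-scale gene x sample matrix of one panel.
#' @param condition Per-sample condition labels.
#' @param alpha,fcFold See \code{\link{classifyDE}}.
#' @param priorProp,priorV0 See \code{\link{moderateFit}}.
#' @param normalize Apply quantile normalization (default TRUE).
#' @return list with \code{table} (gene_id, logFC, s2, s2_post, df_total,
#'   t_mod, p, p_adj, log_odds, call), \code{params}, \code{summary},
#'   \code{normalized} (the normalized log2 matrix).
#' @export
runDEPanel <- function(mat, condition, alpha = 0.05, fcFold = 2,
        priorProp = 0.01, priorV0 = 4, normalize = TRUE) {
    lm2 <- log2(mat + 1)
    if (normalize) lm2 <- quantileNormalize(lm2)
    fit <- fitTwoGroup(lm2, condition)
    mod <- moderateFit(fit, priorProp = priorProp, priorV0 = priorV0)
    tab <- mod$table
    tab$p_adj <- bhAdjust(tab$p)
    cls <- classifyDE(tab, alpha = alpha, fcFold = fcFold)
    tab$call <- unname(cls$calls[tab$gene_id])
    list(table = tab, params = mod$params, summary = cls$summary,
        normalized = lm2)
}
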