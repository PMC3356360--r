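#' Delta-proportion category regulation scores
#'
#' For each category, the number of up-regulated members and the number of
#' down-regulated members are both divided by the category size, and the
#' down ratio is subtracted from the up ratio. A positive score suggests the
#' category is up-regulated. Empty categories are excluded with a warning.
#'
#' @param calls Named character vector (gene -> "up"/"down"/"unchanged")
#'   covering the analysis universe.
#' @param annotation Named list, category id -> character vector of member
#'   gene ids (members outside the universe are ignored).
#' @return data.frame (category_id, N, u, d, score) sorted by score
#'   descending.
#' @export
deltaProportionScores <- function(calls, annotation) {
    universe <- names(calls)
    rows <- lapply(names(annotation), function(cat) {
        members <- intersect(annotation[[cat]], universe)
        if (length(members) == 0L) return(NULL)
        u <- sum(calls[members] == "up")
        d <- sum(calls[members] == "down")
        data.frame(category_id = cat, N = length(members), u = u, d = d,
            score = u / length(members) - d / length(members))
    })
    empty <- vapply(rows, is.null, logical(1))
    if (any(empty))
        warning(sum(empty), " empty categor(y/ies) excluded")
    out <- do.call(rbind, rows[!empty])
    out[order(-out$score, out$category_id), , drop = FALSE]
}

#' Hypergeometric over-representation of a direction within categories
#'
#' One-sided tail probability P(X >= k) for X hypergeometric with universe
#' size U, direction-regulated total K and category size N, with BH
#' adjustment across categories within the direction.
#'
#' @param calls Named character vector of regulation calls (the universe).
#' @param annotation Named list, category -> members.
#' @param direction "up" or "down".
#' @return data.frame (category_id, N, k, p, p_adj) in annotation order
#'   (empty categories dropped).
#' @export
hyperEnrichment <- function(calls, annotation, direction = c("up", "down")) {
    direction <- match.arg(direction)
    universe <- names(calls)
    U <- length(universe)
    K <- sum(calls == direction)
    rows <- lapply(names(annotation), function(cat) {
        members <- intersect(annotation[[cat]], universe)
        if (length(members) == 0L) return(NULL)
        N <- length(members)
        k <- sum(calls[members] == direction)
        if (k > min(K, N)) stop("inconsistent contingency for ", cat)
        data.frame(category_id = cat, N = N, k = k,
            p = phyper(k - 1, K, U - K, N, lower.tail = FALSE))
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    out$p_adj <- bhAdjust(out$p)
    out
}

#' Roll GO-style annotations up to slim classes
#'
#' A gene counts once per distinct slim class reached by any of its terms
#' (multi-class counting: the per-class counts sum over class assignments,
#' not genes). Terms absent from the slim map are tallied under
#' \code{"unmapped"}.
#'
#' @param geneTerms Named list, gene id -> character vector of GO-style
#'   term ids.
#' @param slimMap Named list, term id -> character vector of slim class ids.
#' @return list with \code{counts} (named integer per slim class, including
#'   \code{unmapped}) and \code{assignments} (gene -> classes).
#' @export
slimRollup <- function(geneTerms, slimMap) {
    assignments <- lapply(geneTerms, function(terms) {
        mapped <- unlist(slimMap[intersect(terms, names(slimMap))],
            use.names = FALSE)
        cls <- unique(mapped)
        if (any(!terms %in% names(slimMap))) cls <- c(cls, "unmapped")
        cls
    })
    counts <- table(unlist(assignments, use.names = FALSE))
    list(counts = setNames(as.integer(counts), names(counts)),
        assignments = assignments)
}

# weighted running-sum enrichment score at every position; returns the
# signed maximum deviation, its position, and the full curve on request
runningSumES <- function(stat, hitIdx, weight, curve = FALSE) {
    N <- length(stat)
    Nh <- length(hitIdx)
    w <- abs(stat[hitIdx])^weight
    NR <- sum(w)
    step <- numeric(N)
    step[hitIdx] <- if (NR > 0) w / NR else 1 / Nh
    miss <- 1 / (N - Nh)
    step[-hitIdx] <- -miss
    rs <- cumsum(step)
    i <- which.max(abs(rs))   # first index: earlier-rank tie-break
    if (curve) list(es = rs[i], pos = i, curve = rs)
    else list(es = rs[i], pos = i)
}

#' Gene-set enrichment analysis with gene-set permutation
#'
#' Genes are ranked by the signed statistic (descending); a weighted
#' running sum increments by \code{|r|^weight} (normalized over set
#' members) at each hit and decrements by \code{1/(U - set size)} at each
#' miss. The enrichment score (ES) is the signed maximum deviation from
#' zero; a positive ES indicates enrichment at the top of the ranking
#' (up-regulated). The null distribution draws \code{nperm} random
#' same-size gene sets from the universe; NES divides ES by the mean
#' absolute null ES of matching sign, the nominal p is the fraction of
#' matching-sign null ES at least as extreme, and FDR q follows the pooled
#' sign-matched normalized-null scheme. The leading edge contains the set
#' members at or before the ES extremum (at or after it for negative ES).
#'
#' @param stat Named numeric vector, gene -> signed ranking statistic
#'   (typically the moderated t).
#' @param geneSets Named list of gene id vectors; sets with fewer than 3
#'   members in the universe are skipped with a warning.
#' @param weight Hit-weighting exponent (1 = classic weighted ES).
#' @param nperm Number of random same-size null sets per gene set.
#' @param seed Integer seed for the permutation draws.
#' @return data.frame (set_id, size, ES, NES, nominal_p, FDR_q,
#'   leading_edge) with leading-edge gene ids collapsed by ";".
#' @export
gseaEnrichment <- function(stat, geneSets, weight = 1, nperm = 1000L,
        seed = 1L) {
    ord <- order(-stat, names(stat))
    ranked <- stat[ord]
    genes <- names(ranked)
    N <- length(genes)
    keep <- vapply(geneSets, function(s)
        sum(s %in% genes) >= 3L, logical(1))
    if (any(!keep))
        warning("skipping gene set(s) with < 3 members in the universe: ",
            paste(names(geneSets)[!keep], collapse = ", "))
    geneSets <- geneSets[keep]
    if (length(geneSets) == 0L)
        return(data.frame(set_id = character(), size = integer(),
            ES = numeric(), NES = numeric(), nominal_p = numeric(),
            FDR_q = numeric(), leading_edge = character()))
    obs <- lapply(geneSets, function(s) {
        idx <- which(genes %in% s)
        r <- runningSumES(ranked, idx, weight)
        le <- if (r$es >= 0) idx[idx <= r$pos] else idx[idx >= r$pos]
        list(es = r$es, size = length(idx),
            leading = genes[le])
    })
    sizes <- vapply(obs, `[[`, integer(1), "size")
    esObs <- vapply(obs, `[[`, numeric(1), "es")

    nullES <- withSeed(seed, {
        lapply(sizes, function(sz)
            vapply(seq_len(nperm), function(b) {
                idx <- sort(sample.int(N, sz))
                runningSumES(ranked, idx, weight)$es
            }, numeric(1)))
    })
    normalize <- function(es, null) {
        mp <- mean(null[null >= 0]); mn <- mean(abs(null[null < 0]))
        ifelse(es >= 0, es / mp, es / mn)
    }
    nes <- mapply(function(es, null) normalize(es, null), esObs, nullES)
    pnom <- mapply(function(es, null) {
        same <- if (es >= 0) null[null >= 0] else null[null < 0]
        if (length(same) == 0L) return(1 / (nperm + 1))
        mean(abs(same) >= abs(es))
    }, esObs, nullES)
    # pooled sign-matched normalized null for the FDR
    nullNES <- unlist(mapply(function(null, es) normalize(null, null),
        nullES, esObs, SIMPLIFY = FALSE), use.names = FALSE)
    fdr <- vapply(seq_along(nes), function(i) {
        x <- nes[i]
        if (x >= 0) {
            num <- mean(nullNES[nullNES >= 0] >= x)
            den <- mean(nes[nes >= 0] >= x)
        } else {
            num <- mean(nullNES[nullNES < 0] <= x)
            den <- mean(nes[nes < 0] <= x)
        }
        if (!is.finite(num)) num <- 1
        min(1, max(0, num / max(den, .Machine$double.eps)))
    }, numeric(1))
    data.frame(set_id = names(geneSets), size = unname(sizes),
        ES = unname(esObs), NES = unname(nes),
        nominal_p = unname(pnom), FDR_q = fdr,
        leading_edge = vapply(obs, function(o)
            paste(o$leading, collapse = ";"), character(1)),
        row.names = NULL)
}
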