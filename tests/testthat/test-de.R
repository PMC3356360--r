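cond2v2 <- c("infected", "infected", "uninfected", "uninfected")

test_that("panel splitting is exhaustive, disjoint, and strict about labels", {
    m <- matrix(1, 105, 4, dimnames = list(c(sprintf("h%03d", 1:100),
        sprintf("v%d", 1:5)), c("I1", "I2", "U1", "U2")))
    lab <- setNames(rep(c("host", "virus"), c(100, 5)), rownames(m))
    sp <- splitPanels(m, lab)
    expect_equal(nrow(sp$host), 100)
    expect_equal(nrow(sp$virus), 5)
    expect_setequal(c(rownames(sp$host), rownames(sp$virus)), rownames(m))

    spAll <- splitPanels(m, setNames(rep("host", 105), rownames(m)))
    expect_equal(nrow(spAll$virus), 0)
    expect_error(splitPanels(m, lab[-1]), "unlabeled")
})

test_that("quantile normalization equalizes column distributions exactly", {
    m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
    rownames(m) <- c("g1", "g2", "g3")
    q <- quantileNormalize(m)
    expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))

    same <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
    expect_equal(quantileNormalize(same), same)

    set.seed(33)
    r <- matrix(rnorm(300 * 4, 8, 2), 300, 4,
        dimnames = list(sprintf("g%03d", 1:300), c("I1", "I2", "U1", "U2")))
    qn <- quantileNormalize(r)
    ref <- sort(qn[, 1])
    for (j in 2:4) expect_equal(unname(sort(qn[, j])), unname(ref))
    expect_error(quantileNormalize(r[, 1, drop = FALSE]), "2 samples")
})

test_that("replicate correlations hit the exact and accounting values", {
    x <- rnorm(200, 8, 2)
    m <- cbind(I1 = x, I2 = x, U1 = -x + 2 * mean(x), U2 = rep(1, 200))
    rownames(m) <- sprintf("g%03d", 1:200)
    r <- replicateCorrelation(m, list(c("I1", "I2"), c("I1", "U1"),
        c("I1", "U2")))
    expect_equal(unname(r[1]), 1.000)
    expect_equal(unname(r[2]), -1.000)
    expect_true(is.na(r[3]))

    set.seed(34)
    sig <- rnorm(2000, 10, 2)
    noisy <- cbind(I1 = sig + rnorm(2000, 0, 0.1),
        I2 = sig + rnorm(2000, 0, 0.1))
    rownames(noisy) <- sprintf("g%04d", 1:2000)
    rr <- replicateCorrelation(noisy, list(c("I1", "I2")))
    # r ~ sigma_signal^2 / (sigma_signal^2 + sigma_noise^2) = 0.9975
    expect_gte(rr[[1]], 0.995)
    expect_lte(rr[[1]], 0.999)
})

test_that("two-group fit matches hand-computed pooled statistics", {
    m <- matrix(c(4, 6, 1, 3), 1, 4,
        dimnames = list("g1", c("I1", "I2", "U1", "U2")))
    f <- fitTwoGroup(m, cond2v2)
    expect_equal(f$logFC, 3.0)
    expect_equal(f$s2, 2.0)
    expect_equal(f$df_resid, 2L)

    same <- matrix(c(5, 5, 5, 5), 1, 4,
        dimnames = list("g1", colnames(m)))
    fs <- fitTwoGroup(same, cond2v2)
    expect_equal(fs$logFC, 0)
    expect_equal(fs$s2, 0)

    shifted <- fitTwoGroup(m + 7, cond2v2)
    expect_equal(shifted$logFC, f$logFC)
    expect_equal(shifted$s2, f$s2)
    expect_error(fitTwoGroup(m[, 1:3],
        c("infected", "infected", "uninfected")), "replicates")
})

test_that("empirical-Bayes moderation matches the reference implementation", {
    set.seed(35)
    m <- matrix(rnorm(300 * 4, 8, 1), 300, 4,
        dimnames = list(sprintf("g%03d", 1:300), c("I1", "I2", "U1", "U2")))
    m[1:20, 1:2] <- m[1:20, 1:2] + 2
    fit <- fitTwoGroup(m, cond2v2)
    mod <- moderateFit(fit)
    lf <- limma::eBayes(limma::lmFit(m, cbind(1, c(1, 1, 0, 0))))
    expect_equal(mod$params$d0, lf$df.prior, tolerance = 1e-8)
    expect_equal(mod$params$s0_sq, lf$s2.prior, tolerance = 1e-8)
    expect_equal(mod$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-10)
    expect_equal(mod$table$p, unname(lf$p.value[, 2]), tolerance = 1e-10)
    expect_equal(mod$table$logFC, unname(lf$coefficients[, 2]),
        tolerance = 1e-10)
})

test_that("moderation limits behave as closed forms predict", {
    # equal variances: infinite prior df, z-like statistic from s0 alone
    set.seed(36)
    base <- matrix(rnorm(50 * 2, 8, 1), 50, 2)
    m <- cbind(base[, 1], base[, 1] + 1, base[, 2], base[, 2] + 1)
    dimnames(m) <- list(sprintf("g%02d", 1:50), c("I1", "I2", "U1", "U2"))
    # every gene has identical within-group spread -> identical s2
    fit <- fitTwoGroup(m, cond2v2)
    expect_equal(var(fit$s2), 0)
    mod <- moderateFit(fit)
    expect_equal(mod$params$d0, Inf)
    expect_equal(mod$table$t_mod,
        fit$logFC / sqrt(mod$params$s0_sq * (1 / 2 + 1 / 2)))
    expect_true(all(mod$table$s2_post == mod$params$s0_sq))
})

test_that("null 2v2 moderated inference controls type-I error and FDR", {
    set.seed(37)
    n <- 10000
    m <- matrix(rnorm(n * 4, 8, 0.25), n, 4,
        dimnames = list(sprintf("g%05d", 1:n), c("I1", "I2", "U1", "U2")))
    fit <- fitTwoGroup(m, cond2v2)
    mod <- moderateFit(fit)
    rawRate <- mean(mod$table$p < 0.05)
    expect_gte(rawRate, 0.04)
    expect_lte(rawRate, 0.06)
    expect_lte(mean(bhAdjust(mod$table$p) < 0.05), 0.05)
})

test_that("BH adjustment equals the step-up formula and is order-invariant", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)))

    stepUp <- function(p) {  # direct formula oracle
        n <- length(p)
        o <- order(p)
        adj <- numeric(n)
        running <- Inf
        for (i in n:1) {
            running <- min(running, n * p[o[i]] / i, 1)
            adj[o[i]] <- running
        }
        adj
    }
    set.seed(38)
    for (rep in 1:5) {
        p <- runif(sample(5:50, 1))^2
        expect_equal(bhAdjust(p), stepUp(p))
        perm <- sample(seq_along(p))
        expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
        expect_true(all(diff(bhAdjust(sort(p))) >= -1e-15))
    }
})

test_that("DE classification reproduces printed summary percentages", {
    expect_equal(deSummaryPercent(5709, 27400), 20.84)
    expect_equal(deSummaryPercent(5313, 27400), 19.39)
    expect_equal(deSummaryPercent(1062, 27400), 3.88)
    expect_equal(deSummaryPercent(442, 27400), 1.61)

    tab <- data.frame(gene_id = paste0("g", 1:4),
        logFC = c(2, -2, 0.5, -0.5), p_adj = c(0.01, 0.01, 0.01, 0.9))
    cls <- classifyDE(tab)
    expect_equal(unname(cls$calls),
        c("up", "down", "up", "unchanged"))
    expect_equal(cls$summary$n_up_fc, 1)
    expect_equal(cls$summary$n_down_fc, 1)

    none <- classifyDE(data.frame(gene_id = "g", logFC = 3, p_adj = 1))
    expect_equal(none$summary$n_up + none$summary$n_down, 0)
})

test_that("moderated inference beats the ordinary t at 2v2 for the same FDR", {
    tpMod <- 0L; tpOrd <- 0L
    for (seed in 1:20) {
        set.seed(400 + seed)
        n <- 800; nDE <- 40
        m <- matrix(rnorm(n * 4, 10, 0.25), n, 4,
            dimnames = list(sprintf("g%03d", 1:n),
                c("I1", "I2", "U1", "U2")))
        de <- seq_len(nDE)
        m[de, 1:2] <- m[de, 1:2] + 2
        fit <- fitTwoGroup(m, cond2v2)
        mod <- moderateFit(fit)
        pm <- bhAdjust(mod$table$p)
        tOrd <- fit$logFC / sqrt(fit$s2 * (1 / 2 + 1 / 2))
        pOrd <- bhAdjust(2 * pt(-abs(tOrd), df = 2))
        tpMod <- tpMod + sum(pm[de] < 0.05)
        tpOrd <- tpOrd + sum(pOrd[de] < 0.05)
    }
    expect_gt(tpMod, tpOrd)
})

test_that("the full DE stage recovers planted direction for planted genes", {
    cfg <- generatorConfig(nTranscripts = 400, seed = 42, noiseSd = 0.25,
        deFractionUp = 0.05, deFractionDown = 0.05)
    tr <- simulateTranscriptome(cfg)
    panel <- designProbes(tr, nControls = 40, seed = 7)
    sig <- simulateProbeSignals(tr, panel)
    oc <- inferOrientation(sig$signal, panel)
    gm <- geneSignalMatrix(sig$signal, oc)
    sp <- splitPanels(gm, setNames(tr$info$class, tr$info$id))
    de <- runDEPanel(sp$host, cond2v2)
    planted <- tr$info[tr$info$regulation != "unchanged" &
        tr$info$class == "host", ]
    got <- de$table[match(planted$id, de$table$gene_id), ]
    recovered <- mean(got$call == planted$regulation)
    expect_gte(recovered, 0.90)
})
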