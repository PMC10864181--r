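# Independent oracles and fixture builders. These deliberately avoid the
# package's own single-effect code paths: the BMA oracle enumerates causal
# configurations exhaustively under the spike-and-slab prior, and the
# individual-level oracle runs iterative Bayesian stepwise selection on raw
# data matrices.

# log N(z; 0, Sigma)
logMvn <- function(z, Sigma) {
    p <- length(z)
    ch <- chol(Sigma)
    -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
        sum(backsolve(ch, z, transpose = TRUE)^2))
}

# Exhaustive posterior over all 2^p causal configurations of the
# summary-statistics spike-and-slab model: zhat | config ~ N(0, R + R D R),
# D = diag(gamma * sigma2); prior independent Bernoulli(pi).
bmaPosterior <- function(z, R, pi, sigma2) {
    p <- length(z)
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    configs <- as.matrix(expand.grid(rep(list(0:1), p)))
    logw <- apply(configs, 1L, function(g) {
        Sigma <- R + R %*% (diag(g * sigma2, p)) %*% R
        sum(g * log(pi) + (1 - g) * log(1 - pi)) + logMvn(z, Sigma)
    })
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    list(pip = drop(crossprod(configs, w)), weights = w, configs = configs)
}

# Observed-data log-likelihood of one region under the single-effect
# (at most one causal variable) summary model:
#   P(zhat) = null_weight * N(0, R) + sum_j pi_j * N(0, R + sigma2_j R_j R_j')
# computed by direct enumeration of the p + 1 outcomes.
serRegionLoglik <- function(z, R, pi, sigma2, null_weight) {
    p <- length(z)
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    terms <- vapply(seq_len(p), function(j) {
        Sigma <- R + sigma2[j] * tcrossprod(R[, j])
        log(pi[j]) + logMvn(z, Sigma)
    }, numeric(1L))
    terms <- c(terms, log(null_weight) + logMvn(z, R))
    m <- max(terms)
    m + log(sum(exp(terms - m)))
}

# Exhaustive posterior of the sum-of-L-single-effects spike-and-slab model:
# every ordered assignment of the L effects to a variable (or the null) is
# enumerated; a variable chosen by two effects carries twice the prior
# variance. For L = 1 this is the exact single-effect posterior.
susieExactPosterior <- function(z, R, pi, sigma2, null_weight, L) {
    p <- length(z)
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    tuples <- as.matrix(expand.grid(rep(list(0:p), L)))
    w <- c(null_weight, pi)
    logw <- apply(tuples, 1L, function(t) {
        d <- tabulate(t[t > 0], nbins = p) * sigma2
        sum(log(w[t + 1L])) + logMvn(z, R + R %*% (d * R))
    })
    ww <- exp(logw - max(logw))
    ww <- ww / sum(ww)
    vapply(seq_len(p), function(j) sum(ww[apply(tuples == j, 1L, any)]), numeric(1L))
}

# Individual-level iterative Bayesian stepwise selection with known residual
# sd 1: single-effect regressions on residualized y, prior effect variance
# sigma_b2 (per variable, effect scale), prior weights pi plus a null weight.
susieIndividual <- function(X, y, pi, sigma_b2, null_weight, L = 5L,
                            maxIter = 200L, tol = 1e-10) {
    p <- ncol(X)
    if (length(sigma_b2) == 1L) sigma_b2 <- rep(sigma_b2, p)
    d <- colSums(X^2)
    alpha <- matrix(0, L, p)
    mu1 <- matrix(0, L, p)
    for (iter in seq_len(maxIter)) {
        alpha_prev <- alpha
        for (l in seq_len(L)) {
            b_other <- colSums((alpha * mu1)[-l, , drop = FALSE])
            r <- y - X %*% b_other
            xtr <- drop(crossprod(X, r))
            shat2 <- 1 / d
            betahat <- xtr / d
            lbf <- dnorm(betahat, 0, sqrt(sigma_b2 + shat2), log = TRUE) -
                dnorm(betahat, 0, sqrt(shat2), log = TRUE)
            s1 <- 1 / (1 / sigma_b2 + d)
            m1 <- s1 * xtr
            lw <- c(log(pi) + lbf, log(null_weight))
            w <- exp(lw - max(lw))
            w <- w / sum(w)
            alpha[l, ] <- w[seq_len(p)]
            mu1[l, ] <- m1
        }
        if (max(abs(alpha - alpha_prev)) < tol) break
    }
    list(alpha = alpha, pip = 1 - apply(1 - alpha, 2L, prod))
}

# Standardize columns so that t(x) %*% x == n exactly (population scaling),
# as required for the sufficient-statistic substitutions.
stdCols <- function(X) {
    n <- nrow(X)
    X <- sweep(X, 2L, colMeans(X))
    sweep(X, 2L, sqrt(colSums(X^2) / n), "/")
}

# Small LD block fixture with the given variant table defaults.
makeLdBlock <- function(block_id, chrom, pos, ref, alt, corr,
                        maf = rep(0.3, length(pos))) {
    new("LDBlock",
        block_id = block_id,
        variants = data.frame(
            variant_id = paste(chrom, pos, sep = ":"),
            chrom = chrom, pos = as.integer(pos),
            allele_ref = ref, allele_alt = alt, maf = maf,
            stringsAsFactors = FALSE
        ),
        corr = corr
    )
}

makeWeightModel <- function(gene_id, chrom, pos, ref, alt, weights,
                            scale = "standardized") {
    new("WeightModel",
        gene_id = gene_id, chrom = chrom[1L], tss_pos = as.integer(pos[1L]),
        variants = data.frame(
            variant_id = paste(chrom, pos, sep = ":"),
            chrom = chrom, pos = as.integer(pos),
            allele_ref = ref, allele_alt = alt, stringsAsFactors = FALSE
        ),
        weights = weights, scale = scale
    )
}

# Correlation-matrix fixture: sample correlation of AR(1) Gaussian draws,
# well-conditioned, reproducible.
sampleCorr <- function(p, n = 400L, rho = 0.5, seed = 1L) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
        for (m in 2:p) X[, m] <- rho * X[, m - 1L] + sqrt(1 - rho^2) * X[, m]
    }
    cor(X)
}

# Tiny simulated bundle shared across pipeline tests (built once per run).
tinyBundle <- function(seed = 101L, ...) {
    simulateCtwasData(simConfig(
        n_individuals = 800L, n_blocks = 6L, variants_per_block = 40L,
        genes_per_block = 2L, pi_gene = 0.25, pi_variant = 0.02,
        pve_gene = 0.15, pve_variant = 0.15, ld_subsample = NULL,
        n_chrom = 2L, seed = seed, ...
    ))
}
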