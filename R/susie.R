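## Sum-of-single-effects regression on summary statistics (z-scores and their
## correlation matrix), with per-variable prior inclusion weights, fixed
## per-variable prior effect variances (z-score scale) and a null weight.
## Residual variance is fixed at 1: under the summary-statistics model
## zhat | z, R ~ N(R z, R), the sufficient-statistic substitutions
## X'X -> R, X'y -> zhat, y'y -> 1, n -> 1 force the unit scale.

#' Single-effect regression on summary statistics
#'
#' Bayes posterior for a regression with exactly one causal variable among
#' \code{p} candidates (plus a null "no effect" outcome), given z-scores and a
#' spike-and-slab prior.  For variable \code{j} with prior variance
#' \code{s2 = sigma2[j]}:
#' \code{lbf_j = -log(1 + s2)/2 + z_j^2 s2 / (2 (1 + s2))},
#' \code{mu1_j = z_j s2/(1 + s2)}, \code{s1sq_j = s2/(1 + s2)}, and
#' \code{alpha_j} proportional to \code{pi[j] exp(lbf_j)}, normalized jointly
#' with \code{null_weight}.
#'
#' @param z numeric vector of (residualized) z-scores.
#' @param pi prior inclusion weights per variable (nonnegative;
#'   \code{sum(pi) + null_weight} should be 1).
#' @param sigma2 prior effect variance per variable (scalar recycled), z scale.
#' @param null_weight prior mass on "no effect in this regression".
#' @return list with \code{alpha}, \code{alpha_null}, \code{mu1}, \code{s1_sq},
#'   \code{lbf} and \code{lbf_model} (log Bayes factor of the regression
#'   against the all-null model).
#' @export
serRss <- function(z, pi, sigma2, null_weight = 0) {
    p <- length(z)
    stopifnot(length(pi) == p, all(is.finite(z)), all(pi >= 0), null_weight >= 0)
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    stopifnot(length(sigma2) == p, all(sigma2 >= 0))
    if (sum(pi) + null_weight <= 0) {
        stop("all prior weights are zero")
    }
    lbf <- -0.5 * log1p(sigma2) + 0.5 * z^2 * sigma2 / (1 + sigma2)
    mu1 <- z * sigma2 / (1 + sigma2)
    s1_sq <- sigma2 / (1 + sigma2)
    lw <- c(log(pi) + lbf, log(null_weight)) # log(0) = -Inf drops the term
    m <- max(lw)
    w <- exp(lw - m)
    tot <- sum(w)
    alpha_all <- w / tot
    list(
        alpha = alpha_all[seq_len(p)],
        alpha_null = alpha_all[p + 1L],
        mu1 = mu1,
        s1_sq = s1_sq,
        lbf = lbf,
        lbf_model = m + log(tot) - log(sum(pi) + null_weight)
    )
}

#' Sum-of-single-effects fine-mapping on summary statistics
#'
#' Iterative Bayesian stepwise fit of \code{L} single effects: for each effect
#' \code{l}, the z-scores are residualized against the posterior mean of the
#' other effects, \code{ztilde = z - R \%*\% colSums(alpha * mu1)[-l]}, a
#' single-effect regression (\code{\link{serRss}}) is applied, and the cycle
#' repeats until the maximum absolute change in \code{alpha} drops below
#' \code{tol} or \code{maxIter} is reached.  Prior variances stay fixed at
#' their group values throughout (empirical-Bayes usage); per-variable PIPs
#' are \code{1 - prod_l (1 - alpha[l, j])}.
#'
#' @param z z-score vector.
#' @param R correlation matrix among the variables (genes and variants).
#' @param pi per-variable prior inclusion weights.
#' @param sigma2 per-variable prior effect variances (z scale; scalar
#'   recycled).
#' @param null_weight prior mass per effect on "no effect"; defaults to
#'   \code{1 - sum(pi)}.  If \code{sum(pi) > 1} the weights are renormalized
#'   to \code{1 - 1e-6} with a warning.
#' @param L maximum number of causal effects (default 5).
#' @param maxIter,tol convergence controls on \code{max |delta alpha|}.
#' @param variable_ids,group optional labels stored in the fit.
#' @return a \code{\link{SusieFit}}.
#' @export
susieRss <- function(z, R, pi, sigma2, null_weight = NULL, L = 5L,
                     maxIter = 100L, tol = 1e-3,
                     variable_ids = NULL, group = NULL) {
    p <- length(z)
    stopifnot(all(dim(R) == p), length(pi) == p)
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    if (sum(pi) >= 1 && is.null(null_weight)) {
        warning("sum of prior weights >= 1; renormalizing to leave null weight 1e-6")
        pi <- pi * (1 - 1e-6) / sum(pi)
        null_weight <- 1e-6
    }
    if (is.null(null_weight)) null_weight <- 1 - sum(pi)
    if (is.null(variable_ids)) variable_ids <- as.character(seq_len(p))
    if (is.null(group)) group <- rep("variant", p)

    L <- as.integer(L)
    alpha <- matrix(0, L, p)
    alpha_null <- rep(1, L)
    mu1 <- matrix(0, L, p)
    lbf <- matrix(0, L, p)
    bbar <- matrix(0, L, p) # per-effect posterior mean contribution alpha * mu1
    converged <- FALSE
    deltas <- numeric(0)
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        alpha_prev <- alpha
        for (l in seq_len(L)) {
            others <- colSums(bbar[-l, , drop = FALSE])
            ztilde <- z - drop(R %*% others)
            ser <- serRss(ztilde, pi, sigma2, null_weight)
            alpha[l, ] <- ser$alpha
            alpha_null[l] <- ser$alpha_null
            mu1[l, ] <- ser$mu1
            lbf[l, ] <- ser$lbf
            bbar[l, ] <- ser$alpha * ser$mu1
        }
        deltas[iter] <- max(abs(alpha - alpha_prev))
        if (deltas[iter] < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged) {
        warning("susieRss did not converge in ", maxIter, " iterations (max delta ",
                signif(deltas[length(deltas)], 3), ")")
    }
    pip <- 1 - apply(1 - alpha, 2L, prod)
    pip[pip < 0] <- 0
    pip[pip > 1] <- 1
    new("SusieFit",
        variable_ids = variable_ids,
        group = group,
        alpha = alpha,
        alpha_null = alpha_null,
        mu1 = mu1,
        lbf = lbf,
        pip = pip,
        sets = list(),
        converged = converged,
        niter = iter,
        delta_trace = deltas
    )
}

#' Purity-filtered credible sets of a fit
#'
#' For each effect, the smallest set of variables (by decreasing per-effect
#' inclusion probability) whose cumulative probability reaches
#' \code{coverage}.  Effects whose variable mass cannot reach coverage (mass
#' sits on the null) yield no set.  Sets whose minimum absolute pairwise
#' correlation (purity) is at or below \code{purity} are dropped, and
#' duplicate sets are reported once.
#'
#' @param fit a \code{\link{SusieFit}}.
#' @param corr correlation matrix over the fit's variables.
#' @param coverage target coverage (default 0.95).
#' @param purity minimum absolute pairwise correlation required strictly
#'   above this value (default 0.5).
#' @param prefix credible-set id prefix (typically the region id).
#' @return the fit with its \code{sets} slot populated; each set is a list
#'   with \code{cs_id}, \code{members}, \code{coverage} (attained), and
#'   \code{purity}.
#' @export
credibleSets <- function(fit, corr, coverage = 0.95, purity = 0.5, prefix = "cs") {
    stopifnot(is(fit, "SusieFit"), all(dim(corr) == length(fit@variable_ids)))
    sets <- list()
    seen <- character(0)
    for (l in seq_len(nrow(fit@alpha))) {
        a <- fit@alpha[l, ]
        ord <- order(a, decreasing = TRUE)
        cum <- cumsum(a[ord])
        if (cum[length(cum)] < coverage) next # effect is mostly null
        k <- which(cum >= coverage)[1L]
        members <- sort(ord[seq_len(k)])
        key <- paste(members, collapse = ",")
        if (key %in% seen) next
        sub <- abs(corr[members, members, drop = FALSE])
        pur <- min(sub)
        if (pur <= purity) next
        seen <- c(seen, key)
        sets[[length(sets) + 1L]] <- list(
            cs_id = sprintf("%s:L%d", prefix, l),
            members = fit@variable_ids[members],
            coverage = cum[k],
            purity = pur
        )
    }
    fit@sets <- sets
    fit
}

#' Fine-map one augmented region under group priors
#'
#' Runs \code{\link{susieRss}} on an \code{\link{AugmentedRegion}} with prior
#' inclusion weights and prior variances set per variable group from a
#' \code{\link{GroupPriorEstimate}}, and attaches purity-filtered credible
#' sets.
#'
#' @param region an \code{\link{AugmentedRegion}}.
#' @param theta a \code{\link{GroupPriorEstimate}}.
#' @param L number of effects (default 5).
#' @param thinnedVariants logical; \code{TRUE} when the region's variant set
#'   is the thinned one (use the thinned-scale variant prior), \code{FALSE}
#'   for the full set (variant prior rescaled by the thin factor).
#' @param coverage,purity credible-set parameters.
#' @param ... passed to \code{\link{susieRss}}.
#' @return a \code{\link{SusieFit}} with credible sets.
#' @export
finemapRegion <- function(region, theta, L = 5L, thinnedVariants = TRUE,
                          coverage = 0.95, purity = 0.5, ...) {
    pi_v <- if (thinnedVariants) theta@pi_variant else theta@pi_variant * theta@thin
    pi <- ifelse(region@group == "gene", theta@pi_gene, pi_v)
    sigma2 <- ifelse(region@group == "gene", theta@sigma2_gene, theta@sigma2_variant)
    fit <- susieRss(region@z, region@corr, pi, sigma2,
        L = L, variable_ids = region@variable_ids, group = region@group, ...
    )
    credibleSets(fit, region@corr,
        coverage = coverage, purity = purity, prefix = region@region_id
    )
}
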