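## Empirical-Bayes estimation of the group-level spike-and-slab prior
## parameters theta = (pi_gene, pi_variant, sigma2_gene, sigma2_variant) by EM
## over regions, each region evaluated under a single-effect (L = 1)
## approximation on thinned variants.

#' E-step for one region
#'
#' Runs a single-effect regression (\code{\link{serRss}}) on the region's
#' augmented z-scores with prior weights set by group membership and null
#' weight \code{1 - sum(pi)}, returning the per-variable posterior inclusion
#' probabilities \code{alpha} and the posterior second moments of the effect
#' given inclusion, \code{tau2 = mu1^2 + s1_sq}.
#'
#' @param region an \code{\link{AugmentedRegion}} (thinned variant set).
#' @param pi_gene,pi_variant current prior inclusion probabilities.
#' @param sigma2_gene,sigma2_variant current prior effect variances (z scale).
#' @return list with \code{alpha}, \code{tau2} and the region's \code{group}
#'   labels.
#' @export
eStepRegion <- function(region, pi_gene, pi_variant, sigma2_gene, sigma2_variant) {
    if (pi_gene <= 0 && pi_variant <= 0) {
        stop("degenerate prior: both group inclusion probabilities are zero")
    }
    pi <- ifelse(region@group == "gene", pi_gene, pi_variant)
    s2 <- ifelse(region@group == "gene", sigma2_gene, sigma2_variant)
    tot <- sum(pi)
    if (tot >= 1) {
        pi <- pi * (1 - 1e-6) / tot # pathological: renormalize, keep tiny null
        null_weight <- 1e-6
    } else {
        null_weight <- 1 - tot
    }
    ser <- serRss(region@z, pi, s2, null_weight)
    list(
        alpha = ser$alpha,
        tau2 = ser$mu1^2 + ser$s1_sq,
        group = region@group
    )
}

#' M-step: update group priors from pooled posteriors
#'
#' The new inclusion probability of group k is the average posterior
#' inclusion probability over all variables of the group; the new prior
#' variance is the alpha-weighted average of the posterior second moments.
#' A group with zero posterior mass keeps its previous variance.
#'
#' @param alpha numeric vector of posterior inclusion probabilities pooled
#'   over regions.
#' @param tau2 matching posterior second moments.
#' @param group matching group labels (\code{"gene"}/\code{"variant"}).
#' @param group_sizes named counts of variables per group (denominator of the
#'   pi update).
#' @param prev_sigma2 named fallbacks (\code{gene}, \code{variant}) for groups
#'   with no posterior mass.
#' @return list with \code{pi_gene}, \code{pi_variant}, \code{sigma2_gene},
#'   \code{sigma2_variant}.
#' @export
mStep <- function(alpha, tau2, group, group_sizes,
                  prev_sigma2 = c(gene = 0, variant = 0)) {
    upd <- function(g) {
        a <- alpha[group == g]
        t2 <- tau2[group == g]
        n <- group_sizes[[g]]
        pi_k <- if (n > 0) sum(a) / n else 0
        s2_k <- if (sum(a) > 0) sum(a * t2) / sum(a) else unname(prev_sigma2[[g]])
        c(pi = min(pi_k, 1), sigma2 = s2_k)
    }
    gg <- upd("gene")
    vv <- upd("variant")
    list(
        pi_gene = unname(gg["pi"]), pi_variant = unname(vv["pi"]),
        sigma2_gene = unname(gg["sigma2"]), sigma2_variant = unname(vv["sigma2"])
    )
}

#' Fit group priors by EM over regions
#'
#' Alternates \code{\link{eStepRegion}} over all supplied (thinned) regions
#' and \code{\link{mStep}} for a fixed number of iterations (the default
#' mirrors routine practice: 30 iterations at L = 1 on 10\%-thinned
#' variants).  Regions with more than \code{estimationCap} variables are
#' skipped during estimation only; their variables enter neither numerator
#' nor denominator of the updates.
#'
#' @param regions list of \code{\link{AugmentedRegion}} objects built on the
#'   thinned variant sets.
#' @param nIter number of EM iterations (default 30).
#' @param init named list overriding the starting values \code{pi_gene},
#'   \code{pi_variant}, \code{sigma2_gene}, \code{sigma2_variant}.  By default
#'   the variant prior starts at \code{expectedCausal / p} (p = number of
#'   variant variables seen), the gene prior equal to it, and both variances
#'   at 50 on the z scale.
#' @param expectedCausal prior expected number of causal variants used for the
#'   default initialization (default 50).
#' @param estimationCap skip regions with more than this many variables
#'   (default 10000).
#' @param thin thinning fraction the regions were built with (recorded in the
#'   estimate; default 1).
#' @param tolerance optional early-stop: halt when every parameter moves by
#'   less than this relative amount (default \code{NULL}, fixed-iteration).
#' @return a \code{\link{GroupPriorEstimate}} with full trajectory.
#' @export
fitPriors <- function(regions, nIter = 30L, init = list(), expectedCausal = 50,
                      estimationCap = 10000L, thin = 1, tolerance = NULL) {
    stopifnot(length(regions) > 0L)
    sizes <- vapply(regions, function(r) length(r@variable_ids), integer(1L))
    use <- sizes <= estimationCap
    if (!any(use)) stop("all regions exceed the estimation cap")
    regions <- regions[use]
    group <- unlist(lapply(regions, function(r) r@group), use.names = FALSE)
    group_sizes <- c(
        gene = sum(group == "gene"),
        variant = sum(group == "variant")
    )
    if (group_sizes[["variant"]] == 0L) {
        stop("no variant variables available for estimation")
    }
    pi_v0 <- min(0.5, expectedCausal / group_sizes[["variant"]])
    theta <- list(
        pi_gene = init$pi_gene %||% pi_v0,
        pi_variant = init$pi_variant %||% pi_v0,
        sigma2_gene = init$sigma2_gene %||% 50,
        sigma2_variant = init$sigma2_variant %||% 50
    )
    traj <- vector("list", nIter)
    for (it in seq_len(nIter)) {
        es <- lapply(regions, function(r) {
            eStepRegion(r, theta$pi_gene, theta$pi_variant,
                        theta$sigma2_gene, theta$sigma2_variant)
        })
        alpha <- unlist(lapply(es, `[[`, "alpha"), use.names = FALSE)
        tau2 <- unlist(lapply(es, `[[`, "tau2"), use.names = FALSE)
        prev <- theta
        theta <- mStep(alpha, tau2, group, as.list(group_sizes),
                       prev_sigma2 = c(gene = prev$sigma2_gene,
                                       variant = prev$sigma2_variant))
        if (max(theta$sigma2_gene, theta$sigma2_variant) > 1e8) {
            stop("prior variance diverged (> 1e8) at iteration ", it)
        }
        traj[[it]] <- data.frame(iteration = it,
                                 pi_gene = theta$pi_gene,
                                 pi_variant = theta$pi_variant,
                                 sigma2_gene = theta$sigma2_gene,
                                 sigma2_variant = theta$sigma2_variant)
        if (!is.null(tolerance)) {
            rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
            if (max(rel(theta$pi_gene, prev$pi_gene),
                    rel(theta$pi_variant, prev$pi_variant),
                    rel(theta$sigma2_gene, prev$sigma2_gene),
                    rel(theta$sigma2_variant, prev$sigma2_variant)) < tolerance) {
                traj <- traj[seq_len(it)]
                break
            }
        }
    }
    new("GroupPriorEstimate",
        pi_gene = theta$pi_gene,
        pi_variant = theta$pi_variant,
        sigma2_gene = theta$sigma2_gene,
        sigma2_variant = theta$sigma2_variant,
        thin = thin,
        group_sizes = c(gene = unname(group_sizes[["gene"]]),
                        variant = unname(group_sizes[["variant"]])),
        trajectory = do.call(rbind, traj)
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
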