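## Proportion of phenotypic variance explained per variable group. On the
## z-score scale the expected squared effect of a causal variable in group k
## is sigma2_k, its PVE is sigma2_k / n, and the expected causal count is
## pi_k * |M_k|, giving PVE_k = sigma2_k * pi_k * |M_k| / n.

#' PVE of one variable group
#'
#' Exact product formula \code{sigma2_k * pi_k * group_size / n} for the
#' proportion of phenotypic variance explained by a group of variables under
#' the spike-and-slab prior, with \code{sigma2_k} on the z-score scale.
#'
#' @param sigma2_k prior effect variance (z scale).
#' @param pi_k prior inclusion probability.
#' @param group_size number of variables in the group.
#' @param n GWAS sample size (must be >= 1).
#' @return the group PVE.
#' @examples
#' groupPve(100, 0.01, 1000, 10000) # 0.1
#' @export
groupPve <- function(sigma2_k, pi_k, group_size, n) {
    stopifnot(sigma2_k >= 0, pi_k >= 0, group_size >= 0)
    if (n < 1) stop("sample size n must be >= 1")
    sigma2_k * pi_k * group_size / n
}

#' PVE report from fitted group priors
#'
#' Computes the per-group PVE via \code{\link{groupPve}} and the fraction of
#' explained variance attributable to gene expression,
#' \code{pve_gene / (pve_gene + pve_variant)} (NA when both are zero).
#' The variant group uses the estimation-stage (thinned) group size with the
#' thinned-scale prior, which equals the full-set product.
#'
#' @param theta a \code{\link{GroupPriorEstimate}}.
#' @param n GWAS sample size.
#' @return a \code{\link{PveReport}}.
#' @export
pveReport <- function(theta, n) {
    stopifnot(is(theta, "GroupPriorEstimate"))
    pg <- groupPve(theta@sigma2_gene, theta@pi_gene, theta@group_sizes[["gene"]], n)
    pv <- groupPve(theta@sigma2_variant, theta@pi_variant, theta@group_sizes[["variant"]], n)
    tot <- pg + pv
    new("PveReport",
        pve_gene = pg,
        pve_variant = pv,
        total = tot,
        attributable_to_expression = if (tot > 0) pg / tot else NA_real_,
        n_gwas = as.integer(n)
    )
}

#' Serialize a fit's reports to a list (for YAML/JSON audit output)
#'
#' @param fit a \code{\link{CtwasFit}}.
#' @return a plain list with prior estimates, trajectory and PVE report.
#' @export
reportList <- function(fit) {
    th <- fit@priors
    pv <- fit@pve
    list(
        priors = list(
            pi_gene = th@pi_gene,
            pi_variant_thinned = th@pi_variant,
            pi_variant_full = th@pi_variant * th@thin,
            sigma2_gene = th@sigma2_gene,
            sigma2_variant = th@sigma2_variant,
            enrichment = enrichment(th),
            thin = th@thin,
            group_sizes = as.list(th@group_sizes)
        ),
        trajectory = th@trajectory,
        pve = list(
            pve_gene = pv@pve_gene,
            pve_variant = pv@pve_variant,
            total = pv@total,
            attributable_to_expression = pv@attributable_to_expression,
            n_gwas = pv@n_gwas
        ),
        log = fit@log
    )
}
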