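#' Per-variable posterior inclusion probabilities
#'
#' @param object a \code{\link{SusieFit}} or \code{\link{CtwasFit}}.
#' @return named numeric vector of PIPs (for \code{CtwasFit}, over all
#'   variables in the results table).
#' @export
setGeneric("pip", function(object) standardGeneric("pip"))

#' Prior enrichment of genes over variants
#'
#' Ratio of the per-gene to the per-variant prior inclusion probability,
#' with the variant prior expressed on the full (unthinned) variant scale.
#'
#' @param object a \code{\link{GroupPriorEstimate}} or \code{\link{CtwasFit}}.
#' @return numeric scalar \code{pi_gene / (pi_variant * thin)}.
#' @export
setGeneric("enrichment", function(object) standardGeneric("enrichment"))

#' Credible sets of a fit
#'
#' @param object a \code{\link{SusieFit}} or \code{\link{CtwasFit}}.
#' @param ... unused.
#' @return list of credible sets (each a list with \code{members},
#'   \code{coverage}, \code{purity}, \code{cs_id}).
#' @export
setGeneric("credibleSetsOf", function(object, ...) standardGeneric("credibleSetsOf"))

#' @rdname pip
#' @export
setMethod("pip", "SusieFit", function(object) {
    setNames(object@pip, object@variable_ids)
})

#' @rdname pip
#' @export
setMethod("pip", "CtwasFit", function(object) {
    setNames(object@results$PIP, object@results$variable_id)
})

#' @rdname enrichment
#' @export
setMethod("enrichment", "GroupPriorEstimate", function(object) {
    object@pi_gene / (object@pi_variant * object@thin)
})

#' @rdname enrichment
#' @export
setMethod("enrichment", "CtwasFit", function(object) enrichment(object@priors))

#' @rdname credibleSetsOf
#' @export
setMethod("credibleSetsOf", "SusieFit", function(object, ...) object@sets)

#' @rdname credibleSetsOf
#' @export
setMethod("credibleSetsOf", "CtwasFit", function(object, ...) {
    sets <- lapply(object@fits, function(f) f@sets)
    unlist(unname(sets), recursive = FALSE)
})

setMethod("show", "WeightModel", function(object) {
    cat(sprintf(
        "WeightModel %s (%s:%d): %d variant(s), scale=%s\n",
        object@gene_id, object@chrom, object@tss_pos,
        nrow(object@variants), object@scale
    ))
})

setMethod("show", "LDBlock", function(object) {
    cat(sprintf("LDBlock %s: %d variants\n", object@block_id, nrow(object@variants)))
})

setMethod("show", "RegionIndex", function(object) {
    cat(sprintf(
        "RegionIndex: %d regions, %d variants, %d genes (%d gene(s) rejected)\n",
        nrow(object@regions),
        length(unlist(object@region_variants, use.names = FALSE)),
        length(unlist(object@region_genes, use.names = FALSE)),
        length(object@rejected_genes)
    ))
})

setMethod("show", "AugmentedRegion", function(object) {
    cat(sprintf(
        "AugmentedRegion %s: %d genes + %d variants, n_gwas=%d\n",
        object@region_id, sum(object@group == "gene"),
        sum(object@group == "variant"), object@n_gwas
    ))
})

setMethod("show", "GroupPriorEstimate", function(object) {
    cat("GroupPriorEstimate (z-score scale)\n")
    cat(sprintf("  pi_gene        = %.4g\n", object@pi_gene))
    cat(sprintf(
        "  pi_variant     = %.4g (thinned scale, thin = %.3g; full scale %.4g)\n",
        object@pi_variant, object@thin, object@pi_variant * object@thin
    ))
    cat(sprintf("  sigma2_gene    = %.4g\n", object@sigma2_gene))
    cat(sprintf("  sigma2_variant = %.4g\n", object@sigma2_variant))
    cat(sprintf("  enrichment     = %.4g\n", enrichment(object)))
})

setMethod("show", "SusieFit", function(object) {
    cat(sprintf(
        "SusieFit: L=%d over %d variables; %d credible set(s); %s in %d iteration(s)\n",
        nrow(object@alpha), length(object@variable_ids), length(object@sets),
        if (object@converged) "converged" else "NOT converged", object@niter
    ))
})

setMethod("show", "PveReport", function(object) {
    cat(sprintf(
        "PveReport: gene %.4g + variant %.4g = %.4g total; %.1f%% attributable to expression (n=%d)\n",
        object@pve_gene, object@pve_variant, object@total,
        100 * object@attributable_to_expression, object@n_gwas
    ))
})

setMethod("show", "CtwasFit", function(object) {
    res <- object@results
    cat(sprintf(
        "CtwasFit: %d variables (%d genes) in %d regions; %d gene(s) at PIP > 0.8\n",
        nrow(res), sum(res$type == "gene"), nrow(object@regions@regions),
        sum(res$type == "gene" & res$PIP > 0.8, na.rm = TRUE)
    ))
    show(object@priors)
    show(object@pve)
})

setMethod("show", "SimBundle", function(object) {
    cat(sprintf(
        "SimBundle: %d blocks, %d variants, %d genes, n=%d individuals, %d causal gene(s), %d causal variant(s)\n",
        length(object@ld), nrow(object@gwas), length(object@weights),
        length(object@truth$y), nrow(object@truth$causal_genes),
        nrow(object@truth$causal_variants)
    ))
})
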