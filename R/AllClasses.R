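#' @import methods
#' @importFrom stats cor dnorm pnorm qnorm rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

.validVariantTable <- function(df, need = c("variant_id", "chrom", "pos", "allele_ref", "allele_alt")) {
    if (!is.data.frame(df)) {
        return("variant table must be a data.frame")
    }
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L) {
        return(paste0("variant table lacks columns: ", paste(miss, collapse = ", ")))
    }
    if (nrow(df) > 0L) {
        al <- c(df$allele_ref, df$allele_alt)
        if (!all(al %in% c("A", "C", "G", "T"))) {
            return("alleles must be single nucleotides in {A,C,G,T}")
        }
        if (any(df$allele_ref == df$allele_alt)) {
            return("allele_ref must differ from allele_alt")
        }
        if (any(df$pos < 1L)) {
            return("positions must be >= 1")
        }
    }
    TRUE
}

#' WeightModel: a sparse eQTL expression prediction model for one gene
#'
#' Holds the variants and weights of a gene's cis expression prediction model.
#' Weights on the \code{"standardized"} scale apply to standardized (unit
#' variance) genotypes; \code{"per_allele"} weights apply to allele dosages and
#' must be rescaled by the genotype standard deviation before use
#' (see \code{\link{standardizeWeights}}).
#'
#' @slot gene_id gene identifier.
#' @slot chrom chromosome of the gene's transcription start site.
#' @slot tss_pos transcription start site position (1-based).
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{allele_ref}, \code{allele_alt}; weights are signed with
#'   respect to the \code{allele_alt} dosage.
#' @slot weights numeric vector, one weight per variant row.
#' @slot scale \code{"standardized"} or \code{"per_allele"}.
#' @exportClass WeightModel
setClass("WeightModel",
    representation(
        gene_id = "character",
        chrom = "character",
        tss_pos = "integer",
        variants = "data.frame",
        weights = "numeric",
        scale = "character"
    )
)

setValidity("WeightModel", function(object) {
    v <- .validVariantTable(object@variants)
    if (!isTRUE(v)) return(v)
    if (nrow(object@variants) < 1L) {
        return("a weight model needs at least one variant")
    }
    if (length(object@weights) != nrow(object@variants)) {
        return("one weight per variant required")
    }
    if (!all(is.finite(object@weights))) {
        return("weights must be finite")
    }
    if (!object@scale %in% c("standardized", "per_allele")) {
        return("scale must be 'standardized' or 'per_allele'")
    }
    TRUE
})

#' LDBlock: variant correlation matrix for one LD block
#'
#' An approximately independent LD region: variant metadata plus the matrix of
#' pairwise genotype correlations (on the alternate-allele dosage scale).
#'
#' @slot block_id block identifier.
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{allele_ref}, \code{allele_alt}, \code{maf}.
#' @slot corr symmetric correlation matrix, unit diagonal, one row per variant.
#' @exportClass LDBlock
setClass("LDBlock",
    representation(
        block_id = "character",
        variants = "data.frame",
        corr = "matrix"
    )
)

setValidity("LDBlock", function(object) {
    v <- .validVariantTable(object@variants)
    if (!isTRUE(v)) return(v)
    p <- nrow(object@variants)
    if (!all(dim(object@corr) == c(p, p))) {
        return("corr dimensions must match the number of variants")
    }
    if (p > 0L) {
        if (max(abs(object@corr - t(object@corr))) > 1e-8) {
            return("corr must be symmetric (tolerance 1e-8)")
        }
        if (max(abs(diag(object@corr) - 1)) > 1e-8) {
            return("corr must have unit diagonal")
        }
        if (max(abs(object@corr)) > 1 + 1e-8) {
            return("correlations must lie in [-1, 1]")
        }
    }
    TRUE
})

#' RegionIndex: the partition of the genome into analysis regions
#'
#' Maps every harmonized variant and every retained gene to exactly one
#' analysis region.  Regions are LD blocks, merged whenever a gene's
#' prediction model spans several blocks.
#'
#' @slot regions data.frame with columns \code{region_id}, \code{chrom},
#'   \code{start}, \code{stop} (1-based, inclusive start, exclusive stop in the
#'   half-open sense of the input block table) and \code{member_blocks}
#'   (comma-separated block ids).
#' @slot region_variants named list: region id -> ordered variant ids
#'   (ascending position).
#' @slot region_genes named list: region id -> gene ids.
#' @slot rejected_genes character vector of gene ids that could not be placed
#'   (for example models spanning two chromosomes).
#' @exportClass RegionIndex
setClass("RegionIndex",
    representation(
        regions = "data.frame",
        region_variants = "list",
        region_genes = "list",
        rejected_genes = "character"
    )
)

setValidity("RegionIndex", function(object) {
    ids <- object@regions$region_id
    if (!setequal(names(object@region_variants), ids) ||
        !setequal(names(object@region_genes), ids)) {
        return("region_variants/region_genes must be named by region_id")
    }
    allv <- unlist(object@region_variants, use.names = FALSE)
    if (anyDuplicated(allv)) {
        return("regions must be disjoint in variants")
    }
    allg <- unlist(object@region_genes, use.names = FALSE)
    if (anyDuplicated(allg)) {
        return("each gene must map to exactly one region")
    }
    TRUE
})

#' AugmentedRegion: joint gene + variant summary data for one region
#'
#' The variant-level summary data of one region expanded with imputed genes:
#' the z-score vector over all variables (genes first, then variants) and the
#' full correlation matrix among them, derived from the LD reference and the
#' gene models' weights.
#'
#' @slot region_id region identifier.
#' @slot variable_ids ordered variable ids (genes first, then variants by
#'   position).
#' @slot group character vector, \code{"gene"} or \code{"variant"} per variable.
#' @slot z numeric z-score per variable.
#' @slot corr symmetric correlation matrix among the variables (PSD up to a
#'   small tolerance; repaired by eigenvalue clipping on construction).
#' @slot n_gwas GWAS sample size.
#' @exportClass AugmentedRegion
setClass("AugmentedRegion",
    representation(
        region_id = "character",
        variable_ids = "character",
        group = "character",
        z = "numeric",
        corr = "matrix",
        n_gwas = "integer"
    )
)

setValidity("AugmentedRegion", function(object) {
    p <- length(object@variable_ids)
    if (length(object@z) != p || length(object@group) != p ||
        !all(dim(object@corr) == c(p, p))) {
        return("z, group and corr must match variable_ids in dimension")
    }
    if (!all(object@group %in% c("gene", "variant"))) {
        return("group labels must be 'gene' or 'variant'")
    }
    if (p > 0L) {
        if (!all(is.finite(object@z))) return("z must be finite")
        if (max(abs(diag(object@corr) - 1)) > 1e-6) {
            return("corr must have unit diagonal")
        }
        if (max(abs(object@corr)) > 1 + 1e-8) {
            return("correlations must lie in [-1, 1] (tolerance 1e-8)")
        }
    }
    TRUE
})

#' GroupPriorEstimate: spike-and-slab prior parameters for genes and variants
#'
#' Empirical-Bayes estimates of the group-level prior inclusion probabilities
#' and prior effect-size variances (z-score scale).  \code{pi_variant} is on
#' the scale of the variant set used during estimation (the thinned set); the
#' \code{thin} slot records the thinning fraction so that the per-variant prior
#' on the full set is \code{pi_variant * thin} (see \code{\link{enrichment}}).
#'
#' @slot pi_gene prior inclusion probability per gene.
#' @slot pi_variant prior inclusion probability per thinned variant.
#' @slot sigma2_gene prior effect variance of causal genes (z scale).
#' @slot sigma2_variant prior effect variance of causal variants (z scale).
#' @slot thin thinning fraction used during estimation (1 = no thinning).
#' @slot group_sizes named numeric, numbers of gene/variant variables seen by
#'   the EM (variants counted after thinning).
#' @slot trajectory data.frame of per-iteration parameter values.
#' @exportClass GroupPriorEstimate
setClass("GroupPriorEstimate",
    representation(
        pi_gene = "numeric",
        pi_variant = "numeric",
        sigma2_gene = "numeric",
        sigma2_variant = "numeric",
        thin = "numeric",
        group_sizes = "numeric",
        trajectory = "data.frame"
    )
)

setValidity("GroupPriorEstimate", function(object) {
    if (object@pi_gene < 0 || object@pi_gene > 1 ||
        object@pi_variant < 0 || object@pi_variant > 1) {
        return("prior inclusion probabilities must lie in [0, 1]")
    }
    if (object@sigma2_gene < 0 || object@sigma2_variant < 0) {
        return("prior variances must be nonnegative")
    }
    if (object@thin <= 0 || object@thin > 1) {
        return("thin must lie in (0, 1]")
    }
    if (!all(c("gene", "variant") %in% names(object@group_sizes))) {
        return("group_sizes must name 'gene' and 'variant'")
    }
    TRUE
})

#' SusieFit: a sum-of-single-effects fine-mapping fit
#'
#' Posterior summary of an L-effect fine-mapping fit on one region: per-effect
#' inclusion probabilities, posterior means, per-variable PIPs and (after
#' \code{\link{credibleSets}}) purity-filtered credible sets.
#'
#' @slot variable_ids variable ids (columns of \code{alpha}).
#' @slot group \code{"gene"}/\code{"variant"} per variable.
#' @slot alpha L x p matrix of per-effect posterior inclusion probabilities
#'   (rows need not sum to 1; the remainder is the null weight).
#' @slot alpha_null per-effect posterior mass on the null.
#' @slot mu1 L x p posterior mean effect given inclusion.
#' @slot lbf L x p per-variable log Bayes factors of the final iteration.
#' @slot pip per-variable posterior inclusion probability,
#'   \code{1 - prod_l(1 - alpha[l, j])}.
#' @slot sets list of credible sets (possibly empty; see
#'   \code{\link{credibleSets}}).
#' @slot converged logical.
#' @slot niter iterations run.
#' @slot delta_trace per-iteration max absolute change in \code{alpha}.
#' @exportClass SusieFit
setClass("SusieFit",
    representation(
        variable_ids = "character",
        group = "character",
        alpha = "matrix",
        alpha_null = "numeric",
        mu1 = "matrix",
        lbf = "matrix",
        pip = "numeric",
        sets = "list",
        converged = "logical",
        niter = "integer",
        delta_trace = "numeric"
    )
)

setValidity("SusieFit", function(object) {
    p <- length(object@variable_ids)
    if (ncol(object@alpha) != p || length(object@pip) != p) {
        return("alpha and pip must match variable_ids")
    }
    if (any(object@pip < -1e-12) || any(object@pip > 1 + 1e-12)) {
        return("PIPs must lie in [0, 1]")
    }
    TRUE
})

#' PveReport: phenotypic variance explained per variable group
#'
#' @slot pve_gene proportion of phenotypic variance explained by gene effects.
#' @slot pve_variant proportion explained by direct variant effects.
#' @slot total their sum.
#' @slot attributable_to_expression pve_gene / total (NA when total is 0).
#' @slot n_gwas GWAS sample size used.
#' @exportClass PveReport
setClass("PveReport",
    representation(
        pve_gene = "numeric",
        pve_variant = "numeric",
        total = "numeric",
        attributable_to_expression = "numeric",
        n_gwas = "integer"
    )
)

#' CtwasFit: results of a full causal-TWAS run
#'
#' @slot results data.frame of per-variable results (variable_id, type,
#'   region_id, z, PIP, credible_set_id, in_rescue_pass).
#' @slot priors the fitted \code{\link{GroupPriorEstimate}}.
#' @slot pve the \code{\link{PveReport}}.
#' @slot fits named list of final per-region \code{\link{SusieFit}} objects.
#' @slot regions the \code{\link{RegionIndex}} used.
#' @slot augmented named list of the final per-region
#'   \code{\link{AugmentedRegion}} objects (needed for credible-set based
#'   attribution analyses).
#' @slot log named list of run diagnostics (dropped-variant counts, rescue
#'   region ids, seeds).
#' @exportClass CtwasFit
setClass("CtwasFit",
    representation(
        results = "data.frame",
        priors = "GroupPriorEstimate",
        pve = "PveReport",
        fits = "list",
        regions = "RegionIndex",
        augmented = "list",
        log = "list"
    )
)

#' SimBundle: a simulated genome-lite dataset with ground truth
#'
#' Everything a causal-TWAS run consumes, generated under the generative model
#' itself, plus the simulation truth for evaluation.
#'
#' @slot genotypes named list of integer dosage matrices (individuals x
#'   variants), one per LD block.
#' @slot blocks data.frame of block definitions (chrom, start, stop, block_id;
#'   half-open 0-based, the on-disk convention).
#' @slot ld named list of \code{\link{LDBlock}} objects (in-sample LD from a
#'   subsample of individuals).
#' @slot gwas data.frame of variant summary statistics (variant_id, chrom, pos,
#'   allele_ref, allele_alt, z, n).
#' @slot weights named list of \code{\link{WeightModel}} objects.
#' @slot truth list: causal_genes / causal_variants data.frames (id, effect),
#'   y, realized per-group PVE, residual sd, and the config used.
#' @exportClass SimBundle
setClass("SimBundle",
    representation(
        genotypes = "list",
        blocks = "data.frame",
        ld = "list",
        gwas = "data.frame",
        weights = "list",
        truth = "list"
    )
)
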