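## Expansion of variant-level summary data with imputed genes: gene z-scores
## from eQTL weights and variant z-scores, and the joint correlation matrix
## among genes and variants in a region. All quantities are on the
## standardized scale: a gene variable is its standardized imputed expression,
## so its correlation with anything is the weight-combination correlation
## normalized by sqrt(w' R w).

#' z-score of a gene's imputed expression
#'
#' The marginal association z-score of the standardized imputed expression of
#' a gene with the trait: \code{t(w) z / sqrt(t(w) R w)}, where \code{w} are
#' standardized-scale eQTL weights, \code{z} the variant z-scores at the model
#' variants and \code{R} their LD.
#'
#' @param w numeric weight vector (standardized scale).
#' @param z_v variant z-scores, aligned to \code{w}.
#' @param R_v LD matrix of the model variants.
#' @param varFloor genes whose imputation variance \code{t(w) R w} falls at or
#'   below this floor are degenerate and rejected (returns \code{NA}).
#' @return the gene z-score, or \code{NA_real_} for degenerate models.
#' @export
geneZ <- function(w, z_v, R_v, varFloor = 1e-10) {
    stopifnot(length(w) == length(z_v), all(dim(R_v) == length(w)))
    v <- drop(crossprod(w, R_v %*% w))
    if (!is.finite(v) || v <= varFloor) return(NA_real_)
    drop(crossprod(w, z_v)) / sqrt(v)
}

## Assemble the LD matrix over an ordered set of variants spread over one or
## more member blocks of a (possibly merged) region. Cross-block correlations
## default to 0 (blocks are approximately independent).
.assembleRegionLD <- function(variant_ids, ld_blocks) {
    p <- length(variant_ids)
    R <- matrix(0, p, p)
    found <- rep(FALSE, p)
    for (b in ld_blocks) {
        idx <- match(b@variants$variant_id, variant_ids)
        here <- !is.na(idx)
        if (!any(here)) next
        R[idx[here], idx[here]] <- b@corr[here, here]
        found[idx[here]] <- TRUE
    }
    if (!all(found)) {
        stop("variants absent from the LD blocks: ",
             paste(utils::head(variant_ids[!found], 5L), collapse = ", "))
    }
    diag(R) <- 1
    R
}

## Clip negative eigenvalues to zero and renormalize to unit diagonal.
.psdClip <- function(R, tol = 1e-6) {
    R <- (R + t(R)) / 2
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) >= -tol) return(R)
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(pmax(diag(R), .Machine$double.eps))
    R <- R / tcrossprod(d)
    diag(R) <- 1
    (R + t(R)) / 2
}

#' Build the gene-augmented summary data of a region
#'
#' Expands a region's variant-level z-scores and LD with its genes: computes
#' each gene's z-score via \code{\link{geneZ}}, the gene-variant correlations
#' \code{t(w) R e_m / sqrt(t(w) R w)} and gene-gene correlations
#' \code{t(w_g) R w_h / (sqrt(t(w_g) R w_g) sqrt(t(w_h) R w_h))}, and returns
#' the joint z-vector and correlation matrix with genes ordered first.  The
#' gene rows are always computed from the full model-variant LD; the variant
#' columns of the output are restricted to \code{variant_ids} (for example a
#' thinned set).  The result is symmetrized and eigenvalue-clipped at zero.
#'
#' @param region_id region identifier.
#' @param variant_ids ordered variant ids to include as variant variables;
#'   model variants of the region's genes are added automatically if missing.
#' @param gene_models list of harmonized \code{\link{WeightModel}} objects
#'   assigned to this region.
#' @param gwas harmonized GWAS data.frame (provides \code{z} and \code{n}).
#' @param ld_blocks list of \code{\link{LDBlock}} objects of the region's
#'   member blocks.
#' @return an \code{\link{AugmentedRegion}}; genes with degenerate imputation
#'   variance are dropped (ids recorded in attribute \code{"dropped_genes"}).
#' @export
buildAugmentedRegion <- function(region_id, variant_ids, gene_models, gwas, ld_blocks) {
    model_vars <- unique(unlist(lapply(gene_models, function(m) m@variants$variant_id)))
    extra <- setdiff(model_vars, variant_ids)
    if (length(extra) > 0L) {
        ## model variants are always retained in the augmented matrix
        allv <- .ldVariantTable(ld_blocks)
        variant_ids <- union(variant_ids, extra)
        ord <- match(variant_ids, allv$variant_id)
        variant_ids <- variant_ids[order(allv$chrom[ord], allv$pos[ord])]
    }
    zrow <- match(variant_ids, gwas$variant_id)
    if (anyNA(zrow)) {
        stop("z-scores missing for ", sum(is.na(zrow)), " variant(s) in region ", region_id)
    }
    z_v <- gwas$z[zrow]
    n_gwas <- as.integer(stats::median(gwas$n[zrow]))
    R_v <- .assembleRegionLD(variant_ids, ld_blocks)

    G <- length(gene_models)
    gene_ids <- vapply(gene_models, function(m) m@gene_id, "")
    Wmat <- matrix(0, nrow = G, ncol = length(variant_ids),
                   dimnames = list(gene_ids, variant_ids))
    for (i in seq_len(G)) {
        m <- gene_models[[i]]
        Wmat[i, m@variants$variant_id] <- m@weights
    }
    dropped <- character(0)
    if (G > 0L) {
        WR <- Wmat %*% R_v                    # G x p
        impvar <- rowSums(WR * Wmat)          # w' R w per gene
        ok <- is.finite(impvar) & impvar > 1e-10
        dropped <- gene_ids[!ok]
        Wmat <- Wmat[ok, , drop = FALSE]
        WR <- WR[ok, , drop = FALSE]
        impvar <- impvar[ok]
        gene_ids <- gene_ids[ok]
        G <- sum(ok)
    }
    if (G > 0L) {
        s <- sqrt(impvar)
        z_g <- drop(Wmat %*% z_v) / s
        C_gv <- WR / s                        # gene-variant correlations
        C_gg <- (WR %*% t(Wmat)) / tcrossprod(s)
        corr <- rbind(
            cbind(C_gg, C_gv),
            cbind(t(C_gv), R_v)
        )
        z <- c(z_g, z_v)
        ids <- c(gene_ids, variant_ids)
        grp <- c(rep("gene", G), rep("variant", length(variant_ids)))
    } else {
        corr <- R_v
        z <- z_v
        ids <- variant_ids
        grp <- rep("variant", length(variant_ids))
    }
    corr <- .psdClip(corr)
    corr[corr > 1] <- 1
    corr[corr < -1] <- -1
    out <- new("AugmentedRegion",
        region_id = region_id,
        variable_ids = ids,
        group = grp,
        z = z,
        corr = corr,
        n_gwas = n_gwas
    )
    attr(out, "dropped_genes") <- dropped
    out
}
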