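## Allele harmonization of GWAS z-scores and eQTL weight models against an LD
## reference. Conventions: a variant's ordered allele pair is (allele_ref,
## allele_alt); z-scores, weights and LD correlations are all signed with
## respect to the alternate-allele dosage of the LD reference.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement nucleotide alleles
#'
#' @param x character vector of single nucleotides in \code{{A,C,G,T}}.
#' @return the complementary bases.
#' @keywords internal
alleleComplement <- function(x) {
    out <- .COMPLEMENT[x]
    if (anyNA(out)) stop("non-ACGT allele")
    unname(out)
}

#' Classify an allele pair against the LD reference
#'
#' Compares the ordered allele pair of a variant in another dataset with the
#' pair in the LD reference and decides whether the pair matches, is flipped
#' (ref/alt swapped, so the effect sign must be reversed), is strand-switched
#' (complementary strand, no action needed), is ambiguous (the reference pair
#' is an A/T or G/C complementary pair, so flip and switch cannot be told
#' apart), or is incompatible.
#'
#' @param ref ordered reference pair: length-2 character vector
#'   \code{c(allele_ref, allele_alt)}, or a 2-column character matrix for
#'   vectorized use.
#' @param other ordered pair in the other dataset, same shape as \code{ref}.
#' @return character vector with values in \code{match}, \code{flipped},
#'   \code{switched}, \code{ambiguous}, \code{incompatible}.
#' @examples
#' classifyAllelePair(c("G", "A"), c("C", "T")) # switched (other strand)
#' classifyAllelePair(c("A", "T"), c("T", "A")) # ambiguous
#' @export
classifyAllelePair <- function(ref, other) {
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 2L)
    if (is.null(dim(other))) other <- matrix(other, ncol = 2L)
    stopifnot(ncol(ref) == 2L, ncol(other) == 2L, nrow(ref) == nrow(other))
    a <- ref[, 1L]; b <- ref[, 2L]
    c_ <- other[, 1L]; d <- other[, 2L]
    if (!all(c(a, b, c_, d) %in% names(.COMPLEMENT))) stop("non-ACGT allele")
    if (any(a == b) || any(c_ == d)) stop("alleles within a pair must differ")
    ca <- alleleComplement(a)
    cb <- alleleComplement(b)
    refAmbiguous <- b == ca # reference pair is complementary (A/T or G/C)
    sameSet <- (c_ == a & d == b) | (c_ == b & d == a)
    out <- rep("incompatible", length(a))
    out[refAmbiguous & sameSet] <- "ambiguous"
    idx <- !refAmbiguous
    out[idx & c_ == a & d == b] <- "match"
    out[idx & c_ == b & d == a] <- "flipped"
    out[idx & c_ == ca & d == cb] <- "switched"
    out
}

.variantKey <- function(df) paste(df$chrom, df$pos, sep = ":")

## sentinel returned when a weight model cannot be harmonized
.rejectModel <- function(reason) {
    structure(NA, class = "ctwasRejection", reason = reason)
}

#' Test whether a harmonization result is a rejection
#'
#' @param x result of \code{\link{harmonizeWeights}} or
#'   \code{\link{standardizeWeights}}.
#' @return logical; the reason sits in \code{attr(x, "reason")}.
#' @export
isRejected <- function(x) inherits(x, "ctwasRejection")

.ldVariantTable <- function(ld_blocks) {
    tabs <- lapply(ld_blocks, function(b) {
        v <- b@variants
        v$block_id <- b@block_id
        v$idx_in_block <- seq_len(nrow(v))
        v
    })
    do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Harmonize GWAS z-scores to an LD reference
#'
#' Intersects GWAS summary statistics with the LD reference by chromosome and
#' position, reverses the sign of z-scores whose alleles are flipped, leaves
#' strand-switched variants untouched, and drops variants that are missing
#' from the reference or allele-incompatible.  Ambiguous variants (A/T, G/C
#' pairs) pass through unchanged unless \code{resolveAmbiguous = TRUE}, in
#' which case each ambiguous z-score's sign is set to the sign of its
#' LD-imputed value, the ridge-regularized conditional expectation given all
#' unambiguous variants in the same block; magnitudes are never altered.
#'
#' @param gwas data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{allele_ref}, \code{allele_alt}, \code{z}, \code{n}.
#' @param ld_blocks list of \code{\link{LDBlock}} objects.
#' @param resolveAmbiguous logical; impute-and-correct ambiguous signs.
#'   Keep \code{FALSE} when GWAS and LD panel come from the same cohort.
#' @param ridge ridge penalty added to the unambiguous-variant LD diagonal in
#'   the imputation solve.
#' @return the harmonized data.frame (alleles rewritten to the LD reference
#'   orientation) with a \code{"harmonization"} attribute holding counts of
#'   dropped, flipped, switched, ambiguous and sign-corrected variants.
#' @export
harmonizeGwas <- function(gwas, ld_blocks, resolveAmbiguous = FALSE, ridge = 0.01) {
    stopifnot(is.data.frame(gwas))
    ldv <- .ldVariantTable(ld_blocks)
    key <- .variantKey(gwas)
    hit <- match(key, .variantKey(ldv))
    log <- list(n_input = nrow(gwas), n_missing_from_ld = sum(is.na(hit)))
    keep <- !is.na(hit)
    gwas <- gwas[keep, , drop = FALSE]
    hit <- hit[keep]
    cls <- classifyAllelePair(
        as.matrix(ldv[hit, c("allele_ref", "allele_alt")]),
        as.matrix(gwas[, c("allele_ref", "allele_alt")])
    )
    log$n_incompatible <- sum(cls == "incompatible")
    keep <- cls != "incompatible"
    gwas <- gwas[keep, , drop = FALSE]
    hit <- hit[keep]
    cls <- cls[keep]
    gwas$z[cls == "flipped"] <- -gwas$z[cls == "flipped"]
    ## rewrite identity to the LD reference orientation
    gwas$allele_ref <- ldv$allele_ref[hit]
    gwas$allele_alt <- ldv$allele_alt[hit]
    gwas$variant_id <- ldv$variant_id[hit]
    log$n_flipped <- sum(cls == "flipped")
    log$n_switched <- sum(cls == "switched")
    log$n_ambiguous <- sum(cls == "ambiguous")
    log$n_sign_corrected <- 0L
    if (resolveAmbiguous && log$n_ambiguous > 0L) {
        block_of <- ldv$block_id[hit]
        idx_in_block <- ldv$idx_in_block[hit]
        blocks <- setNames(ld_blocks, vapply(ld_blocks, function(b) b@block_id, ""))
        for (bid in unique(block_of[cls == "ambiguous"])) {
            inb <- which(block_of == bid)
            amb <- inb[cls[inb] == "ambiguous"]
            una <- inb[cls[inb] != "ambiguous"]
            if (length(una) == 0L) next
            R <- blocks[[bid]]@corr
            ia <- idx_in_block[amb]
            is_ <- idx_in_block[una]
            Rss <- R[is_, is_, drop = FALSE] + diag(ridge, length(is_))
            zimp <- R[ia, is_, drop = FALSE] %*% solve(Rss, gwas$z[una])
            bad <- sign(zimp) != 0 & sign(zimp) != sign(gwas$z[amb])
            gwas$z[amb[bad]] <- -gwas$z[amb[bad]]
            log$n_sign_corrected <- log$n_sign_corrected + sum(bad)
        }
    }
    rownames(gwas) <- NULL
    attr(gwas, "harmonization") <- log
    gwas
}

#' Harmonize one eQTL weight model to an LD reference
#'
#' Intersects the model's variants with the LD reference, reverses the sign of
#' flipped weights and leaves strand-switched weights untouched.  Ambiguous
#' variants are resolved by comparing, for each ambiguous variant, the sum of
#' its correlations with the model's unambiguous variants in the model's own
#' LD (from \code{model_ld_cov}) against the same sum in the reference LD: a
#' sign mismatch reverses the weight, and a reference sum of exactly zero sets
#' the weight to zero.  A model whose sole variant is ambiguous is kept
#' unchanged; a model with two or more ambiguous variants and no unambiguous
#' ones is rejected (its gene z-score could be wrong in magnitude, not just
#' sign).
#'
#' @param model a \code{\link{WeightModel}}.
#' @param ld_blocks list of \code{\link{LDBlock}} objects.
#' @param model_ld_cov optional data.frame of pairwise covariances in the LD
#'   panel the model was trained on, columns \code{var1}, \code{var2},
#'   \code{cov} (variant ids as in the model).  When absent, ambiguous weights
#'   are left unchanged.
#' @return the harmonized \code{WeightModel} (scale unchanged), or a
#'   rejection object (see \code{\link{isRejected}}) carrying the reason.
#' @export
harmonizeWeights <- function(model, ld_blocks, model_ld_cov = NULL) {
    ldv <- .ldVariantTable(ld_blocks)
    mv <- model@variants
    hit <- match(.variantKey(mv), .variantKey(ldv))
    keep <- !is.na(hit)
    if (!any(keep)) {
        return(.rejectModel("no model variant present in the LD reference"))
    }
    mv <- mv[keep, , drop = FALSE]
    w <- model@weights[keep]
    hit <- hit[keep]
    cls <- classifyAllelePair(
        as.matrix(ldv[hit, c("allele_ref", "allele_alt")]),
        as.matrix(mv[, c("allele_ref", "allele_alt")])
    )
    keep <- cls != "incompatible"
    mv <- mv[keep, , drop = FALSE]
    w <- w[keep]
    hit <- hit[keep]
    cls <- cls[keep]
    if (length(w) == 0L) {
        return(.rejectModel("all model variants allele-incompatible with the LD reference"))
    }
    w[cls == "flipped"] <- -w[cls == "flipped"]
    mv$allele_ref <- ldv$allele_ref[hit]
    mv$allele_alt <- ldv$allele_alt[hit]
    mv$variant_id <- ldv$variant_id[hit]
    amb <- which(cls == "ambiguous")
    una <- which(cls != "ambiguous")
    if (length(amb) >= 2L && length(una) == 0L) {
        return(.rejectModel("multiple ambiguous variants and no unambiguous variants"))
    }
    if (length(amb) >= 1L && length(una) >= 1L && !is.null(model_ld_cov)) {
        refsum <- .refCorrelationSums(mv, amb, una, hit, ldv, ld_blocks)
        modsum <- .modelCorrelationSums(model, mv, amb, una, model_ld_cov)
        for (k in seq_along(amb)) {
            if (is.na(modsum[k])) next
            if (refsum[k] == 0) {
                w[amb[k]] <- 0 # unambiguous partners sit in another LD region
            } else if (sign(modsum[k]) != sign(refsum[k])) {
                w[amb[k]] <- -w[amb[k]]
            }
        }
    }
    ## single ambiguous variant without unambiguous partners: keep sign as is
    initialize(model, variants = mv, weights = w)
}

.refCorrelationSums <- function(mv, amb, una, hit, ldv, ld_blocks) {
    blocks <- setNames(ld_blocks, vapply(ld_blocks, function(b) b@block_id, ""))
    bid <- ldv$block_id[hit]
    idx <- ldv$idx_in_block[hit]
    vapply(amb, function(a) {
        partners <- una[bid[una] == bid[a]]
        if (length(partners) == 0L) {
            return(0) # zero by definition: no unambiguous partner in this LD region
        }
        R <- blocks[[bid[a]]]@corr
        sum(R[idx[a], idx[partners]])
    }, numeric(1L))
}

.modelCorrelationSums <- function(model, mv, amb, una, model_ld_cov) {
    cov <- model_ld_cov
    lookup <- function(v1, v2) {
        i <- (cov$var1 == v1 & cov$var2 == v2) | (cov$var1 == v2 & cov$var2 == v1)
        if (!any(i)) return(NA_real_)
        cov$cov[which(i)[1L]]
    }
    ## original (pre-harmonization) ids index the covariance table
    orig_id <- model@variants$variant_id[match(.variantKey(mv), .variantKey(model@variants))]
    sds <- vapply(orig_id, function(v) sqrt(lookup(v, v)), numeric(1L))
    vapply(seq_along(amb), function(k) {
        a <- amb[k]
        r <- vapply(una, function(u) {
            cv <- lookup(orig_id[a], orig_id[u])
            cv / (sds[a] * sds[u])
        }, numeric(1L))
        sum(r, na.rm = TRUE)
    }, numeric(1L))
}

#' Rescale per-allele weights to the standardized-genotype scale
#'
#' Per-allele weights (effect per alternate-allele dosage) are multiplied by
#' the genotype standard deviation, \code{sqrt(2 * maf * (1 - maf))} under
#' Hardy-Weinberg equilibrium, so that the weights apply to unit-variance
#' genotypes.  Variants with zero genotype variance are dropped.
#'
#' @param model a \code{\link{WeightModel}} with \code{scale = "per_allele"}.
#' @param genotype_sd numeric vector of genotype standard deviations from the
#'   LD reference, one per model variant (NA or 0 drops the variant).
#' @return the model on the \code{"standardized"} scale.
#' @export
standardizeWeights <- function(model, genotype_sd) {
    stopifnot(model@scale == "per_allele",
              length(genotype_sd) == nrow(model@variants))
    keep <- !is.na(genotype_sd) & genotype_sd > 0
    if (!any(keep)) {
        return(.rejectModel("no variant with positive genotype variance"))
    }
    initialize(model,
        variants = model@variants[keep, , drop = FALSE],
        weights = model@weights[keep] * genotype_sd[keep],
        scale = "standardized"
    )
}

#' Harmonize a set of weight models
#'
#' Applies \code{\link{harmonizeWeights}} (and, for per-allele models,
#' \code{\link{standardizeWeights}} with HWE genotype SDs from the LD
#' reference MAFs) to every model, dropping rejected models.
#'
#' @param models list of \code{\link{WeightModel}} objects.
#' @param ld_blocks list of \code{\link{LDBlock}} objects.
#' @param model_ld_cov optional covariance table (see
#'   \code{\link{harmonizeWeights}}).
#' @return named list of harmonized, standardized models; rejected gene ids
#'   and reasons in attribute \code{"rejected"}.
#' @export
harmonizeWeightSet <- function(models, ld_blocks, model_ld_cov = NULL) {
    ldv <- .ldVariantTable(ld_blocks)
    out <- list()
    rejected <- character()
    for (m in models) {
        hm <- harmonizeWeights(m, ld_blocks, model_ld_cov)
        if (isRejected(hm)) {
            rejected[m@gene_id] <- attr(hm, "reason")
            next
        }
        if (hm@scale == "per_allele") {
            maf <- ldv$maf[match(.variantKey(hm@variants), .variantKey(ldv))]
            hm <- standardizeWeights(hm, sqrt(2 * maf * (1 - maf)))
            if (isRejected(hm)) {
                rejected[m@gene_id] <- attr(hm, "reason")
                next
            }
        }
        out[[hm@gene_id]] <- hm
    }
    attr(out, "rejected") <- rejected
    out
}
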