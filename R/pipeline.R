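## End-to-end orchestration: harmonize -> region assembly -> gene expansion ->
## empirical-Bayes prior estimation (L = 1, thinned variants) -> screening
## fine-mapping (L = 5, thinned variants) -> rescue refits with the full
## (capped) variant set in regions whose top gene PIP clears the threshold ->
## results table + prior and PVE reports.

#' Pipeline configuration
#'
#' @param thin fraction of variants kept in the EM and screening passes
#'   (default 0.1).
#' @param L number of causal effects per region in fine-mapping (default 5).
#' @param em_iter EM iterations for prior estimation (default 30, at L = 1).
#' @param rescue_threshold regions with maximum gene PIP above this in the
#'   screening pass are refit with all variants (default 0.8).
#' @param max_variants cap on variants per region in the rescue pass
#'   (default 20000; a uniform random subset is taken above it).
#' @param estimation_cap regions with more variables than this are skipped
#'   during prior estimation only (default 10000).
#' @param resolve_ambiguous impute-and-correct ambiguous z-score signs during
#'   harmonization (default FALSE: in-sample LD).
#' @param coverage,purity credible-set parameters.
#' @param pip_threshold PIP threshold for declaring significant genes
#'   (default 0.8).
#' @param seed master seed; all randomness (thinning phase, cap sampling)
#'   derives from it.
#' @return a list of class \code{"CtwasConfig"}.
#' @export
ctwasConfig <- function(thin = 0.1, L = 5L, em_iter = 30L,
                        rescue_threshold = 0.8, max_variants = 20000L,
                        estimation_cap = 10000L, resolve_ambiguous = FALSE,
                        coverage = 0.95, purity = 0.5, pip_threshold = 0.8,
                        seed = 1L) {
    stopifnot(thin > 0, thin <= 1, L >= 1L, em_iter >= 1L, max_variants >= 1L)
    structure(
        list(
            thin = thin, L = as.integer(L), em_iter = as.integer(em_iter),
            rescue_threshold = rescue_threshold,
            max_variants = as.integer(max_variants),
            estimation_cap = as.integer(estimation_cap),
            resolve_ambiguous = resolve_ambiguous,
            coverage = coverage, purity = purity,
            pip_threshold = pip_threshold, seed = as.integer(seed)
        ),
        class = "CtwasConfig"
    )
}

#' Run the full causal-TWAS analysis
#'
#' @param x a \code{\link{SimBundle}}, or a harmonization-ready GWAS
#'   data.frame (see \code{\link{harmonizeGwas}} for columns).
#' @param weights list of \code{\link{WeightModel}} objects (ignored for a
#'   \code{SimBundle}).
#' @param ld_blocks list of \code{\link{LDBlock}} objects (ignored for a
#'   \code{SimBundle}).
#' @param blocks block-definition data.frame, BED-like half-open 0-based
#'   (ignored for a \code{SimBundle}).
#' @param config a \code{\link{ctwasConfig}}.
#' @param model_ld_cov optional weight-model covariance table (see
#'   \code{\link{harmonizeWeights}}).
#' @return a \code{\link{CtwasFit}}.
#' @export
setGeneric("runCtwas", function(x, ..., config = ctwasConfig()) {
    standardGeneric("runCtwas")
})

#' @rdname runCtwas
#' @export
setMethod("runCtwas", "SimBundle", function(x, ..., config = ctwasConfig()) {
    runCtwas(x@gwas, weights = x@weights, ld_blocks = x@ld, blocks = x@blocks,
             config = config, ...)
})

#' @rdname runCtwas
#' @export
setMethod("runCtwas", "data.frame", function(x, weights, ld_blocks, blocks,
                                             model_ld_cov = NULL, ...,
                                             config = ctwasConfig()) {
    .runCtwasCore(x, weights, ld_blocks, blocks, model_ld_cov, config)
})

.runCtwasCore <- function(gwas, weights, ld_blocks, blocks, model_ld_cov, config) {
    stopifnot(inherits(config, "CtwasConfig"), is.data.frame(gwas),
              is.list(weights), is.list(ld_blocks), is.data.frame(blocks))
    run_log <- list(seed = config$seed)

    gwas <- harmonizeGwas(gwas, ld_blocks,
                          resolveAmbiguous = config$resolve_ambiguous)
    run_log$harmonization <- attr(gwas, "harmonization")
    weights <- harmonizeWeightSet(weights, ld_blocks, model_ld_cov)
    run_log$rejected_models <- attr(weights, "rejected")

    index <- assignRegions(blocks, gwas, weights)
    run_log$rejected_genes <- index@rejected_genes
    block_lookup <- setNames(ld_blocks, vapply(ld_blocks, function(b) b@block_id, ""))

    regionBlocks <- function(rid) {
        members <- strsplit(index@regions$member_blocks[
            index@regions$region_id == rid], ",", fixed = TRUE)[[1L]]
        block_lookup[members]
    }
    regionModels <- function(rid) weights[index@region_genes[[rid]]]

    rids <- index@regions$region_id
    aug_screen <- list()
    for (rid in rids) {
        vids <- index@region_variants[[rid]]
        mask <- thinVariants(length(vids), config$thin,
                             seed = config$seed + .regionSeedOffset(rid))
        aug_screen[[rid]] <- buildAugmentedRegion(
            rid, vids[mask], regionModels(rid), gwas, regionBlocks(rid)
        )
    }

    ## the rescale factor from the estimation-stage variant prior to the
    ## full-set per-variant prior is the realized coverage (strided variants
    ## plus the always-kept model variants), not the nominal thin fraction
    n_variant_vars <- sum(vapply(aug_screen, function(r) sum(r@group == "variant"),
                                 integer(1L)))
    thin_realized <- min(1, n_variant_vars / nrow(gwas))
    theta <- fitPriors(aug_screen,
        nIter = config$em_iter,
        estimationCap = config$estimation_cap,
        thin = thin_realized
    )

    fits <- list()
    augmented <- list()
    rescued <- character(0)
    failed <- character(0)
    for (rid in rids) {
        fit <- tryCatch(
            finemapRegion(aug_screen[[rid]], theta,
                L = config$L, thinnedVariants = TRUE,
                coverage = config$coverage, purity = config$purity
            ),
            error = function(e) e
        )
        if (inherits(fit, "error")) {
            failed <- c(failed, rid)
            next
        }
        region <- aug_screen[[rid]]
        gene_pips <- fit@pip[fit@group == "gene"]
        if (length(gene_pips) > 0L && max(gene_pips) > config$rescue_threshold &&
            config$thin < 1) {
            full <- index@region_variants[[rid]]
            model_vars <- unique(unlist(lapply(regionModels(rid),
                                               function(m) m@variants$variant_id)))
            pool <- setdiff(full, model_vars)
            room <- config$max_variants - length(model_vars)
            if (length(pool) > max(room, 0L)) {
                keep <- capVariants(length(pool), max(room, 0L),
                                    seed = config$seed + .regionSeedOffset(rid) + 1L)
                full <- union(model_vars, pool[keep])
                run_log$cap_triggered <- union(run_log$cap_triggered, rid)
            }
            region <- buildAugmentedRegion(rid, full, regionModels(rid), gwas,
                                           regionBlocks(rid))
            fit <- tryCatch(
                finemapRegion(region, theta,
                    L = config$L, thinnedVariants = FALSE,
                    coverage = config$coverage, purity = config$purity
                ),
                error = function(e) e
            )
            if (inherits(fit, "error")) {
                failed <- c(failed, rid)
                next
            }
            rescued <- c(rescued, rid)
        }
        fits[[rid]] <- fit
        augmented[[rid]] <- region
    }
    run_log$rescued_regions <- rescued
    run_log$failed_regions <- failed

    results <- .resultsTable(fits, augmented, rescued)
    n_gwas <- as.integer(stats::median(gwas$n))
    new("CtwasFit",
        results = results,
        priors = theta,
        pve = pveReport(theta, n_gwas),
        fits = fits,
        regions = index,
        augmented = augmented,
        log = run_log
    )
}

.resultsTable <- function(fits, augmented, rescued) {
    rows <- lapply(names(fits), function(rid) {
        f <- fits[[rid]]
        cs <- rep(NA_character_, length(f@variable_ids))
        for (s in f@sets) {
            cs[match(s$members, f@variable_ids)] <- s$cs_id
        }
        data.frame(
            variable_id = f@variable_ids,
            type = f@group,
            region_id = rid,
            z = augmented[[rid]]@z[match(f@variable_ids, augmented[[rid]]@variable_ids)],
            PIP = f@pip,
            credible_set_id = cs,
            in_rescue_pass = rid %in% rescued,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out[order(out$region_id, out$type, out$variable_id), , drop = FALSE]
}

#' Significant genes of a fit
#'
#' @param fit a \code{\link{CtwasFit}}.
#' @param threshold PIP threshold (default the config's, 0.8).
#' @return data.frame of gene rows with PIP above the threshold.
#' @export
significantGenes <- function(fit, threshold = 0.8) {
    res <- fit@results
    out <- res[res$type == "gene" & !is.na(res$PIP) & res$PIP > threshold, , drop = FALSE]
    rownames(out) <- NULL
    out
}
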