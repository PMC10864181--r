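## Genome-lite simulator: LD-blocked genotypes from a thresholded latent
## Gaussian, sparse eQTL weight models, spike-and-slab (or scale-mixture)
## causal effects for genes and variants, a standardized phenotype, in-sample
## GWAS z-scores and subsample LD -- with full ground truth. The generator
## emulates the statistical structure a causal-TWAS run consumes; it does not
## attempt coalescent realism.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study design: 5,000 individuals, 100 LD
#' blocks of 300 variants and 3 genes each, MAF uniform in [0.05, 0.5],
#' adjacent-variant latent LD 0.99, 1-5 eQTLs per gene, gene prior 0.1 with
#' gene PVE 0.05 (about 30 causal genes), variant prior 0.005 with variant
#' PVE 0.2 (about 150 causal variants), and LD estimated from a subsample of
#' 2,000 individuals.
#'
#' @param n_individuals cohort size.
#' @param n_blocks number of LD blocks.
#' @param variants_per_block variants per block.
#' @param genes_per_block genes per block.
#' @param maf_range minor allele frequency range (uniform draw per variant).
#' @param ld_decay latent AR(1) correlation between adjacent variants in
#'   [0, 1); 0 gives near-independent variants.  The default 0.99 leaves a
#'   variant and its nearest 10\%-thinned proxy (up to five positions, about
#'   5 kb, apart) with dosage correlation r-squared of roughly 0.6-0.8,
#'   emulating the tagging strength of a dense common-variant biobank panel.
#' @param eqtls_per_gene integer range (min, max) of eQTLs per gene.
#' @param pi_gene,pi_variant prior causal probabilities per gene / variant.
#' @param pve_gene,pve_variant target proportions of phenotypic variance
#'   explained by gene and by direct variant effects (sum < 1).
#' @param effect_dist \code{"normal"} or \code{"mixture_1248"} (equal-weight
#'   mixture of four normals with SD ratios 1:2:4:8, scaled to the same
#'   target group PVE).
#' @param span_prob probability that a gene's eQTLs span two adjacent blocks
#'   (exercises region merging).
#' @param ld_subsample individuals used to estimate the LD reference
#'   (\code{NULL} or >= n uses all individuals, giving exact in-sample LD).
#' @param n_chrom number of chromosomes the blocks tile.
#' @param seed master seed.
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_individuals = 5000L, n_blocks = 100L,
                      variants_per_block = 300L, genes_per_block = 3L,
                      maf_range = c(0.05, 0.5), ld_decay = 0.99,
                      eqtls_per_gene = c(1L, 5L),
                      pi_gene = 0.1, pi_variant = 0.005,
                      pve_gene = 0.05, pve_variant = 0.2,
                      effect_dist = c("normal", "mixture_1248"),
                      span_prob = 0.02, ld_subsample = 2000L,
                      n_chrom = 10L, seed = 1L) {
    effect_dist <- match.arg(effect_dist)
    stopifnot(
        pve_gene >= 0, pve_variant >= 0, pve_gene + pve_variant < 1,
        pi_gene >= 0, pi_gene <= 1, pi_variant >= 0, pi_variant <= 1,
        maf_range[1] > 0, maf_range[2] <= 0.5, ld_decay >= 0, ld_decay < 1,
        eqtls_per_gene[1] >= 1L
    )
    structure(
        list(
            n_individuals = as.integer(n_individuals),
            n_blocks = as.integer(n_blocks),
            variants_per_block = as.integer(variants_per_block),
            genes_per_block = as.integer(genes_per_block),
            maf_range = maf_range, ld_decay = ld_decay,
            eqtls_per_gene = as.integer(eqtls_per_gene),
            pi_gene = pi_gene, pi_variant = pi_variant,
            pve_gene = pve_gene, pve_variant = pve_variant,
            effect_dist = effect_dist, span_prob = span_prob,
            ld_subsample = if (is.null(ld_subsample)) NULL else as.integer(ld_subsample),
            n_chrom = as.integer(n_chrom), seed = as.integer(seed)
        ),
        class = "SimConfig"
    )
}

.withSeed <- function(seed, code) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

## latent AR(1) Gaussian matrix, rows independent, columns correlated
.latentAR1 <- function(nrow, ncol, rho) {
    X <- matrix(rnorm(nrow * ncol), nrow, ncol)
    if (rho > 0 && ncol > 1L) {
        s <- sqrt(1 - rho^2)
        for (m in 2:ncol) {
            X[, m] <- rho * X[, m - 1L] + s * X[, m]
        }
    }
    X
}

#' Simulate LD-blocked genotype dosages
#'
#' Per block, two haplotypes per individual are drawn from a latent Gaussian
#' with AR(1) column correlation \code{ld_decay} and thresholded at the
#' allele-frequency quantile, so dosages are 0/1/2 under Hardy-Weinberg
#' equilibrium with block-local LD; blocks are independent.  Deterministic
#' given \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{genotypes} (named list of integer n x m dosage
#'   matrices, columns named by variant id), \code{variants} (named list of
#'   per-block variant data.frames with realized MAF), and \code{blocks}
#'   (BED-like half-open 0-based block definition data.frame).
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    .withSeed(config$seed, {
        n <- config$n_individuals
        M <- config$variants_per_block
        per_chrom <- ceiling(config$n_blocks / config$n_chrom)
        span <- M * 1000L
        genotypes <- list()
        variants <- list()
        blocks <- vector("list", config$n_blocks)
        for (b in seq_len(config$n_blocks)) {
            chrom_i <- (b - 1L) %/% per_chrom + 1L
            j <- (b - 1L) %% per_chrom # block rank within chromosome
            chrom <- paste0("chr", chrom_i)
            block_id <- sprintf("B%03d", b)
            start0 <- j * span
            pos <- start0 + 1000L * (seq_len(M) - 1L) + 500L
            ## allele frequencies drift smoothly along the block: neighbours in
            ## strong LD share similar MAF (mismatched MAFs would cap the
            ## attainable dosage correlation well below the latent LD)
            maf <- config$maf_range[1] + diff(config$maf_range) *
                pnorm(drop(.latentAR1(1L, M, config$ld_decay)))
            thr <- qnorm(maf)
            H <- .latentAR1(2L * n, M, config$ld_decay)
            A <- H < rep(thr, each = 2L * n)
            dos <- A[seq_len(n), , drop = FALSE] + A[n + seq_len(n), , drop = FALSE]
            storage.mode(dos) <- "integer"
            ## transitions (A/G, C/T) twice as likely as transversions, so a
            ## realistic ~1/6 of variants are strand-ambiguous (A/T or G/C)
            al <- t(vapply(seq_len(M), function(i) {
                pair <- if (runif(1) < 2 / 3) {
                    if (runif(1) < 0.5) c("A", "G") else c("C", "T")
                } else {
                    list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))[[
                        sample.int(4L, 1L)]]
                }
                sample(pair)
            }, character(2L)))
            vid <- sprintf("%s_%s", block_id, format(pos, trim = TRUE, scientific = FALSE))
            colnames(dos) <- vid
            genotypes[[block_id]] <- dos
            variants[[block_id]] <- data.frame(
                variant_id = vid, chrom = chrom, pos = pos,
                allele_ref = al[, 1L], allele_alt = al[, 2L],
                maf = colMeans(dos) / 2,
                stringsAsFactors = FALSE
            )
            blocks[[b]] <- data.frame(
                chrom = chrom, start = start0, stop = start0 + span,
                block_id = block_id, stringsAsFactors = FALSE
            )
        }
        list(
            genotypes = genotypes,
            variants = variants,
            blocks = do.call(rbind, c(blocks, list(make.row.names = FALSE)))
        )
    })
}

#' Simulate sparse eQTL weight models
#'
#' Each gene receives 1-5 eQTL variants inside its block (occasionally, with
#' probability \code{span_prob}, split over two adjacent blocks on the same
#' chromosome, which exercises region merging downstream) and normal weights
#' on the standardized-genotype scale.  Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param geno output of \code{\link{simulateGenotypes}}.
#' @return named list of \code{\link{WeightModel}} objects.
#' @export
simulateWeights <- function(config, geno) {
    stopifnot(inherits(config, "SimConfig"))
    .withSeed(config$seed + 1L, {
        models <- list()
        block_ids <- names(geno$genotypes)
        blocks <- geno$blocks
        for (b in seq_along(block_ids)) {
            bid <- block_ids[b]
            nxt <- if (b < length(block_ids) &&
                       blocks$chrom[b + 1L] == blocks$chrom[b]) block_ids[b + 1L] else NA
            for (g in seq_len(config$genes_per_block)) {
                k <- sample(seq(config$eqtls_per_gene[1], config$eqtls_per_gene[2]), 1L)
                span <- !is.na(nxt) && k >= 2L && runif(1) < config$span_prob
                if (span) {
                    k1 <- max(1L, k %/% 2L)
                    rows <- rbind(
                        geno$variants[[bid]][sample(nrow(geno$variants[[bid]]), k1), ],
                        geno$variants[[nxt]][sample(nrow(geno$variants[[nxt]]), k - k1), ]
                    )
                } else {
                    rows <- geno$variants[[bid]][sample(nrow(geno$variants[[bid]]), k), ]
                }
                rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
                rownames(rows) <- NULL
                gene_id <- sprintf("GENE_%s_%d", bid, g)
                models[[gene_id]] <- new("WeightModel",
                    gene_id = gene_id,
                    chrom = rows$chrom[1L],
                    tss_pos = as.integer(rows$pos[1L]),
                    variants = rows[, c("variant_id", "chrom", "pos",
                                        "allele_ref", "allele_alt")],
                    weights = rnorm(k),
                    scale = "standardized"
                )
            }
        }
        models
    })
}

## draw causal effects for one group: normal, or an equal-weight mixture of
## four normals with SD ratios 1:2:4:8, both with overall variance sigma2_b
.drawEffects <- function(n_causal, sigma2_b, effect_dist) {
    if (n_causal == 0L) return(numeric(0))
    if (effect_dist == "normal") {
        rnorm(n_causal, sd = sqrt(sigma2_b))
    } else {
        ## E[beta^2] = mean(1,4,16,64) * s^2 = 21.25 s^2
        s <- sqrt(sigma2_b / 21.25)
        comp <- sample(c(1, 2, 4, 8), n_causal, replace = TRUE)
        rnorm(n_causal, sd = comp * s)
    }
}

#' Simulate a phenotype under the joint gene + variant model
#'
#' Imputes each gene's expression from its weight model (standardized to unit
#' variance), draws causal indicators Bernoulli(\code{pi_k}) per group,
#' effect sizes with per-variable variance \code{pve_k / (pi_k * |M_k|)}
#' (standardized scale, so the expected group PVE matches the target; under
#' \code{"mixture_1248"} the four component SDs keep exact ratios 1:2:4:8),
#' and a residual completing unit variance.  The returned phenotype is
#' standardized.  If no causal variable at all is drawn, the indicators are
#' resampled once.  Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param geno output of \code{\link{simulateGenotypes}}.
#' @param weights output of \code{\link{simulateWeights}}.
#' @return a truth list: \code{y}, \code{causal_genes} / \code{causal_variants}
#'   data.frames (id, effect), realized per-group PVE, residual sd
#'   \code{sigma}, and the imputed standardized expression matrix.
#' @export
simulateTrait <- function(config, geno, weights) {
    stopifnot(inherits(config, "SimConfig"))
    .withSeed(config$seed + 2L, {
        n <- config$n_individuals
        gene_ids <- names(weights)
        nG <- length(gene_ids)
        expr <- matrix(0, n, nG, dimnames = list(NULL, gene_ids))
        block_of_variant <- rep(names(geno$variants),
                                vapply(geno$variants, nrow, integer(1L)))
        names(block_of_variant) <- unlist(lapply(geno$variants, `[[`, "variant_id"),
                                          use.names = FALSE)
        ## standardize single genotype columns on demand (the full standardized
        ## matrix would not fit comfortably in memory at genome-lite scale)
        stdCol <- function(vid) {
            g <- geno$genotypes[[block_of_variant[[vid]]]][, vid]
            sdg <- sd(g)
            if (sdg > 0) (g - mean(g)) / sdg else numeric(length(g))
        }
        for (i in seq_len(nG)) {
            m <- weights[[i]]
            x <- numeric(n)
            for (j in seq_len(nrow(m@variants))) {
                x <- x + m@weights[j] * stdCol(m@variants$variant_id[j])
            }
            sdx <- sd(x)
            expr[, i] <- if (sdx > 0) (x - mean(x)) / sdx else 0
        }
        all_vids <- names(block_of_variant)
        nV <- length(all_vids)

        drawIndicators <- function() {
            list(
                genes = which(rbinom(nG, 1L, config$pi_gene) == 1L),
                vars = which(rbinom(nV, 1L, config$pi_variant) == 1L)
            )
        }
        ind <- drawIndicators()
        resampled <- FALSE
        if (length(ind$genes) + length(ind$vars) == 0L) {
            ind <- drawIndicators() # one resample, then proceed regardless
            resampled <- TRUE
        }
        s2g <- if (config$pi_gene > 0 && nG > 0) config$pve_gene / (config$pi_gene * nG) else 0
        s2v <- if (config$pi_variant > 0 && nV > 0) config$pve_variant / (config$pi_variant * nV) else 0
        beta <- .drawEffects(length(ind$genes), s2g, config$effect_dist)
        theta <- .drawEffects(length(ind$vars), s2v, config$effect_dist)

        gene_comp <- if (length(ind$genes) > 0L) {
            drop(expr[, ind$genes, drop = FALSE] %*% beta)
        } else numeric(n)
        var_comp <- numeric(n)
        for (k in seq_along(ind$vars)) {
            var_comp <- var_comp + theta[k] * stdCol(all_vids[ind$vars[k]])
        }
        sigma <- sqrt(max(0, 1 - config$pve_gene - config$pve_variant))
        eps <- rnorm(n, sd = sigma)
        y_raw <- gene_comp + var_comp + eps
        vy <- var(y_raw)
        list(
            y = drop(scale(y_raw)),
            causal_genes = data.frame(
                id = gene_ids[ind$genes], effect = beta, stringsAsFactors = FALSE
            ),
            causal_variants = data.frame(
                id = all_vids[ind$vars], effect = theta, stringsAsFactors = FALSE
            ),
            realized_pve_gene = var(gene_comp) / vy,
            realized_pve_variant = var(var_comp) / vy,
            sigma = sigma,
            resampled = resampled,
            expression = expr
        )
    })
}

#' Compute GWAS summary statistics and in-sample LD
#'
#' Per-variant z-scores from simple regression of the standardized phenotype
#' on standardized genotypes, \code{z = sqrt(n) * cor(G_m, y)}, and per-block
#' LD correlation matrices from a subsample of individuals (exact in-sample
#' LD when the subsample is the whole cohort).  Monomorphic variants get
#' \code{z = 0} and are flagged.
#'
#' @param config a \code{\link{simConfig}} (provides the subsample size and
#'   seed).
#' @param geno output of \code{\link{simulateGenotypes}}.
#' @param y standardized phenotype vector.
#' @return list with \code{gwas} (summary-statistics data.frame) and \code{ld}
#'   (named list of \code{\link{LDBlock}}).
#' @export
computeSumstats <- function(config, geno, y) {
    stopifnot(inherits(config, "SimConfig"))
    .withSeed(config$seed + 3L, {
        n <- config$n_individuals
        sub <- if (is.null(config$ld_subsample) || config$ld_subsample >= n) {
            seq_len(n)
        } else {
            sort(sample.int(n, config$ld_subsample))
        }
        gwas <- list()
        ld <- list()
        for (bid in names(geno$genotypes)) {
            G <- geno$genotypes[[bid]]
            r <- suppressWarnings(drop(cor(G, y)))
            mono <- !is.finite(r)
            r[mono] <- 0
            z <- sqrt(n) * r
            vt <- geno$variants[[bid]]
            gwas[[bid]] <- data.frame(
                variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
                allele_ref = vt$allele_ref, allele_alt = vt$allele_alt,
                z = z, n = n, monomorphic = mono, stringsAsFactors = FALSE
            )
            R <- suppressWarnings(cor(G[sub, , drop = FALSE]))
            R[!is.finite(R)] <- 0
            diag(R) <- 1
            ld[[bid]] <- new("LDBlock", block_id = bid, variants = vt, corr = R)
        }
        gwas <- do.call(rbind, c(unname(gwas), list(make.row.names = FALSE)))
        list(gwas = gwas, ld = ld)
    })
}

#' Simulate a complete causal-TWAS input bundle with ground truth
#'
#' Chains \code{\link{simulateGenotypes}}, \code{\link{simulateWeights}},
#' \code{\link{simulateTrait}} and \code{\link{computeSumstats}} into a
#' \code{\link{SimBundle}} that the pipeline (or the on-disk writers) can
#' consume directly.
#'
#' @param config a \code{\link{simConfig}}.
#' @param keep_genotypes keep the dosage matrices in the bundle (needed for
#'   individual-level cross-checks; set \code{FALSE} to save memory).
#' @return a \code{\link{SimBundle}}.
#' @export
simulateCtwasData <- function(config = simConfig(), keep_genotypes = TRUE) {
    geno <- simulateGenotypes(config)
    weights <- simulateWeights(config, geno)
    truth <- simulateTrait(config, geno, weights)
    ss <- computeSumstats(config, geno, truth$y)
    truth$config <- config
    expr <- truth$expression
    truth$expression <- NULL
    new("SimBundle",
        genotypes = if (keep_genotypes) geno$genotypes else list(),
        blocks = geno$blocks,
        ld = ss$ld,
        gwas = ss$gwas,
        weights = weights,
        truth = c(truth, list(expression = if (keep_genotypes) expr else NULL))
    )
}
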