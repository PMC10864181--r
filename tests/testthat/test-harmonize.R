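test_that("allele pair classification covers match, flip, switch, ambiguity and incompatibility", {
    cases <- list(
        list(c("G", "A"), c("G", "A"), "match"),
        list(c("G", "A"), c("A", "G"), "flipped"),
        list(c("G", "A"), c("C", "T"), "switched"),
        list(c("A", "T"), c("T", "A"), "ambiguous"),
        list(c("A", "T"), c("A", "T"), "ambiguous"),
        list(c("C", "G"), c("G", "C"), "ambiguous"),
        list(c("G", "A"), c("C", "A"), "incompatible"),
        list(c("G", "A"), c("T", "C"), "incompatible")
    )
    for (cs in cases) {
        expect_identical(classifyAllelePair(cs[[1]], cs[[2]]), cs[[3]])
    }
    ## identity is a match for every valid non-complementary pair, ambiguous
    ## for complementary pairs
    pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    for (i in seq_len(nrow(pairs))) {
        pr <- c(pairs$a[i], pairs$b[i])
        expected <- if (alleleComplement(pr[1]) == pr[2]) "ambiguous" else "match"
        expect_identical(classifyAllelePair(pr, pr), expected)
    }
    expect_error(classifyAllelePair(c("G", "N"), c("G", "A")), "non-ACGT")
    expect_error(classifyAllelePair(c("G", "G"), c("G", "A")), "differ")
})

test_that("classification is invariant under simultaneous strand complementation of unambiguous pairs", {
    set.seed(42)
    for (i in 1:50) {
        repeat {
            pr <- sample(c("A", "C", "G", "T"), 2L)
            if (alleleComplement(pr[1]) != pr[2]) break
        }
        other <- switch(sample(3L, 1L), pr, rev(pr), alleleComplement(pr))
        base <- classifyAllelePair(pr, other)
        ## complementing both datasets together preserves the classification
        ## of unambiguous pairs
        comp <- classifyAllelePair(alleleComplement(pr), alleleComplement(other))
        expect_identical(comp, base)
    }
})

.harmonizeFixture <- function() {
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- 0.9
    ld <- makeLdBlock("B1", rep("chr1", 4), c(100, 200, 300, 400),
                      ref = c("G", "A", "G", "T"), alt = c("A", "C", "C", "C"),
                      corr = R)
    gwas <- data.frame(
        variant_id = paste0("v", 1:5),
        chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 999L),
        allele_ref = c("A", "G", "C", "T", "A"),
        allele_alt = c("G", "T", "G", "C", "C"),
        z = c(2.5, 1.0, -1.5, 3.0, 9.9), n = 1000L,
        stringsAsFactors = FALSE
    )
    list(gwas = gwas, ld = list(ld))
}

test_that("z harmonization flips, strand-corrects, drops and is idempotent", {
    fx <- .harmonizeFixture()
    out <- harmonizeGwas(fx$gwas, fx$ld)
    log <- attr(out, "harmonization")
    ## v5 missing from the reference, v2 (G/T vs ref A/C) incompatible
    expect_equal(log$n_missing_from_ld, 1L)
    expect_equal(log$n_incompatible, 1L)
    expect_equal(nrow(out), 3L)
    ## v1 flipped (ref G/A, gwas A/G): sign reversed
    expect_equal(out$z[out$pos == 100], -2.5)
    ## v3 switched (ref G/C is ambiguous pair? G/C IS complementary -> ambiguous)
    ## pos 300 ref G/C: complementary pair, gwas C/G: ambiguous, untouched
    expect_equal(out$z[out$pos == 300], -1.5)
    ## v4 switched unambiguously? ref T/C vs gwas T/C reversed-comp:
    ## gwas (T, C) vs ref (T, C) -> match, untouched
    expect_equal(out$z[out$pos == 400], 3.0)
    ## alleles rewritten to the reference orientation
    expect_identical(out$allele_ref, fx$ld[[1]]@variants$allele_ref[c(1, 3, 4)])
    ## idempotence
    twice <- harmonizeGwas(out, fx$ld)
    expect_equal(twice$z, out$z)
    expect_identical(twice$variant_id, out$variant_id)
})

test_that("ambiguous z signs are corrected from LD-imputed values", {
    ## two variants, r = 1: one unambiguous anchor, one ambiguous with the
    ## wrong sign; the imputed value (r * z_anchor = +3) overrides the sign
    R <- matrix(c(1, 1, 1, 1), 2, 2)
    ld <- makeLdBlock("B1", c("chr1", "chr1"), c(10, 20),
                      ref = c("G", "A"), alt = c("A", "T"), corr = R)
    gwas <- data.frame(
        variant_id = c("u", "a"), chrom = "chr1", pos = c(10L, 20L),
        allele_ref = c("G", "A"), allele_alt = c("A", "T"),
        z = c(3, -3), n = 500L, stringsAsFactors = FALSE
    )
    out <- harmonizeGwas(gwas, list(ld), resolveAmbiguous = TRUE)
    expect_equal(out$z[out$pos == 20], 3) # sign corrected, magnitude kept
    expect_equal(attr(out, "harmonization")$n_sign_corrected, 1L)
    ## without the flag the ambiguous variant passes through
    out2 <- harmonizeGwas(gwas, list(ld), resolveAmbiguous = FALSE)
    expect_equal(out2$z[out2$pos == 20], -3)
    ## a block with no ambiguous variants is returned unchanged
    gwas3 <- gwas
    gwas3$allele_ref[2] <- "C"
    gwas3$allele_alt[2] <- "A"
    ld3 <- makeLdBlock("B1", c("chr1", "chr1"), c(10, 20),
                       ref = c("G", "C"), alt = c("A", "A"), corr = R)
    out3 <- harmonizeGwas(gwas3, list(ld3), resolveAmbiguous = TRUE)
    expect_equal(out3$z, gwas3$z)
})

test_that("weight harmonization handles flips, lone-ambiguous retention and rejection", {
    R <- diag(3)
    ld <- makeLdBlock("B1", rep("chr1", 3), c(10, 20, 30),
                      ref = c("G", "C", "A"), alt = c("A", "A", "T"), corr = R)
    ## flipped second variant: weight sign reversed
    m <- makeWeightModel("g1", rep("chr1", 2), c(10, 20),
                         ref = c("G", "A"), alt = c("A", "C"), weights = c(0.3, 0.4))
    hm <- harmonizeWeights(m, list(ld))
    expect_s4_class(hm, "WeightModel")
    expect_equal(hm@weights, c(0.3, -0.4))
    ## single-variant ambiguous model: kept, sign unchanged
    m2 <- makeWeightModel("g2", "chr1", 30, ref = "T", alt = "A", weights = 0.7)
    hm2 <- harmonizeWeights(m2, list(ld))
    expect_equal(hm2@weights, 0.7)
    ## two ambiguous, zero unambiguous: rejected
    ld2 <- makeLdBlock("B2", rep("chr1", 2), c(40, 50),
                       ref = c("A", "C"), alt = c("T", "G"), corr = diag(2))
    m3 <- makeWeightModel("g3", rep("chr1", 2), c(40, 50),
                          ref = c("A", "C"), alt = c("T", "G"), weights = c(0.1, 0.2))
    rej <- harmonizeWeights(m3, list(ld2))
    expect_true(isRejected(rej))
    expect_match(attr(rej, "reason"), "multiple ambiguous")
})

test_that("ambiguous weights follow the correlation-sum comparison against the model LD", {
    ## variant 2 is ambiguous (A/T); its correlation sum with the unambiguous
    ## variant is +0.8 in the reference but -0.8 in the model's own LD, so the
    ## weight sign must be reversed
    R <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
    ld <- makeLdBlock("B1", c("chr1", "chr1"), c(10, 20),
                      ref = c("G", "A"), alt = c("A", "T"), corr = R)
    m <- makeWeightModel("g1", c("chr1", "chr1"), c(10, 20),
                         ref = c("G", "A"), alt = c("A", "T"), weights = c(0.5, 0.5))
    cov_tbl <- data.frame(
        var1 = c("chr1:10", "chr1:20", "chr1:10"),
        var2 = c("chr1:10", "chr1:20", "chr1:20"),
        cov = c(1, 1, -0.8), stringsAsFactors = FALSE
    )
    hm <- harmonizeWeights(m, list(ld), model_ld_cov = cov_tbl)
    expect_equal(hm@weights, c(0.5, -0.5))
    ## matching signs: weight unchanged
    cov_tbl$cov[3] <- 0.8
    hm2 <- harmonizeWeights(m, list(ld), model_ld_cov = cov_tbl)
    expect_equal(hm2@weights, c(0.5, 0.5))
    ## reference correlation sum exactly zero: ambiguous weight zeroed
    R0 <- diag(2)
    ld0 <- makeLdBlock("B1", c("chr1", "chr1"), c(10, 20),
                       ref = c("G", "A"), alt = c("A", "T"), corr = R0)
    hm3 <- harmonizeWeights(m, list(ld0), model_ld_cov = cov_tbl)
    expect_equal(hm3@weights, c(0.5, 0))
})

test_that("per-allele weights rescale by genotype standard deviation", {
    m <- makeWeightModel("g1", rep("chr1", 3), c(10, 20, 30),
                         ref = rep("G", 3), alt = rep("A", 3),
                         weights = c(0.5, 0.5, 0.9), scale = "per_allele")
    out <- standardizeWeights(m, genotype_sd = c(1, 0.5, 0))
    expect_equal(out@weights, c(0.5, 0.25)) # unit variance, then sd scaling
    expect_equal(nrow(out@variants), 2L) # zero-variance variant dropped
    expect_identical(out@scale, "standardized")
    ## HWE sd from MAF used by the set-level wrapper
    expect_equal(sqrt(2 * 0.25 * 0.75), 0.6123724, tolerance = 1e-6)
})

test_that("negating a weight together with its allele order leaves the gene z-score unchanged", {
    set.seed(7)
    R <- sampleCorr(3, seed = 7)
    ld <- makeLdBlock("B1", rep("chr1", 3), c(10, 20, 30),
                      ref = c("G", "C", "A"), alt = c("A", "A", "G"), corr = R)
    gwas <- data.frame(
        variant_id = paste0("chr1:", c(10, 20, 30)), chrom = "chr1",
        pos = c(10L, 20L, 30L), allele_ref = c("G", "C", "A"),
        allele_alt = c("A", "A", "G"), z = c(2, -1, 0.5), n = 1000L,
        stringsAsFactors = FALSE
    )
    m <- makeWeightModel("g1", rep("chr1", 3), c(10, 20, 30),
                         ref = c("G", "C", "A"), alt = c("A", "A", "G"),
                         weights = c(0.4, -0.2, 0.3))
    ## same model with variant 1 stated on the opposite allele order and the
    ## weight negated: harmonization must recover the same gene z-score
    m_flip <- m
    m_flip@variants$allele_ref[1] <- "A"
    m_flip@variants$allele_alt[1] <- "G"
    m_flip@weights[1] <- -m_flip@weights[1]
    gz <- function(model) {
        hm <- harmonizeWeights(model, list(ld))
        idx <- match(hm@variants$variant_id, gwas$variant_id)
        geneZ(hm@weights, gwas$z[idx], R[idx, idx])
    }
    expect_equal(gz(m_flip), gz(m), tolerance = 1e-12)
})
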