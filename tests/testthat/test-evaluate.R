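test_that("calibration table bins PIPs against causal fractions", {
    ## a perfect oracle occupies only the extreme bins, each on the diagonal
    pips <- c(rep(0, 50), rep(1, 10))
    truth <- pips == 1
    tab <- calibrationTable(pips, truth)
    occ <- tab[tab$count > 0, ]
    expect_equal(occ$frac_causal, occ$mean_pip)
    ## a single [0, 1] bin recovers the overall causal rate
    tab1 <- calibrationTable(c(0.1, 0.6, 0.9), c(TRUE, FALSE, TRUE),
                             bin_edges = c(0, 1))
    expect_equal(tab1$frac_causal, 2 / 3)
    expect_equal(tab1$count, 3L)
    ## empty bins carry count 0 and NA fraction
    tab2 <- calibrationTable(c(0.05, 0.95), c(FALSE, TRUE))
    expect_true(all(is.na(tab2$frac_causal[tab2$count == 0])))
    ## replicate-wise standard errors appear when labels are supplied
    set.seed(1)
    pp <- runif(200)
    tr <- runif(200) < pp
    tab3 <- calibrationTable(pp, tr, replicate = rep(1:4, each = 50))
    expect_true(any(is.finite(tab3$se)))
})

test_that("FDP and power count detections correctly", {
    out <- fdpPower(c(0.9, 0.85, 0.95, 0.2), c(TRUE, TRUE, FALSE, TRUE),
                    threshold = 0.8)
    expect_equal(out$fdp, 1 / 3)
    expect_equal(out$power, 2 / 3)
    expect_equal(out$n_detected, 3L)
    ## no detections
    out0 <- fdpPower(c(0.1, 0.2), c(TRUE, FALSE))
    expect_equal(out0$fdp, 0)
    expect_equal(out0$power, 0)
    ## threshold above 1 detects nothing
    out1 <- fdpPower(c(0.9, 1.0), c(TRUE, TRUE), threshold = 1.000001)
    expect_equal(out1$n_detected, 0L)
})

test_that("the TWAS baseline applies a two-sided Bonferroni threshold", {
    expect_false(twasBaseline(0, n_genes = 1)[[1]])
    ## |z| = 5.5 at 10,000 genes: p ~ 3.8e-8 < 5e-6
    expect_true(twasBaseline(5.5, n_genes = 10000)[[1]])
    expect_equal(attr(twasBaseline(5.5, n_genes = 10000), "p"),
                 2 * pnorm(-5.5), tolerance = 1e-12)
    ## classical boundary: |z| = 1.96 at a single test sits at p ~ 0.05
    expect_equal(attr(twasBaseline(1.96, n_genes = 1), "p"), 0.05, tolerance = 1e-3)
    expect_true(twasBaseline(1.97, n_genes = 1)[[1]])
    expect_false(twasBaseline(1.95, n_genes = 1)[[1]])
})

test_that("silver-standard precision follows the detected-positive ratio", {
    pos <- paste0("p", 1:10)
    neg <- paste0("n", 1:20)
    ## six detected positives and two detected negatives: 6/8 = 75%
    expect_equal(precisionMetric(c(pos[1:6], neg[1:2]), pos, neg), 0.75)
    ## detections outside both sets are ignored
    expect_equal(precisionMetric(c(pos[1:6], neg[1:2], "other"), pos, neg), 0.75)
    expect_equal(precisionMetric(pos[1], pos, neg), 1.0)
    expect_true(is.na(precisionMetric("other", pos, neg)))
    expect_error(precisionMetric("x", c("a", "b"), c("b", "c")))
})

.attributionFixture <- function() {
    ## region with one gene (g_fp, low PIP), one confounding variant (v1,
    ## PIP 0.9) in a credible set, plus a second region where a set holds a
    ## strong gene
    mkfit <- function(ids, grp, pips, sets) {
        new("SusieFit",
            variable_ids = ids, group = grp,
            alpha = matrix(pips, 1, length(ids)), alpha_null = 0,
            mu1 = matrix(0, 1, length(ids)), lbf = matrix(0, 1, length(ids)),
            pip = pips, sets = sets, converged = TRUE, niter = 1L,
            delta_trace = 0
        )
    }
    mkreg <- function(rid, ids, grp, corr) {
        new("AugmentedRegion", region_id = rid, variable_ids = ids,
            group = grp, z = rep(0, length(ids)), corr = corr, n_gwas = 1000L)
    }
    corr1 <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
    fit1 <- mkfit(c("g_fp", "v1"), c("gene", "variant"), c(0.1, 0.9),
                  list(list(cs_id = "r1:L1", members = "v1", coverage = 0.95,
                            purity = 1)))
    reg1 <- mkreg("r1", c("g_fp", "v1"), c("gene", "variant"), corr1)
    corr2 <- matrix(c(1, 0.8, 0.1, 0.8, 1, 0.1, 0.1, 0.1, 1), 3, 3)
    fit2 <- mkfit(c("g_fp2", "g_strong", "v2"), c("gene", "gene", "variant"),
                  c(0.2, 0.7, 0.1),
                  list(list(cs_id = "r2:L1", members = c("g_strong", "v2"),
                            coverage = 0.95, purity = 0.6)))
    reg2 <- mkreg("r2", c("g_fp2", "g_strong", "v2"),
                  c("gene", "gene", "variant"), corr2)
    ## unassignable gene: no set in its region
    fit3 <- mkfit(c("g_lone", "v3"), c("gene", "variant"), c(0.1, 0.2), list())
    reg3 <- mkreg("r3", c("g_lone", "v3"), c("gene", "variant"), diag(2))
    results <- data.frame(
        variable_id = c("g_fp", "v1", "g_fp2", "g_strong", "v2", "g_lone", "v3"),
        type = c("gene", "variant", "gene", "gene", "variant", "gene", "variant"),
        region_id = c("r1", "r1", "r2", "r2", "r2", "r3", "r3"),
        z = 0, PIP = c(0.1, 0.9, 0.2, 0.7, 0.1, 0.1, 0.2),
        credible_set_id = NA_character_, in_rescue_pass = FALSE,
        stringsAsFactors = FALSE
    )
    th <- new("GroupPriorEstimate", pi_gene = 0.01, pi_variant = 0.001,
              sigma2_gene = 10, sigma2_variant = 10, thin = 1,
              group_sizes = c(gene = 3, variant = 3), trajectory = data.frame())
    new("CtwasFit",
        results = results, priors = th, pve = pveReport(th, 1000),
        fits = list(r1 = fit1, r2 = fit2, r3 = fit3),
        regions = new("RegionIndex",
            regions = data.frame(region_id = c("r1", "r2", "r3"), chrom = "chr1",
                                 start = 0L, stop = 1L, member_blocks = ""),
            region_variants = list(r1 = "v1", r2 = "v2", r3 = "v3"),
            region_genes = list(r1 = "g_fp", r2 = c("g_fp2", "g_strong"),
                                r3 = "g_lone"),
            rejected_genes = character(0)
        ),
        augmented = list(r1 = reg1, r2 = reg2, r3 = reg3),
        log = list()
    )
}

test_that("TWAS false positives are attributed to confounding genes or variants", {
    fit <- .attributionFixture()
    out <- attributeFalsePositives(c("g_fp", "g_fp2", "g_lone"), fit)
    out <- out[order(out$gene_id), ]
    ## g_fp is correlated (0.8) with the variant-only set: variant confounding
    expect_equal(out$verdict[out$gene_id == "g_fp"], "confounded_by_variants")
    ## g_fp2 is correlated with a set whose gene PIP (0.7) beats variants (0.1)
    expect_equal(out$verdict[out$gene_id == "g_fp2"], "confounded_by_genes")
    ## no set, no correlated member: unassigned
    expect_equal(out$verdict[out$gene_id == "g_lone"], "unassigned")
    ## genes with high fine-mapping PIP are not false positives
    out2 <- attributeFalsePositives("g_strong", fit)
    expect_equal(nrow(out2), 0L)
    ## verdicts are invariant to the order of the query
    out3 <- attributeFalsePositives(c("g_lone", "g_fp2", "g_fp"), fit)
    out3 <- out3[order(out3$gene_id), ]
    rownames(out3) <- rownames(out) <- NULL
    expect_identical(out3, out)
})

test_that("ties in attribution go to variant confounding", {
    fit <- .attributionFixture()
    ## doctor the r2 set so gene and variant PIP sums tie
    fit@fits$r2@pip <- c(0.2, 0.5, 0.5)
    out <- attributeFalsePositives("g_fp2", fit)
    expect_equal(out$verdict, "confounded_by_variants")
})
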