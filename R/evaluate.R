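## Scoring against simulation truth: PIP calibration, false discovery
## proportion and power, the Bonferroni TWAS baseline, the silver-standard
## precision metric, and credible-set attribution of TWAS false positives to
## confounding genes versus variants.

#' PIP calibration table
#'
#' Bins PIPs and reports, per bin, the mean PIP and the empirical fraction of
#' truly causal variables.  With a \code{replicate} factor, the per-bin
#' standard error of the causal fraction across replicates is included.
#'
#' @param pips numeric vector of PIPs.
#' @param truth logical vector (truly causal), aligned with \code{pips}.
#' @param bin_edges monotone bin edges on [0, 1] (default deciles).
#' @param replicate optional replicate labels for standard errors.
#' @return data.frame: \code{bin_lo}, \code{bin_hi}, \code{mean_pip},
#'   \code{frac_causal}, \code{count}, \code{se}.
#' @export
calibrationTable <- function(pips, truth, bin_edges = seq(0, 1, by = 0.1),
                             replicate = NULL) {
    stopifnot(length(pips) == length(truth), !is.unsorted(bin_edges))
    bin <- cut(pips, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
    levs <- levels(bin)
    out <- data.frame(
        bin_lo = bin_edges[-length(bin_edges)],
        bin_hi = bin_edges[-1L],
        mean_pip = NA_real_, frac_causal = NA_real_,
        count = 0L, se = NA_real_
    )
    for (i in seq_along(levs)) {
        sel <- which(bin == levs[i])
        out$count[i] <- length(sel)
        if (length(sel) == 0L) next
        out$mean_pip[i] <- mean(pips[sel])
        out$frac_causal[i] <- mean(truth[sel])
        if (!is.null(replicate)) {
            fr <- tapply(truth[sel], droplevels(factor(replicate[sel])), mean)
            if (length(fr) > 1L) out$se[i] <- sd(fr) / sqrt(length(fr))
        }
    }
    out
}

#' False discovery proportion and power at a PIP threshold
#'
#' @param pips numeric PIPs.
#' @param truth logical causal status, aligned.
#' @param threshold detection threshold (default 0.8).
#' @return list: \code{fdp} (false detections over detections, 0 when there
#'   are none), \code{power} (true detections over causal count, NA when
#'   nothing is causal), \code{n_detected}.
#' @export
fdpPower <- function(pips, truth, threshold = 0.8) {
    stopifnot(length(pips) == length(truth))
    det <- !is.na(pips) & pips > threshold
    tp <- sum(det & truth)
    fp <- sum(det & !truth)
    ncausal <- sum(truth)
    list(
        fdp = fp / max(tp + fp, 1L),
        power = if (ncausal > 0L) tp / ncausal else NA_real_,
        n_detected = tp + fp
    )
}

#' Bonferroni TWAS baseline
#'
#' Declares a gene significant when its two-sided normal p-value from the
#' gene z-score falls below \code{alpha / n_genes}.
#'
#' @param gene_z named numeric vector of gene z-scores.
#' @param n_genes number of tests (default the number of z-scores).
#' @param alpha family-wise error target (default 0.05).
#' @return logical vector (named as \code{gene_z}) with the p-values in
#'   attribute \code{"p"}.
#' @export
twasBaseline <- function(gene_z, n_genes = length(gene_z), alpha = 0.05) {
    stopifnot(all(is.finite(gene_z)), n_genes >= 1L)
    p <- 2 * pnorm(-abs(gene_z))
    out <- p < alpha / n_genes
    names(out) <- names(gene_z)
    attr(out, "p") <- p
    out
}

#' Silver-standard precision
#'
#' Precision of a detected gene set against a curated positive set and a
#' nearby-bystander negative set: detected positives over detected positives
#' plus detected negatives.  Detections outside both sets are ignored; NA
#' when no detection falls in either set.
#'
#' @param detected character vector of detected gene ids.
#' @param positives,negatives disjoint character vectors.
#' @return precision in [0, 1], or NA.
#' @export
precisionMetric <- function(detected, positives, negatives) {
    stopifnot(length(intersect(positives, negatives)) == 0L)
    dp <- length(intersect(detected, positives))
    dn <- length(intersect(detected, negatives))
    if (dp + dn == 0L) return(NA_real_)
    dp / (dp + dn)
}

#' Attribute TWAS false positives to confounding genes or variants
#'
#' A TWAS false positive is a gene significant in the Bonferroni TWAS
#' baseline whose fine-mapping PIP falls below \code{pip_cutoff}.  Each such
#' gene is assigned to a credible set of its region -- by membership, or,
#' failing that, to the set holding the member it is most correlated with
#' when that correlation exceeds \code{r_cutoff}.  The PIPs of the set's
#' other genes and of its variants are then summed: a larger gene total means
#' the false positive is confounded by nearby gene effects, otherwise by
#' variant effects (ties go to variants).  Genes assignable to no set are
#' reported \code{unassigned}.
#'
#' @param twas_significant character vector of TWAS-significant gene ids.
#' @param fit a \code{\link{CtwasFit}}.
#' @param pip_cutoff PIP below which a TWAS hit counts as a false positive
#'   (default 0.5).
#' @param r_cutoff correlation needed to adopt a credible set by proximity
#'   (default 0.5).
#' @return data.frame: \code{gene_id}, \code{verdict}
#'   (\code{confounded_by_genes} / \code{confounded_by_variants} /
#'   \code{unassigned}), \code{credible_set_id}, \code{competing_gene_pip},
#'   \code{competing_variant_pip}.
#' @export
attributeFalsePositives <- function(twas_significant, fit,
                                    pip_cutoff = 0.5, r_cutoff = 0.5) {
    stopifnot(is(fit, "CtwasFit"))
    res <- fit@results
    fp <- twas_significant[twas_significant %in%
        res$variable_id[res$type == "gene" & !is.na(res$PIP) & res$PIP < pip_cutoff]]
    rows <- lapply(fp, function(g) {
        rid <- res$region_id[match(g, res$variable_id)]
        f <- fit@fits[[rid]]
        region <- fit@augmented[[rid]]
        assigned <- NULL
        for (s in f@sets) {
            if (g %in% s$members) {
                assigned <- s
                break
            }
        }
        if (is.null(assigned) && length(f@sets) > 0L) {
            gi <- match(g, region@variable_ids)
            best_r <- r_cutoff
            for (s in f@sets) {
                r <- max(abs(region@corr[gi, match(s$members, region@variable_ids)]))
                if (r > best_r) {
                    best_r <- r
                    assigned <- s
                }
            }
        }
        if (is.null(assigned)) {
            return(data.frame(
                gene_id = g, verdict = "unassigned",
                credible_set_id = NA_character_,
                competing_gene_pip = NA_real_, competing_variant_pip = NA_real_,
                stringsAsFactors = FALSE
            ))
        }
        others <- setdiff(assigned$members, g)
        oi <- match(others, f@variable_ids)
        gsum <- sum(f@pip[oi][f@group[oi] == "gene"])
        vsum <- sum(f@pip[oi][f@group[oi] == "variant"])
        data.frame(
            gene_id = g,
            verdict = if (gsum > vsum) "confounded_by_genes" else "confounded_by_variants",
            credible_set_id = assigned$cs_id,
            competing_gene_pip = gsum, competing_variant_pip = vsum,
            stringsAsFactors = FALSE
        )
    })
    if (length(rows) == 0L) {
        return(data.frame(
            gene_id = character(), verdict = character(),
            credible_set_id = character(),
            competing_gene_pip = numeric(), competing_variant_pip = numeric(),
            stringsAsFactors = FALSE
        ))
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Score a fit against simulation truth
#'
#' Convenience wrapper: gene PIPs joined with the truth labels of a
#' \code{\link{SimBundle}}.
#'
#' @param fit a \code{\link{CtwasFit}}.
#' @param bundle the \code{\link{SimBundle}} the fit was run on.
#' @return data.frame: \code{gene_id}, \code{PIP}, \code{z}, \code{causal}.
#' @export
geneTruthTable <- function(fit, bundle) {
    res <- fit@results
    genes <- res[res$type == "gene", , drop = FALSE]
    data.frame(
        gene_id = genes$variable_id,
        PIP = genes$PIP,
        z = genes$z,
        causal = genes$variable_id %in% bundle@truth$causal_genes$id,
        stringsAsFactors = FALSE
    )
}
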